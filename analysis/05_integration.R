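# Stages 3-4: for each contrast, pool significant single analytes,
# sub-network principal components, age and sex; compute full-order
# partial correlations; keep edges with |R| strictly above 0.6.
#
# Runs the orchestrated pipeline (which repeats stages 1-2 internally so
# this script does not depend on script-level intermediates being in
# sync) and writes the per-contrast networks.

source("analysis/00_common.R")

pr <- read_processed()
res <- run_pipeline(pr$blocks, pr$meta,
                    config = pipeline_config(n_perm = N_PERM,
                                             seed = PIPELINE_SEED,
                                             out_dir = res_dir("pipeline")))
print(res)
for (ct in names(res$networks)) {
  nw <- res$networks[[ct]]
  cat(ct, ":", nrow(nw$nodes), "nodes,", nrow(nw$edges), "edges\n")
  if (nrow(nw$edges) > 0) print(nw$edges, row.names = FALSE)
}
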