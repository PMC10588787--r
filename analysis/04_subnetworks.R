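# Stage 2: Gaussian-graphical-model sub-network discovery per block over
# the penalty sweep K in {1, 1.5, ..., 6}, set-level association of each
# sub-network with each contrast (signed Stouffer over member p-values
# and directions, calibrated by analyte resampling), and selection of the
# K maximising the number of significant (sub-network, contrast) pairs.
# Chosen sub-networks are summarised by PC1, adding PC2 when PC1 explains
# less than 75% of the member variance.

source("analysis/00_common.R")

pr <- read_processed()
out <- res_dir("subnetworks")
cfg <- pipeline_config(n_perm = N_PERM, seed = PIPELINE_SEED)

zmats <- lapply(pr$blocks, zscore_by_analyte)
contrast_results <- lapply(pr$blocks, function(m)
  fit_moderated_contrasts(m, pr$meta))

sw <- sweep_K(zmats, grid = cfg$k_grid, family = cfg$ggm_family)
print(sw)
assoc <- test_all_subnetworks(sw, contrast_results, n_perm = cfg$n_perm,
                              seed = cfg$seed + 202L, q = cfg$q)
chosen <- choose_K(sw, assoc)

write.table(assoc, file.path(out, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(K = names(chosen$counts),
                       significant_pairs = chosen$counts),
            file.path(out, "k_selection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("significant pairs by K:",
    paste(names(chosen$counts), chosen$counts, sep = "=",
          collapse = ", "), "\n")
cat("chosen K:", chosen$K, "\n")
if (!is.na(chosen$K)) {
  for (id in unique(chosen$subnetworks$subnetwork_id)) {
    row <- chosen$subnetworks[chosen$subnetworks$subnetwork_id == id, ][1, ]
    sn <- structure(list(members = strsplit(row$members, ";")[[1]],
                         block = row$block, K = chosen$K),
                    class = "subnetwork")
    sm <- summarize_pcs(zmats[[row$block]], sn,
                        pc1_threshold = cfg$pc1_threshold)
    cat(sprintf("  %s: %d members, %d component(s), PC1 explains %.0f%%\n",
                id, length(sn$members), ncol(sm$scores),
                100 * sm$var_explained[1]))
    scores <- data.frame(sample_id = rownames(sm$scores), sm$scores)
    write.table(scores, file.path(out, paste0(id, "_scores.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
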