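# Stage 1: per-analyte moderated linear models with age and sex in the
# design, empirical-Bayes variance shrinkage across analytes, and
# Benjamini-Hochberg correction per contrast at 5% FDR.

source("analysis/00_common.R")

pr <- read_processed()
out <- res_dir("contrasts")

for (b in names(pr$blocks)) {
  res <- fit_moderated_contrasts(pr$blocks[[b]], pr$meta)
  write.table(res, file.path(out, paste0(b, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prior <- attr(res, "prior")
  cat(sprintf("%-11s prior df %.1f, prior variance %.3f\n", b,
              prior$d0, prior$s0_sq))
  for (ct in names(contrast_specs()))
    cat(sprintf("  %-22s %d significant analytes\n", ct,
                sum(res$significant[res$contrast == ct])))
}
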