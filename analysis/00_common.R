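# shared paths and settings for the numbered analysis scripts
library(triomics)

STUDY_SEED <- 18L
PIPELINE_SEED <- 20L
N_PERM <- 2000

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

read_processed <- function() {
  dir <- file.path("results", "processed")
  blocks <- list()
  for (b in c("protein", "eicosanoid", "metabolite"))
    blocks[[b]] <- read_analyte_matrix(file.path(dir, paste0(b, ".tsv")),
                                       block = b, scale = "log2")
  list(blocks = blocks,
       meta = read_sample_meta(file.path(dir, "samples.tsv")))
}
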