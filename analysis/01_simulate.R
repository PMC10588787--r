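# Generate the demonstration three-block plasma study.
#
# The study emulates the cohort design: 11 healthy donors, 12 patients in
# remission, 16 with active disease; three omics blocks (60 proteins, 24
# eicosanoids, 90 targeted metabolites) with planted correlated
# sub-networks, group effects, age/sex confounding, left censoring of the
# eicosanoid block and missing protein values. Ground truth is written
# alongside the data so later stages can be scored.

source("analysis/00_common.R")

study <- generate_study(demo_study_config(STUDY_SEED))
write_study(study, res_dir("study"))

cat("study written to results/study\n")
for (b in names(study$blocks)) print(study$blocks[[b]])
cat("groups:", paste(names(table(study$meta$group)),
                     table(study$meta$group), sep = "=",
                     collapse = ", "), "\n")
cat("planted effect analytes per contrast:",
    paste(names(study$truth$true_effect_sets),
          lengths(study$truth$true_effect_sets), sep = "=",
          collapse = ", "), "\n")
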