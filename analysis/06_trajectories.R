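# Trajectory classification: per analyte, residualise on age and sex,
# z-score, average per group, and classify the healthy -> remission ->
# active pattern (normalising / non-normalising / exceptional, with
# sentinels for patterns outside the taxonomy). delta = 1/3 of the
# healthy-to-active span operationalises "close to".

source("analysis/00_common.R")

pr <- read_processed()
out <- res_dir("trajectories")

all_traj <- do.call(rbind, lapply(pr$blocks, function(m)
  classify_trajectories(m, pr$meta)))
rownames(all_traj) <- NULL
write.table(all_traj, file.path(out, "trajectories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("trajectory classes over", nrow(all_traj), "analytes:\n")
print(table(all_traj$block, all_traj$class))

# score against the planted ground truth
truth <- jsonlite::read_json(file.path("results", "study",
                                       "truth.json"))
tt <- unlist(truth$true_trajectory)
if (length(tt)) {
  got <- all_traj$class[match(names(tt), all_traj$analyte_id)]
  cat(sprintf("planted profiles recovered: %d / %d\n",
              sum(got == tt, na.rm = TRUE), length(tt)))
}
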