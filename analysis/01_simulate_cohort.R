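#!/usr/bin/env Rscript

# Step 1: generate the synthetic study at full scale.
#
# Composes the 8 stimulus pairs (each excerpt embedded in a long and a
# short context), enumerates the 26-participant trial roster, and
# produces every performance from the range-model generative law with
# planted ground truth. Writes the stimuli, the roster, the pooled
# keystroke table, the planted truth, and a run manifest under results/.

suppressPackageStartupMessages({
  library(rangeplan)
  library(dplyr)
})

seed <- as.integer(Sys.getenv("RANGEPLAN_SEED", "1"))
out <- "results"
dir.create(file.path(out, "stimuli"), showWarnings = FALSE, recursive = TRUE)

message("Generating cohort with seed ", seed, " ...")
cohort <- generate_cohort(n_participants = 26L, truth = generative_truth(),
                          seed = seed)

for (s in seq_along(cohort$stimuli)) {
  write_score(cohort$stimuli[[s]]$long,
              file.path(out, "stimuli", sprintf("stimulus%02d_long.tsv", s)))
  write_score(cohort$stimuli[[s]]$short,
              file.path(out, "stimuli", sprintf("stimulus%02d_short.tsv", s)))
}
write_table_tsv(cohort$design, file.path(out, "design.tsv"))

keystrokes <- bind_rows(lapply(seq_along(cohort$trials), function(r) {
  d <- cohort$design[r, ]
  ks <- cohort$trials[[r]]$performance$keystrokes
  ks$participant <- d$participant
  ks$trial_index <- d$trial_index
  ks
}))
write_table_tsv(keystrokes, file.path(out, "keystrokes.tsv"))

truths <- bind_rows(lapply(cohort$trials, `[[`, "truth"))
write_table_tsv(truths, file.path(out, "planted_truth.tsv"))

saveRDS(cohort, file.path(out, "cohort.rds"))
write_run_config(utils::modifyList(default_run_config(),
                                   list(seed = seed)),
                 file.path(out, "manifest.yaml"))

message("Cohort: ", nrow(cohort$design), " performances, ",
        nrow(keystrokes), " keystrokes, ", nrow(truths),
        " planted errors (rate ",
        round(nrow(truths) / sum(keystrokes$pitch > 0), 3), " per keystroke).")
message("Wrote stimuli, design, keystrokes, ground truth and manifest to ",
        out, "/.")
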