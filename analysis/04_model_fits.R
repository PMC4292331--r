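#!/usr/bin/env Rscript

# Step 4: range-model fits.
#
# Two-step per-participant fits (memory parameter a with equal weights,
# then the tactus weight w2 with a fixed at the participant mean), and
# the condition-mean model comparison of the serial (S), serial x
# metrical (S x M, equal weights), and weighted-tactus (S x M, w2 free)
# models by VAF and AIC.

suppressPackageStartupMessages({
  library(rangeplan)
  library(dplyr)
})

cohort <- readRDS("results/cohort.rds")
records <- read.delim("results/error_records.tsv")

message("Summarizing conditions ...")
summaries <- condition_summaries(cohort, records)

message("Two-step fits per participant x condition ...")
fits <- fit_cohort(summaries)
write_table_tsv(fits, "results/individual_fits.tsv")
message(sprintf(
  "%d of %d participant-conditions fitted; mean VAF %.2f; %.0f%% significant.",
  nrow(fits), nrow(summaries), mean(fits$vaf), 100 * mean(fits$significant)))
message(sprintf("Mean fitted w2: long %.2f, short %.2f.",
                mean(fits$w2_hat[fits$context == "long"]),
                mean(fits$w2_hat[fits$context == "short"])))

message("Condition-mean model comparison ...")
cmp <- compare_models_by_condition(cohort, records)
write_table_tsv(cmp, "results/model_comparison.tsv")
print(as.data.frame(cmp[, c("context", "tempo", "model_tag", "vaf", "aic",
                            "best")]), digits = 3)
best <- cmp[cmp$best, ]
message("Best model per condition: ",
        paste(best$context, best$tempo, "->", best$model_tag,
              collapse = "; "))
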