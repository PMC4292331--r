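#!/usr/bin/env Rscript

# Step 3: context effects on planning.
#
# Movement gradients by context, mean range of planning, the share of
# metrically similar errors, accent-conditioned error rates with the
# linear contrast, and keystroke-intensity summaries.

suppressPackageStartupMessages({
  library(rangeplan)
  library(dplyr)
  library(tidyr)
})

cohort <- readRDS("results/cohort.rds")
records <- read.delim("results/error_records.tsv")
n_trials <- nrow(cohort$design)

grad <- lapply(c(long = "long", short = "short"), function(ctx)
  movement_gradient(records[records$context == ctx, ]))
grad_tab <- bind_rows(lapply(names(grad), function(ctx)
  tibble::tibble(context = ctx, distance = 1:8,
                 proportion = as.numeric(grad[[ctx]]),
                 n_errors = attr(grad[[ctx]], "n_errors"))))
write_table_tsv(grad_tab, "results/movement_gradients.tsv")

ctx_tab <- bind_rows(lapply(c("long", "short"), function(ctx) {
  r <- records[records$context == ctx, ]
  tibble::tibble(context = ctx,
                 mean_range = mean_range(r),
                 similar_prop = similar_proportion(r),
                 anticipatory_prop = anticipatory_proportion(r))
}))
write_table_tsv(ctx_tab, "results/context_effects.tsv")
message("Context effects (long vs short):")
print(as.data.frame(ctx_tab), digits = 3)

# accent-conditioned error rates per context, opportunity-adjusted
sc <- cohort$stimuli[[1]]$long
rate_tab <- bind_rows(lapply(c("long", "short"), function(ctx) {
  r <- records[records$context == ctx, ]
  n_t <- sum(cohort$design$context == ctx)
  out <- error_rates_by_accent(r, sc, n_trials = n_t)
  out$context <- ctx
  out
}))
write_table_tsv(rate_tab, "results/error_rates_by_accent.tsv")
contrasts <- rate_tab |>
  group_by(context) |>
  summarise(contrast = accent_contrast(rate), .groups = "drop")
write_table_tsv(contrasts, "results/accent_contrasts.tsv")
message("Accent contrasts (negative = fewer errors at stronger accents):")
print(as.data.frame(contrasts), digits = 3)

# intensity summaries on a systematic subsample of trials
idx <- seq(1, n_trials, by = 4)
als <- lapply(idx, function(r) {
  d <- cohort$design[r, ]
  align_performance(cohort$stimuli[[d$stimulus_id]][[d$context]],
                    cohort$trials[[r]]$performance)
})
write_table_tsv(intensity_by_accent(als), "results/intensity_by_accent.tsv")
write_table_tsv(intensity_by_hand(als), "results/intensity_by_hand.tsv")
message("Intensity by accent level:")
print(as.data.frame(intensity_by_accent(als)), digits = 4)
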