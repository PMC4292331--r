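#' Contextual records usable for distance analyses
#'
#' @param records Error records.
#' @param window Maximum absolute source distance.
#' @param excerpt_only Restrict to errors on excerpt positions.
#' @return Filtered records.
#' @keywords internal
.gradient_records <- function(records, window = 8L, excerpt_only = TRUE) {
  keep <- records$contextual & !records$excluded &
    !is.na(records$signed_source_distance) &
    abs(records$signed_source_distance) <= window
  if (excerpt_only) keep <- keep & records$in_excerpt
  records[keep, ]
}

#' Observed movement gradient
#'
#' The distribution of contextual-error proportions over absolute source
#' distances 1..window, computed from coded error records (excluded
#' records never contribute). With zero qualifying errors the gradient
#' is undefined: proportions are NA and `n_errors` is 0, which
#' [is_defined_gradient()] reports.
#'
#' @param records Error records from [classify_errors()].
#' @param window Maximum absolute distance (default 8).
#' @param excerpt_only Restrict to excerpt errors (default TRUE, the
#'   analyses' convention).
#' @return A `movement_gradient`.
#' @export
movement_gradient <- function(records, window = 8L, excerpt_only = TRUE) {
  g <- .gradient_records(records, window, excerpt_only)
  n <- nrow(g)
  if (n == 0) {
    return(new_movement_gradient(rep(NA_real_, window), n_errors = 0L,
                                 window = window, source = "observed"))
  }
  counts <- tabulate(abs(g$signed_source_distance), nbins = window)
  new_movement_gradient(counts / n, n_errors = n, window = window,
                        source = "observed")
}

#' Mean range of planning
#'
#' The mean absolute distance between contextual errors and their
#' sources within the window; larger values indicate that more of the
#' sequence was simultaneously active during planning.
#'
#' @inheritParams movement_gradient
#' @return Mean absolute source distance in events (NA with no
#'   qualifying errors).
#' @export
mean_range <- function(records, window = 8L, excerpt_only = TRUE) {
  g <- .gradient_records(records, window, excerpt_only)
  if (!nrow(g)) return(NA_real_)
  mean(abs(g$signed_source_distance))
}

#' Proportion of metrically similar errors
#'
#' The share of contextual errors arising from even distances (2, 4, 6,
#' 8), the metrically similar positions of a strictly binary meter.
#'
#' @inheritParams movement_gradient
#' @return Fraction in [0, 1] (NA with no qualifying errors).
#' @export
similar_proportion <- function(records, window = 8L, excerpt_only = TRUE) {
  g <- .gradient_records(records, window, excerpt_only)
  if (!nrow(g)) return(NA_real_)
  mean(abs(g$signed_source_distance) %% 2 == 0)
}

#' Proportion of anticipatory errors
#'
#' @inheritParams movement_gradient
#' @return Fraction of contextual errors whose source lies ahead of the
#'   error position.
#' @export
anticipatory_proportion <- function(records, window = 8L, excerpt_only = TRUE) {
  g <- .gradient_records(records, window, excerpt_only)
  if (!nrow(g)) return(NA_real_)
  mean(g$signed_source_distance > 0)
}

#' Error rates by metrical accent strength
#'
#' Error rates per accent level, adjusted for the number of opportunities
#' for an error to receive each accent strength: in each 8-event excerpt
#' per hand, four events carry accent strength 1, two carry 2, one
#' carries 3, and one carries 4. The rate at level L is the number of
#' (non-excluded) errors at level-L positions divided by opportunities
#' at L times the number of performances.
#'
#' @param records Error records (all error types).
#' @param score A `score` (provides the accent layout of the excerpt).
#' @param n_trials Number of performances the records pool over.
#' @param include_deletions Count deletions as errors (default TRUE; the
#'   alternative tally is obtained with FALSE).
#' @return A tibble with `accent`, `opportunities`, `n_errors`, `rate`.
#' @export
error_rates_by_accent <- function(records, score, n_trials,
                                  include_deletions = TRUE) {
  stopifnot(inherits(score, "score"), n_trials >= 1)
  ex <- score$events[score$events$in_excerpt, ]
  opp <- table(factor(ex$accent_count, levels = 1:4))
  keep <- records$in_excerpt & !records$excluded
  if (!include_deletions) keep <- keep & records$error_type != "deletion"
  r <- records[keep, ]
  counts <- table(factor(r$accent_at_target, levels = 1:4))
  tibble::tibble(
    accent = 1:4,
    opportunities = as.integer(opp),
    n_errors = as.integer(counts),
    rate = ifelse(opp > 0, as.numeric(counts) / (as.numeric(opp) * n_trials),
                  NA_real_)
  )
}

#' Linear accent contrast of error rates
#'
#' Sums the products of per-accent-level error rates with mean-zero,
#' unit-spaced linear weights. Negative values indicate decreasing error
#' probability with increasing metrical accent strength.
#'
#' @param rates Numeric vector of rates for accent levels 1..4, or the
#'   tibble returned by [error_rates_by_accent()].
#' @param weights Contrast weights (default `c(-1.5, -0.5, 0.5, 1.5)`).
#' @return Scalar contrast value.
#' @export
accent_contrast <- function(rates, weights = c(-1.5, -0.5, 0.5, 1.5)) {
  if (is.data.frame(rates)) rates <- rates$rate
  stopifnot(length(rates) == length(weights),
            abs(sum(weights)) < 1e-12)
  sum(rates * weights)
}

#' Keystroke intensity by metrical accent strength
#'
#' Mean MIDI velocity of correctly produced tones per accent level,
#' from one or more alignments. Performers mark stronger metrical
#' accents with harder keystrokes, so these means increase with accent
#' level.
#'
#' @param alignments An `alignment` or list of alignments.
#' @param excerpt_only Restrict to excerpt positions (default TRUE).
#' @return A tibble with `accent`, `n`, `mean_velocity`.
#' @export
intensity_by_accent <- function(alignments, excerpt_only = TRUE) {
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  m <- dplyr::bind_rows(lapply(alignments, function(a) a$matches))
  m <- m[m$matched & m$correct & !m$is_final, ]
  if (excerpt_only) m <- m[m$in_excerpt, ]
  out <- dplyr::summarise(
    dplyr::group_by(m, accent = .data$accent_count),
    n = dplyr::n(),
    mean_velocity = mean(.data$velocity_correct),
    .groups = "drop")
  out
}

#' Mean keystroke intensity by hand
#'
#' @param alignments An `alignment` or list of alignments.
#' @return A tibble with `hand`, `n`, `mean_velocity` for correct tones.
#' @export
intensity_by_hand <- function(alignments) {
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  m <- dplyr::bind_rows(lapply(alignments, function(a) a$matches))
  m <- m[m$matched & m$correct & !m$is_final, ]
  dplyr::summarise(dplyr::group_by(m, hand = .data$hand),
                   n = dplyr::n(),
                   mean_velocity = mean(.data$velocity_correct),
                   .groups = "drop")
}

#' Per-trial error rate
#'
#' Errors per scored event in the analysis region. Both tallies of the
#' deletion question are available via `include_deletions`.
#'
#' @param records Error records of one or more trials.
#' @param n_events Number of scored events in the analysis region per
#'   trial (e.g. 16 for the two-hand excerpt).
#' @param n_trials Number of trials pooled over.
#' @param excerpt_only Restrict to excerpt errors.
#' @param include_deletions Count deletions (default TRUE).
#' @return Errors per event per trial.
#' @export
error_rate <- function(records, n_events, n_trials, excerpt_only = TRUE,
                       include_deletions = TRUE) {
  keep <- !records$excluded
  if (excerpt_only) keep <- keep & records$in_excerpt
  if (!include_deletions) keep <- keep & records$error_type != "deletion"
  sum(keep) / (n_events * n_trials)
}
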