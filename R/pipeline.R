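#' Per-condition summaries for a coded cohort
#'
#' Groups pooled error records by participant and condition (context x
#' tempo) and computes the distance summaries the model is fitted to:
#' the movement gradient, mean range of planning, metrically-similar
#' error proportion, and the mean produced IOI (the model's t).
#'
#' @param cohort A `cohort`.
#' @param records Pooled records from [code_cohort()].
#' @param window Source window (default 8).
#' @return A tibble keyed by `participant`, `context`, `tempo` with
#'   `n_contextual`, `mean_range`, `similar_prop`, `t_used` (s), and a
#'   `gradient` list-column.
#' @export
condition_summaries <- function(cohort, records, window = 8L) {
  des <- cohort$design
  t_trial <- vapply(cohort$trials, function(tr)
    mean_produced_ioi(tr$performance), numeric(1))
  des$t_ms <- t_trial
  combos <- unique(des[, c("participant", "context", "tempo")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    c0 <- combos[k, ]
    r <- records[records$participant == c0$participant &
                   records$context == c0$context &
                   records$tempo == c0$tempo, ]
    g <- movement_gradient(r, window = window)
    tibble::tibble(
      participant = c0$participant, context = c0$context, tempo = c0$tempo,
      n_contextual = attr(g, "n_errors"),
      mean_range = mean_range(r, window),
      similar_prop = similar_proportion(r, window),
      anticipatory_prop = anticipatory_proportion(r, window),
      t_used = mean(des$t_ms[des$participant == c0$participant &
                               des$context == c0$context &
                               des$tempo == c0$tempo]) / 1000,
      gradient = list(g))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$participant, .data$context,
                 .data$tempo)
}

#' Metrical grid of a context layout
#'
#' @param context "long" (33 isochronous events per hand) or "short"
#'   (17).
#' @return A `metrical_grid`.
#' @export
context_grid <- function(context = c("long", "short")) {
  context <- match.arg(context)
  metrical_grid(8L, 4L, if (context == "long") 33L else 17L)
}

#' Excerpt evaluation positions of a context layout (1-based)
#'
#' @param context "long" or "short".
#' @return Integer positions for model evaluation.
#' @export
context_excerpt_positions <- function(context = c("long", "short")) {
  context <- match.arg(context)
  if (context == "long") 13:20 else 5:12
}

#' Two-step model fits for every participant of a cohort
#'
#' Runs the published two-step procedure per participant over the four
#' context x tempo conditions: step 1 fits a (equal weights) to each
#' condition with errors and averages over the available conditions;
#' step 2 fits w2 with a fixed at that mean. Conditions without errors
#' are skipped.
#'
#' @param summaries Output of [condition_summaries()].
#' @return A tibble with one row per fitted participant x condition.
#' @export
fit_cohort <- function(summaries) {
  out <- lapply(split(summaries, summaries$participant), function(s) {
    conds <- paste(s$context, s$tempo, sep = "-")
    gradients <- stats::setNames(s$gradient, conds)
    grids <- stats::setNames(lapply(s$context, context_grid), conds)
    ts <- stats::setNames(s$t_used, conds)
    defined <- vapply(gradients, is_defined_gradient, logical(1))
    if (!any(defined)) return(NULL)
    step1 <- lapply(which(defined), function(k) {
      eq <- metrical_weights(4L, 2L, 0.25)
      fit_a(gradients[[k]], accent_profile(grids[[k]], eq), ts[[k]],
            positions = context_excerpt_positions(s$context[k]))
    })
    a_mean <- mean(vapply(step1, `[[`, numeric(1), "a_hat"))
    dplyr::bind_rows(lapply(seq_along(step1), function(j) {
      k <- which(defined)[j]
      fw <- fit_w2(gradients[[k]], grids[[k]], ts[[k]], a = a_mean,
                   positions = context_excerpt_positions(s$context[k]))
      tibble::tibble(
        participant = s$participant[k], context = s$context[k],
        tempo = s$tempo[k], n_contextual = s$n_contextual[k],
        t_used = ts[[k]], a_hat = step1[[j]]$a_hat, a_mean = a_mean,
        w2_hat = fw$w2_hat, vaf = fw$vaf, aic = fw$aic,
        significant = fw$significant)
    }))
  })
  dplyr::bind_rows(out)
}

#' Condition-mean model comparison table
#'
#' Pools records across participants per context x tempo condition and
#' compares the serial (S), serial x metrical with equal weights
#' (S x M), and tactus-weighted (S x M, w2 free) models on the mean
#' movement gradients, like-for-like in free parameters for the first
#' two.
#'
#' @param cohort A `cohort`.
#' @param records Pooled records from [code_cohort()].
#' @param window Source window.
#' @return A tibble with one row per condition x model.
#' @export
compare_models_by_condition <- function(cohort, records, window = 8L) {
  des <- cohort$design
  t_trial <- vapply(cohort$trials, function(tr)
    mean_produced_ioi(tr$performance), numeric(1))
  combos <- unique(des[, c("context", "tempo")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    c0 <- combos[k, ]
    r <- records[records$context == c0$context & records$tempo == c0$tempo, ]
    g <- movement_gradient(r, window = window)
    if (!is_defined_gradient(g)) return(NULL)
    t_used <- mean(t_trial[des$context == c0$context &
                             des$tempo == c0$tempo]) / 1000
    cmp <- compare_models(g, context_grid(c0$context), t_used,
                          positions = context_excerpt_positions(c0$context))
    cmp$context <- c0$context
    cmp$tempo <- c0$tempo
    cmp$n_errors <- attr(g, "n_errors")
    cmp
  })
  dplyr::bind_rows(rows)
}
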