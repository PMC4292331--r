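#' Monte-Carlo chance movement gradient
#'
#' Estimates the movement gradient a meter-blind random process would
#' produce for a stimulus: in each simulation every excerpt event errs
#' with probability `p_error`; the intruding pitch is drawn from the
#' multiset of all stimulus pitches (so frequent pitches are
#' proportionally likely intruders; set `multiset = FALSE` to draw from
#' the set of distinct pitches); the distance to the nearest
#' octave-specific same pitch in that hand is recorded, and draws with
#' no source within the window -- or that happen to reproduce the
#' intended pitch -- are dropped, mirroring the observed-gradient
#' coding. Per-simulation gradients are averaged.
#'
#' @param score A `score`.
#' @param p_error Per-event error probability (default 0.10, the
#'   observed per-trial rate).
#' @param n_sims Number of simulations (default 1000).
#' @param seed RNG seed.
#' @param window Maximum absolute source distance (default 8).
#' @param multiset Sample intruders from the pitch multiset (default
#'   TRUE) or the distinct pitch set.
#' @return A list of class `chance_gradient`: `gradient` (a
#'   `movement_gradient` with source "chance"), `bin_se` (Monte-Carlo
#'   standard error per bin), `n_sims`, `p_error`, `seed`.
#' @export
simulate_chance <- function(score, p_error = 0.10, n_sims = 1000L,
                            seed = 1L, window = 8L, multiset = TRUE) {
  stopifnot(inherits(score, "score"), p_error > 0, p_error <= 1, n_sims >= 1)
  set.seed(seed)
  pool <- stimulus_pitches(score)
  if (!multiset) pool <- unique(pool)
  hp <- lapply(c(R = "R", L = "L"), function(h)
    score_pitches(score, h, include_final = TRUE))
  ex <- excerpt_positions(score, base = 1L)
  slots <- expand.grid(hand = c("R", "L"), i = ex, stringsAsFactors = FALSE)
  sims <- matrix(NA_real_, nrow = n_sims, ncol = window)
  for (s in seq_len(n_sims)) {
    err <- which(stats::runif(nrow(slots)) < p_error)
    if (!length(err)) next
    d <- integer(0)
    for (k in err) {
      h <- slots$hand[k]; i <- slots$i[k]
      intruder <- pool[sample.int(length(pool), 1L)]
      if (intruder == hp[[h]][i]) next          # not an error
      src <- .nearest_source(intruder, hp[[h]], i, window)
      if (!is.na(src$distance)) d <- c(d, abs(src$distance))
    }
    if (length(d)) sims[s, ] <- tabulate(d, nbins = window) / length(d)
  }
  ok <- stats::complete.cases(sims)
  props <- colMeans(sims[ok, , drop = FALSE])
  props <- props / sum(props)
  se <- apply(sims[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
  structure(list(
    gradient = new_movement_gradient(props, n_errors = NA_integer_,
                                     window = window, source = "chance"),
    bin_se = se, n_sims = as.integer(n_sims), n_used = sum(ok),
    p_error = p_error, seed = seed), class = "chance_gradient")
}

#' @export
print.chance_gradient <- function(x, ...) {
  cat("Chance gradient:", x$n_used, "of", x$n_sims,
      "simulations with >= 1 codable error, p_error =", x$p_error, "\n")
  print(x$gradient)
  invisible(x)
}

#' Meter-alternation statistic of a gradient
#'
#' Measures the even/odd alternation a metrical similarity component
#' imprints on a movement gradient: the difference between the mean of
#' the even-distance bins (2, 4, 6, 8) and the mean of the odd bins
#' (1, 3, 5, 7), computed on residuals from an ordinary least-squares
#' line over distance. The detrending removes the overall decrease with
#' distance (which a random process also shows) so the statistic
#' isolates alternation: near zero for meter-blind gradients, positive
#' when metrically similar distances are elevated.
#'
#' @param gradient A `movement_gradient` (or numeric vector).
#' @return Scalar alternation statistic (proportion units).
#' @export
meter_alternation <- function(gradient) {
  g <- as.numeric(gradient)
  d <- seq_along(g)
  res <- stats::residuals(stats::lm(g ~ d))
  mean(res[d %% 2 == 0]) - mean(res[d %% 2 == 1])
}

#' Analytic chance rates for intrusion outcomes
#'
#' For uniform random intrusions over the chromatic set: an in-key
#' outcome has chance 7/12 (7 scale tones of 12), an in-chord outcome
#' 3/12 (3 triad tones), and either hand 1/2.
#'
#' @param key A `key_spec` (validated to carry 7 scale tones).
#' @return Named numeric vector `in_key`, `in_chord`, `hand`.
#' @export
chance_memberships <- function(key) {
  stopifnot(inherits(key, "key_spec"))
  n_scale <- length(scale_pitch_classes(key))
  n_triad <- length(triad_pitch_classes(key))
  if (n_scale != 7L) stop("malformed key: expected 7 scale tones", call. = FALSE)
  if (n_triad != 3L) stop("malformed triad: expected 3 tones", call. = FALSE)
  c(in_key = n_scale / 12, in_chord = n_triad / 12, hand = 0.5)
}
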