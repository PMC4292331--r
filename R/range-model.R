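#' Range model parameter set
#'
#' Bundles the free and fixed parameters of the range model: the memory
#' parameter `a` (dimensionless; larger values mean weaker working-memory
#' constraints and slower decay of contextual activation with distance),
#' the event duration `t` in seconds (the produced interonset interval),
#' the metrical level weights, the source window `W` in events, and the
#' activation scale `B` applied to the absolute activation of the current
#' event.
#'
#' @param a Memory parameter, 0.8 < a <= 1.0.
#' @param t Event duration (IOI) in seconds, 0.1 < t <= 2.0.
#' @param weights A `metrical_weights` object (default: 4 equally weighted
#'   levels).
#' @param window Maximum absolute source distance in events (default 8,
#'   one full metrical cycle of the 4-tier sixteenth-note grid).
#' @param B Non-negative output scale on the absolute activation
#'   (default 1; it never affects normalized gradients).
#' @return An object of class `range_params`.
#' @export
range_params <- function(a = 0.85, t = 0.225,
                         weights = metrical_weights(4L),
                         window = 8L, B = 1) {
  if (!(a > 0.8 && a <= 1.0)) {
    stop("a must satisfy 0.8 < a <= 1.0, got ", a, call. = FALSE)
  }
  if (!(t > 0.1 && t <= 2.0)) {
    stop("t must satisfy 0.1 < t <= 2.0 (seconds), got ", t, call. = FALSE)
  }
  stopifnot(window >= 1, B >= 0, inherits(weights, "metrical_weights"))
  structure(list(a = a, t = t, weights = weights,
                 window = as.integer(window), B = B),
            class = "range_params")
}

#' Serial proximity activation
#'
#' The serial component of the range model: the activation contributed by
#' a contextual event at signed distance `x` events from the current
#' event, `S_x = a^(|x| / t)`. Activation decays geometrically with
#' distance, faster at fast tempi (small `t`) or under stronger memory
#' constraints (small `a`); it is symmetric in +/- x and equals 1 at
#' x = 0.
#'
#' @param x Integer event distance(s); may be signed.
#' @param a Memory parameter, 0.8 < a <= 1.0.
#' @param t Event duration in seconds, 0.1 < t <= 2.0.
#' @return Numeric activation(s) in (0, 1].
#' @examples
#' serial_activation(1, 0.85, 0.225)  # ~0.4856
#' @export
serial_activation <- function(x, a, t) {
  if (!(all(a > 0.8) && all(a <= 1.0))) {
    stop("a must satisfy 0.8 < a <= 1.0", call. = FALSE)
  }
  if (!(all(t > 0.1) && all(t <= 2.0))) {
    stop("t must satisfy 0.1 < t <= 2.0 (seconds)", call. = FALSE)
  }
  a^(abs(x) / t)
}

#' Metrical similarity of two accent strengths
#'
#' The metrical component of the range model: a Weber-law similarity
#' between the accent strength of the current event and that of a
#' contextual event, `M = 1 - |m_i - m_j| / (m_i + m_j)`. It is 1 iff the
#' accents are equal and decreases as their difference grows relative to
#' their sum.
#'
#' @param m_current,m_other Positive accent strengths (vectors recycle).
#' @return Similarity value(s) in (0, 1].
#' @examples
#' metrical_similarity(1.0, 0.25)  # 0.4
#' @export
metrical_similarity <- function(m_current, m_other) {
  if (any(m_current <= 0) || any(m_other <= 0)) {
    stop("accent strengths must be positive", call. = FALSE)
  }
  1 - abs(m_current - m_other) / (m_current + m_other)
}

#' Contextual activation field around one position
#'
#' Computes, for the current event at position `i`, the activation of
#' every contextual event within the signed window: the product of the
#' serial proximity component and the metrical similarity component,
#' `S_x * M_x(i)`. Positions beyond the sequence edges contribute
#' nothing (no phantom events).
#'
#' @param profile An `accent_profile` for the sequence.
#' @param i Current position (1-based), within the sequence.
#' @param params A `range_params`.
#' @return A data.frame with columns `x` (signed distance), `s`, `m`,
#'   `activation` for every in-sequence distance in `[-W, W] \ {0}`.
#' @export
contextual_activations <- function(profile, i, params) {
  stopifnot(inherits(profile, "accent_profile"), inherits(params, "range_params"))
  n <- profile$n_positions
  if (i < 1 || i > n) stop("position i = ", i, " outside 1..", n, call. = FALSE)
  x <- setdiff(seq(-params$window, params$window), 0L)
  x <- x[i + x >= 1 & i + x <= n]
  s <- serial_activation(x, params$a, params$t)
  m <- metrical_similarity(profile$strengths[i], profile$strengths[i + x])
  data.frame(x = x, s = s, m = m, activation = s * m)
}

#' Absolute activation of the current event
#'
#' The extended range model's absolute activation: the current event's
#' activation grows with the squared sum of its contextual events'
#' activations, `Event(0) = B * (sum_{x != 0} S_x M_x)^2`. An event with
#' no context has activation 0. Longer contexts and slower production
#' rates both increase it.
#'
#' @param profile An `accent_profile`.
#' @param positions 1-based positions to evaluate (default: all).
#' @param params A `range_params`.
#' @return Numeric vector of activations, one per position.
#' @export
event_activation <- function(profile, positions = seq_len(profile$n_positions),
                             params) {
  stopifnot(inherits(profile, "accent_profile"), inherits(params, "range_params"))
  vapply(positions, function(i) {
    act <- contextual_activations(profile, i, params)$activation
    params$B * sum(act)^2
  }, numeric(1))
}

#' Construct a movement gradient object
#'
#' A movement gradient is the distribution of contextual-error
#' proportions over absolute source distances `1..window`. Observed
#' gradients carry the number of errors they are based on; model and
#' chance gradients carry `n_errors = NA` and a `source` marker.
#'
#' @param proportions Numeric vector of length `window`; must sum to 1
#'   when defined.
#' @param n_errors Number of contextual errors the proportions summarize
#'   (NA for model/chance gradients).
#' @param window Maximum absolute distance (default 8).
#' @param source One of "observed", "model", "chance".
#' @return An object of class `movement_gradient` (a numeric vector with
#'   attributes).
#' @export
new_movement_gradient <- function(proportions, n_errors = NA_integer_,
                                  window = 8L, source = "observed") {
  stopifnot(length(proportions) == window)
  if (!anyNA(proportions)) {
    if (any(proportions < 0)) stop("gradient proportions must be non-negative")
    if (abs(sum(proportions) - 1) > 1e-9) {
      stop("gradient proportions must sum to 1", call. = FALSE)
    }
  }
  structure(as.numeric(proportions),
            n_errors = n_errors, window = as.integer(window),
            source = source, names = as.character(seq_len(window)),
            class = "movement_gradient")
}

#' @export
print.movement_gradient <- function(x, ...) {
  cat("Movement gradient (", attr(x, "source"), "), distances 1..",
      attr(x, "window"), sep = "")
  if (!is.na(attr(x, "n_errors"))) cat(", n =", attr(x, "n_errors"))
  cat("\n")
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}

#' Is a movement gradient defined?
#'
#' An observed gradient is undefined (all-NA proportions) when no
#' contextual error with an identified source contributed to it.
#'
#' @param gradient A `movement_gradient`.
#' @return Logical.
#' @export
is_defined_gradient <- function(gradient) {
  inherits(gradient, "movement_gradient") && !anyNA(unclass(gradient))
}

#' Model-predicted movement gradient
#'
#' Folds the contextual activation field `S_x * M_x(i)` into absolute
#' distance bins (summing the two signed distances of each bin), averages
#' across the evaluation positions, and normalizes the bins to sum to 1.
#' This is the model's conditional probability that an error arises from
#' a source at each absolute distance, given that an error occurred.
#'
#' With `meter = FALSE` the metrical component is dropped (M = 1
#' everywhere), giving the serial-only model's gradient.
#'
#' @param profile An `accent_profile`.
#' @param params A `range_params`.
#' @param positions 1-based evaluation positions (default: all; for
#'   stimulus-level predictions pass the excerpt positions).
#' @param meter Include the metrical similarity component? Default TRUE.
#' @param exclude_clipped Drop positions whose +/- window crosses a
#'   sequence boundary before averaging? Default FALSE (clipped positions
#'   contribute their existing pairs).
#' @return A `movement_gradient` with `source = "model"`.
#' @export
predicted_gradient <- function(profile, params,
                               positions = seq_len(profile$n_positions),
                               meter = TRUE, exclude_clipped = FALSE) {
  stopifnot(inherits(profile, "accent_profile"), inherits(params, "range_params"))
  n <- profile$n_positions
  W <- params$window
  if (any(positions < 1 | positions > n)) {
    stop("evaluation positions must lie inside the sequence", call. = FALSE)
  }
  if (exclude_clipped) {
    positions <- positions[positions - W >= 1 & positions + W <= n]
    if (!length(positions)) {
      stop("no evaluation positions with an unclipped window", call. = FALSE)
    }
  }
  avg <- .gradient_kernel(profile$strengths, positions, params$a, params$t,
                          W, meter)
  tot <- sum(avg)
  if (tot <= 0) stop("degenerate gradient: all activations zero", call. = FALSE)
  new_movement_gradient(avg / tot, n_errors = NA_integer_, window = W,
                        source = "model")
}

# Vectorized S_x * M_x folding for the fitting inner loop: per-bin mean
# over positions of the summed signed-distance activations.
.gradient_kernel <- function(m, positions, a, t, W, meter) {
  n <- length(m)
  bins <- numeric(W)
  np <- length(positions)
  for (x in seq_len(W)) {
    s <- a^(x / t)
    for (sgn in c(-1L, 1L)) {
      j <- positions + sgn * x
      ok <- j >= 1 & j <= n
      if (!any(ok)) next
      if (meter) {
        mi <- m[positions[ok]]
        mj <- m[j[ok]]
        bins[x] <- bins[x] + s * sum(1 - abs(mi - mj) / (mi + mj))
      } else {
        bins[x] <- bins[x] + s * sum(ok)
      }
    }
  }
  bins / np
}

#' Sample an observed gradient from the model
#'
#' Draws `n_errors` contextual-error source distances from the model's
#' predicted gradient (a multinomial draw over the absolute distance
#' bins) and returns the resulting empirical gradient. This is the
#' Monte-Carlo harness used for parameter-recovery studies of the
#' fitting procedure.
#'
#' @param profile An `accent_profile`.
#' @param params A `range_params` (the generating truth).
#' @param n_errors Number of errors to draw.
#' @param positions Evaluation positions passed to [predicted_gradient()].
#' @param meter Include the metrical component in the generating model?
#' @return A `movement_gradient` with `source = "observed"`.
#' @export
sample_gradient <- function(profile, params, n_errors,
                            positions = seq_len(profile$n_positions),
                            meter = TRUE) {
  p <- predicted_gradient(profile, params, positions, meter = meter)
  counts <- as.numeric(stats::rmultinom(1, size = n_errors, prob = unclass(p)))
  new_movement_gradient(counts / n_errors, n_errors = as.integer(n_errors),
                        window = params$window, source = "observed")
}
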