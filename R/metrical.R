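#' Build a binary metrical accent grid
#'
#' Constructs the nested accent-presence matrix of a binary metrical
#' hierarchy over an isochronous sequence of positions. Level 1 is the
#' lowest (sixteenth-note) level and is present at every position; each
#' higher level doubles the period, so a grid with `n_levels = 4` and
#' `meter_cycle = 8` reproduces the familiar 4/4 grid of Xs in which the
#' per-cycle accent counts run 4, 1, 2, 1, 3, 1, 2, 1.
#'
#' Only strictly binary (power-of-two) hierarchies are supported; ternary
#' and mixed meters are rejected. The grid may be phase-shifted with
#' `offset` for sequences whose first sounded event does not fall on the
#' strongest accent.
#'
#' @param meter_cycle Positions per full metrical cycle; must equal
#'   `2^(n_levels - 1)`.
#' @param n_levels Number of hierarchy tiers (k).
#' @param n_positions Number of sequence positions to cover.
#' @param tactus_level Index of the tactus (beat) level, in `1..n_levels`.
#' @param offset Integer phase offset in positions (0 = first event on the
#'   strongest accent).
#' @return An object of class `metrical_grid`: a list with `n_levels`,
#'   `periods`, `presence` (a `n_levels` x `n_positions` 0/1 matrix),
#'   `accent_counts`, `tactus_level`, `cycle_length`, `n_positions`,
#'   `offset`.
#' @examples
#' g <- metrical_grid(8, 4, 8)
#' g$accent_counts  # 4 1 2 1 3 1 2 1
#' @export
metrical_grid <- function(meter_cycle, n_levels, n_positions,
                          tactus_level = 2L, offset = 0L) {
  stopifnot(n_levels >= 1, n_positions >= 1)
  if (n_levels > 1 && tactus_level > n_levels) {
    stop("tactus_level must lie in 1..n_levels", call. = FALSE)
  }
  periods <- 2L^(seq_len(n_levels) - 1L)
  if (meter_cycle != periods[n_levels]) {
    stop("unsupported meter: cycle length ", meter_cycle,
         " is not the binary hierarchy 2^(n_levels - 1) = ",
         periods[n_levels], call. = FALSE)
  }
  pos <- seq_len(n_positions) - 1L          # 0-based internally
  presence <- vapply(periods, function(p) as.integer((pos + offset) %% p == 0L),
                     integer(n_positions))
  presence <- t(presence)                   # levels x positions
  structure(
    list(
      n_levels      = as.integer(n_levels),
      periods       = periods,
      presence      = presence,
      accent_counts = as.integer(colSums(presence)),
      tactus_level  = as.integer(tactus_level),
      cycle_length  = as.integer(meter_cycle),
      n_positions   = as.integer(n_positions),
      offset        = as.integer(offset)
    ),
    class = "metrical_grid"
  )
}

#' Metrical level weights with a highlighted tactus
#'
#' Builds the per-level weight vector w_j. The tactus level carries
#' `tactus_weight`; the remaining levels share the complement equally,
#' `(1 - tactus_weight) / (n_levels - 1)`, so the weights always sum to 1.
#'
#' @param n_levels Number of hierarchy levels (k).
#' @param tactus_level Which level is the tactus (default 2, the
#'   eighth-note level in the 4-tier sixteenth-note grid).
#' @param tactus_weight Weight on the tactus level, in `[0.25, 0.99]`.
#'   0.25 with 4 levels gives equal weighting.
#' @return An object of class `metrical_weights`: list with `weights`,
#'   `tactus_level`, `tactus_weight`, `n_levels`.
#' @examples
#' metrical_weights(4, 2, 0.25)$weights  # all 0.25
#' @export
metrical_weights <- function(n_levels, tactus_level = 2L, tactus_weight = 0.25) {
  stopifnot(n_levels >= 1, tactus_level >= 1, tactus_level <= n_levels)
  if (tactus_weight < 0.25 || tactus_weight > 0.99) {
    stop("tactus_weight must lie in [0.25, 0.99], got ", tactus_weight,
         call. = FALSE)
  }
  if (n_levels == 1L) {
    w <- 1
  } else {
    w <- rep((1 - tactus_weight) / (n_levels - 1L), n_levels)
    w[tactus_level] <- tactus_weight
  }
  structure(
    list(
      weights       = w,
      tactus_level  = as.integer(tactus_level),
      tactus_weight = tactus_weight,
      n_levels      = as.integer(n_levels)
    ),
    class = "metrical_weights"
  )
}

#' Per-position metrical accent strengths
#'
#' Computes the accent strength of every position as the weight-weighted
#' sum of accent presences across levels, m_i = sum_j w_j g_ji. With
#' equal weights the strengths are proportional to the number of Xs above
#' each position; the strongest position (all levels present) always has
#' m = 1 because the weights sum to 1.
#'
#' @param grid A `metrical_grid`.
#' @param weights A `metrical_weights` with the same number of levels.
#' @return An object of class `accent_profile`: list with `strengths`
#'   (m_i), `accent_counts`, `cycle_length`, `n_positions`, plus the grid
#'   and weights used.
#' @examples
#' g <- metrical_grid(8, 4, 8)
#' accent_profile(g, metrical_weights(4))$strengths
#' @export
accent_profile <- function(grid, weights) {
  stopifnot(inherits(grid, "metrical_grid"), inherits(weights, "metrical_weights"))
  if (weights$n_levels != grid$n_levels) {
    stop("weights have ", weights$n_levels, " levels but grid has ",
         grid$n_levels, call. = FALSE)
  }
  m <- as.numeric(crossprod(grid$presence, weights$weights))
  structure(
    list(
      strengths     = m,
      accent_counts = grid$accent_counts,
      cycle_length  = grid$cycle_length,
      n_positions   = grid$n_positions,
      grid          = grid,
      weights       = weights
    ),
    class = "accent_profile"
  )
}

#' @export
print.metrical_grid <- function(x, ...) {
  cat("Binary metrical grid:", x$n_levels, "levels, cycle", x$cycle_length,
      ",", x$n_positions, "positions (tactus level", x$tactus_level, ")\n")
  n_show <- min(x$n_positions, x$cycle_length)
  cat("accent counts (first cycle):",
      paste(x$accent_counts[seq_len(n_show)], collapse = " "), "\n")
  invisible(x)
}

#' @export
print.metrical_weights <- function(x, ...) {
  cat("Metrical weights (tactus level ", x$tactus_level, " = ",
      format(x$tactus_weight), "): ",
      paste(format(x$weights, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.accent_profile <- function(x, ...) {
  n_show <- min(x$n_positions, x$cycle_length)
  cat("Accent profile over", x$n_positions, "positions; first cycle m_i:\n")
  print(round(x$strengths[seq_len(n_show)], 4))
  invisible(x)
}

#' Export an accent profile as a table
#'
#' @param profile An `accent_profile`.
#' @return A tibble with `position` (1-based), `accent_count`, `m`.
#' @export
accent_profile_table <- function(profile) {
  stopifnot(inherits(profile, "accent_profile"))
  tibble::tibble(
    position     = seq_len(profile$n_positions),
    accent_count = profile$accent_counts,
    m            = profile$strengths
  )
}
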