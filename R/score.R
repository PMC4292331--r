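#' Musical key helpers
#'
#' A key is a list with `tonic` (note name, e.g. "C", "F#", "Bb") and
#' `mode` ("major" or "minor"; minor keys use the harmonic minor scale).
#'
#' @param tonic Note name of the tonic.
#' @param mode "major" or "minor".
#' @return A list of class `key_spec`.
#' @export
key_spec <- function(tonic, mode = c("major", "minor")) {
  mode <- match.arg(mode)
  pc <- .pitch_class(tonic)
  structure(list(tonic = tonic, mode = mode, tonic_pc = pc), class = "key_spec")
}

.pitch_class <- function(name) {
  base <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  m <- regmatches(name, regexec("^([A-Ga-g])([#b]?)$", name))[[1]]
  if (length(m) == 0) stop("malformed note name: ", name, call. = FALSE)
  pc <- base[[toupper(m[2])]] + switch(m[3], "#" = 1L, "b" = -1L, 0L)
  pc %% 12L
}

#' Scale pitch classes of a key
#'
#' Major keys use the 7-tone major scale; minor keys the harmonic minor
#' scale. Under uniform chromatic intrusion the chance of an in-key
#' outcome is 7/12.
#'
#' @param key A `key_spec`.
#' @return Integer vector of 7 pitch classes (0-11).
#' @export
scale_pitch_classes <- function(key) {
  stopifnot(inherits(key, "key_spec"))
  steps <- if (key$mode == "major") c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
           else c(0L, 2L, 3L, 5L, 7L, 8L, 11L)  # harmonic minor
  sort((key$tonic_pc + steps) %% 12L)
}

#' Triad pitch classes of a key's tonic chord
#'
#' @param key A `key_spec`.
#' @return Integer vector of 3 pitch classes. Chance of an in-chord
#'   outcome under uniform chromatic intrusion is 3/12.
#' @export
triad_pitch_classes <- function(key) {
  stopifnot(inherits(key, "key_spec"))
  third <- if (key$mode == "major") 4L else 3L
  sort((key$tonic_pc + c(0L, third, 7L)) %% 12L)
}

#' Construct a score
#'
#' A score is the intended event sequence for one stimulus: two
#' isochronous per-hand voices of sixteenth-note events (plus a final
#' held note), with the binary metrical grid aligned to the first
#' sounded event, an excerpt mask marking the embedded 8-event excerpt,
#' and key/context metadata.
#'
#' @param events Data frame with columns `position` (0-based, per hand),
#'   `hand` ("R"/"L"), `pitch` (integer note number, middle C = 60),
#'   `onset_units` (sixteenths), `finger` (integer or NA),
#'   `in_excerpt` (logical), `is_final` (logical).
#' @param key A `key_spec`.
#' @param context "long" or "short".
#' @param stimulus_id Identifier for the excerpt/stimulus.
#' @param meter_cycle,n_levels,tactus_level,grid_offset Metrical grid
#'   parameters (defaults: the 4-tier, 8-position binary grid;
#'   `grid_offset` shifts the cycle for sequences not starting on the
#'   strongest accent).
#' @return An object of class `score`.
#' @export
new_score <- function(events, key, context = c("long", "short"),
                      stimulus_id = 1L, meter_cycle = 8L, n_levels = 4L,
                      tactus_level = 2L, grid_offset = 0L) {
  context <- match.arg(context)
  stopifnot(is.data.frame(events), inherits(key, "key_spec"))
  need <- c("position", "hand", "pitch", "onset_units", "in_excerpt", "is_final")
  if (!all(need %in% names(events))) {
    stop("score events need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"finger" %in% names(events)) events$finger <- NA_integer_
  events <- events[order(events$hand, events$position), ]
  n_iso <- max(events$position[!events$is_final]) + 1L
  for (h in unique(events$hand)) {
    p <- events$position[events$hand == h & !events$is_final]
    if (!identical(sort(p), seq.int(0L, n_iso - 1L))) {
      stop("positions must be consecutive from 0 in each hand", call. = FALSE)
    }
  }
  grid <- metrical_grid(meter_cycle, n_levels, n_iso,
                        tactus_level = tactus_level, offset = grid_offset)
  events$accent_count <- ifelse(events$is_final, NA_integer_,
                                grid$accent_counts[events$position + 1L])
  structure(
    list(events = tibble::as_tibble(events), key = key, context = context,
         stimulus_id = stimulus_id, n_positions = n_iso, grid = grid),
    class = "score"
  )
}

#' @export
print.score <- function(x, ...) {
  cat("Score: stimulus", x$stimulus_id, "|", x$context, "context |",
      x$n_positions, "sixteenth events per hand | key", x$key$tonic,
      x$key$mode, "\n")
  cat("excerpt positions (0-based):",
      paste(range(x$events$position[x$events$in_excerpt]), collapse = "-"), "\n")
  invisible(x)
}

#' Accent profile of a score's isochronous events
#'
#' @param score A `score`.
#' @param tactus_weight Weight on the tactus level (default 0.25, equal
#'   weighting of the 4 levels).
#' @return An `accent_profile` over the score's isochronous positions.
#' @export
score_profile <- function(score, tactus_weight = 0.25) {
  stopifnot(inherits(score, "score"))
  w <- metrical_weights(score$grid$n_levels, score$grid$tactus_level,
                        tactus_weight)
  accent_profile(score$grid, w)
}

#' Excerpt positions of a score
#'
#' @param score A `score`.
#' @param base 0 for the internal 0-based convention, 1 for profile
#'   indexing.
#' @return Integer vector of excerpt positions (identical in both hands).
#' @export
excerpt_positions <- function(score, base = 0L) {
  p <- sort(unique(score$events$position[score$events$in_excerpt]))
  p + as.integer(base)
}

#' Pitches of one hand of a score
#'
#' @param score A `score`.
#' @param hand "R" or "L".
#' @param include_final Include the final held note? Default TRUE (it is
#'   part of the stimulus and a legitimate error source).
#' @return Integer pitch vector ordered by position.
#' @export
score_pitches <- function(score, hand, include_final = TRUE) {
  ev <- score$events[score$events$hand == hand, ]
  if (!include_final) ev <- ev[!ev$is_final, ]
  ev$pitch[order(ev$position)]
}

#' Stimulus pitch multiset
#'
#' All pitches occurring anywhere in the stimulus (both hands), used to
#' decide whether an intruder is contextual and as the sampling multiset
#' of the chance simulation.
#'
#' @param score A `score`.
#' @return Integer vector (with repetitions).
#' @export
stimulus_pitches <- function(score) {
  score$events$pitch
}

#' Mean pitch-recurrence distance of a score
#'
#' For each event with an earlier occurrence of the same (octave-specific)
#' pitch in the same hand, the gap in events to that nearest earlier
#' occurrence; averaged over events and hands. The stimuli are composed
#' so this is about 6 events, with no immediate repetitions.
#'
#' @param score A `score`.
#' @return Mean recurrence distance (numeric scalar).
#' @export
mean_recurrence_distance <- function(score) {
  gaps <- unlist(lapply(c("R", "L"), function(h) {
    p <- score_pitches(score, h, include_final = FALSE)
    .recurrence_gaps(p)
  }))
  mean(gaps)
}

.recurrence_gaps <- function(pitches) {
  n <- length(pitches)
  gaps <- integer(0)
  for (i in seq_len(n)) {
    prev <- which(pitches[seq_len(i - 1L)] == pitches[i])
    if (length(prev)) gaps <- c(gaps, i - max(prev))
  }
  gaps
}
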