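#' Classify aligned errors into the full taxonomy
#'
#' Turns an alignment into one record per error. Substituted positions
#' whose intruding pitch occurs (octave-specifically) elsewhere in the
#' stimulus are contextual, coded with the signed distance to the
#' nearest same-pitch source within the window (smaller absolute
#' distance wins; an exact past/future tie prefers the anticipatory
#' source and is flagged). Two adjacent substitutions whose intruders
#' are each other's targets collapse into a single exchange. Intruding
#' pitches found nowhere in the stimulus are noncontextual additions;
#' unmatched score positions are deletions; clusters with more than one
#' wrong pitch are chord errors. An unmatched keystroke that is followed
#' within one nominal IOI by a correct keystroke serving the same
#' position is coded as a corrected error (flagged, to be excluded).
#'
#' @param alignment An `alignment` from [align_performance()].
#' @param score The `score` the trial was aligned to.
#' @param window Maximum absolute source distance (default 8 events).
#' @return A tibble of error records with trial metadata columns.
#' @export
classify_errors <- function(alignment, score, window = 8L) {
  stopifnot(inherits(alignment, "alignment"), inherits(score, "score"))
  meta <- alignment$meta
  stim_pitches <- stimulus_pitches(score)
  key <- score$key
  scale_pcs <- scale_pitch_classes(key)
  triad_pcs <- triad_pitch_classes(key)
  recs <- list()

  hand_pitches <- lapply(c(R = "R", L = "L"), function(h)
    score_pitches(score, h, include_final = TRUE))

  mk <- function(type, hand, position, target_pitch, intruder_pitch,
                 distance, tie, velocity, onset, accent_target, in_excerpt,
                 chord_size = 1L, corrected = FALSE, finger_match = NA) {
    contextual <- !is.na(intruder_pitch) && intruder_pitch %in% stim_pitches &&
      type != "deletion"
    accent_src <- NA_integer_
    if (!is.na(distance)) {
      src <- position + distance
      if (src >= 0 && src < score$n_positions) {
        accent_src <- score$grid$accent_counts[src + 1L]
      }
    }
    list(
      participant = meta$participant, stimulus_id = meta$stimulus_id,
      context = meta$context, tempo = meta$tempo, block = meta$block,
      rep = meta$rep, trial_index = meta$trial_index,
      error_type = type, hand = hand,
      target_position = as.integer(position),
      target_pitch = as.integer(target_pitch),
      intruder_pitch = as.integer(intruder_pitch),
      contextual = contextual,
      signed_source_distance = as.integer(distance),
      direction = if (is.na(distance)) "none"
                  else if (distance > 0) "anticipatory" else "perseveratory",
      source_tie = tie,
      accent_at_target = accent_target,
      accent_at_source = accent_src,
      velocity = velocity, onset_ms = onset,
      in_excerpt = in_excerpt, chord_size = chord_size,
      in_key = if (is.na(intruder_pitch)) NA else
        (intruder_pitch %% 12L) %in% scale_pcs,
      in_chord = if (is.na(intruder_pitch)) NA else
        (intruder_pitch %% 12L) %in% triad_pcs,
      semitone_distance = if (is.na(intruder_pitch) || is.na(target_pitch))
        NA_integer_ else abs(intruder_pitch - target_pitch),
      same_finger = finger_match,
      corrected = corrected,
      excluded = FALSE, exclusion_reason = NA_character_
    )
  }

  m <- alignment$matches
  # --- substituted positions -------------------------------------------
  subs <- which(m$matched & !m$correct)
  sub_info <- lapply(subs, function(i) {
    wrong <- m$wrong_pitches[[i]]
    vels <- m$wrong_velocities[[i]]
    hp <- hand_pitches[[m$hand[i]]]
    srcs <- lapply(wrong, .nearest_source, pitches = hp,
                   i = m$position[i] + 1L, window = window)
    dists <- vapply(srcs, function(s) if (is.na(s$distance)) Inf else
      abs(s$distance), numeric(1))
    pick <- if (any(is.finite(dists))) which.min(dists)
            else which.min(abs(wrong - m$score_pitch[i]))
    list(intruder = wrong[pick], velocity = vels[pick],
         distance = srcs[[pick]]$distance, tie = srcs[[pick]]$tie,
         chord_size = length(wrong))
  })
  names(sub_info) <- paste0(m$hand[subs], m$position[subs])

  # --- exchange collapse ------------------------------------------------
  consumed <- rep(FALSE, length(subs))
  for (k in seq_along(subs)) {
    if (consumed[k]) next
    i <- subs[k]
    k2 <- which(subs == i + 1L & m$hand[subs] == m$hand[i] &
                  !consumed)
    k2 <- k2[m$position[subs[k2]] == m$position[i] + 1L]
    if (length(k2) == 1L &&
        sub_info[[k]]$chord_size == 1L && sub_info[[k2]]$chord_size == 1L &&
        sub_info[[k]]$intruder == m$score_pitch[subs[k2]] &&
        sub_info[[k2]]$intruder == m$score_pitch[i]) {
      recs[[length(recs) + 1L]] <- mk(
        "exchange", m$hand[i], m$position[i], m$score_pitch[i],
        sub_info[[k]]$intruder, distance = 1L, tie = FALSE,
        velocity = sub_info[[k]]$velocity, onset = m$onset_ms[i],
        accent_target = m$accent_count[i], in_excerpt = m$in_excerpt[i])
      consumed[k] <- TRUE
      consumed[k2] <- TRUE
    }
  }
  for (k in seq_along(subs)) {
    if (consumed[k]) next
    i <- subs[k]
    info <- sub_info[[k]]
    type <- if (info$chord_size > 1L) "chord_error"
            else if (info$intruder %in% stim_pitches) "contextual_substitution"
            else "addition"
    recs[[length(recs) + 1L]] <- mk(
      type, m$hand[i], m$position[i], m$score_pitch[i], info$intruder,
      distance = info$distance, tie = info$tie, velocity = info$velocity,
      onset = m$onset_ms[i], accent_target = m$accent_count[i],
      in_excerpt = m$in_excerpt[i], chord_size = info$chord_size)
  }

  # --- deletions --------------------------------------------------------
  for (i in which(!m$matched)) {
    recs[[length(recs) + 1L]] <- mk(
      "deletion", m$hand[i], m$position[i], m$score_pitch[i],
      NA_integer_, distance = NA_integer_, tie = FALSE,
      velocity = NA_real_, onset = NA_real_,
      accent_target = m$accent_count[i], in_excerpt = m$in_excerpt[i])
  }

  # --- additions and corrections ---------------------------------------
  ioi <- meta$ioi_ms
  ad <- alignment$additions
  for (r in seq_len(nrow(ad))) {
    h <- ad$hand[r]
    onset <- ad$onset_ms[r]
    pitches <- ad$pitches[[r]]
    vels <- ad$velocities[[r]]
    mh <- m[m$hand == h & m$matched, ]
    # correction: a correct keystroke for some position follows this
    # stray keystroke within one nominal IOI, and the stray keystroke
    # sits in that position's nominal slot
    later <- which(mh$correct & mh$onset_ms > onset &
                     mh$onset_ms - onset <= ioi &
                     abs(onset - mh$nominal_onset) <= 0.75 * ioi)
    if (length(later)) {
      i <- later[which.min(mh$onset_ms[later])]
      hp <- hand_pitches[[h]]
      src <- .nearest_source(pitches[1], hp, mh$position[i] + 1L, window)
      type <- if (pitches[1] %in% stim_pitches) "contextual_substitution"
              else "addition"
      recs[[length(recs) + 1L]] <- mk(
        type, h, mh$position[i], mh$score_pitch[i], pitches[1],
        distance = src$distance, tie = src$tie, velocity = vels[1],
        onset = onset, accent_target = mh$accent_count[i],
        in_excerpt = mh$in_excerpt[i], chord_size = length(pitches),
        corrected = TRUE)
    } else {
      near <- which.min(abs(m$nominal_onset[m$hand == h] - onset))
      mn <- m[m$hand == h, ][near, ]
      recs[[length(recs) + 1L]] <- mk(
        "addition", h, mn$position, NA_integer_, pitches[1],
        distance = NA_integer_, tie = FALSE, velocity = vels[1],
        onset = onset, accent_target = mn$accent_count,
        in_excerpt = mn$in_excerpt, chord_size = length(pitches))
    }
  }

  if (!length(recs)) return(.empty_records())
  dplyr::bind_rows(recs)
}

.empty_records <- function() {
  tibble::tibble(
    participant = integer(), stimulus_id = integer(), context = character(),
    tempo = character(), block = integer(), rep = integer(),
    trial_index = integer(), error_type = character(), hand = character(),
    target_position = integer(), target_pitch = integer(),
    intruder_pitch = integer(), contextual = logical(),
    signed_source_distance = integer(), direction = character(),
    source_tie = logical(), accent_at_target = integer(),
    accent_at_source = integer(), velocity = numeric(), onset_ms = numeric(),
    in_excerpt = logical(), chord_size = integer(), in_key = logical(),
    in_chord = logical(), semitone_distance = integer(),
    same_finger = logical(), corrected = logical(), excluded = logical(),
    exclusion_reason = character())
}

# Nearest octave-specific occurrence of `pitch` around 1-based position i.
.nearest_source <- function(pitch, pitches, i, window) {
  n <- length(pitches)
  x <- setdiff(seq(-window, window), 0L)
  x <- x[i + x >= 1 & i + x <= n]
  hits <- x[pitches[i + x] == pitch]
  if (!length(hits)) return(list(distance = NA_integer_, tie = FALSE))
  d <- abs(hits)
  best <- hits[d == min(d)]
  tie <- length(best) > 1L
  list(distance = as.integer(if (tie) max(best) else best), tie = tie)
}

#' Apply the error exclusion filters
#'
#' Marks (never deletes) excluded records: corrected errors, and errors
#' at positions that already went wrong in the learning phase and keep
#' going wrong in at least half of the test performances of the same
#' stimulus (learned-error rule). The learned-error rule needs
#' learning-phase records; without them it is skipped with a warning.
#'
#' @param records Error records across the test performances (all trials
#'   of at least one participant-stimulus pairing).
#' @param learning_records Optional error records from the learning
#'   phase (columns `participant`, `stimulus_id`, `target_position`,
#'   `hand`).
#' @param n_test Number of test performances per stimulus (default 8).
#' @return `records` with `excluded` and `exclusion_reason` filled in.
#' @export
apply_exclusions <- function(records, learning_records = NULL, n_test = 8L) {
  if (!nrow(records)) return(records)
  records$excluded <- records$corrected
  records$exclusion_reason <- ifelse(records$corrected, "corrected",
                                     NA_character_)
  if (is.null(learning_records)) {
    warning("learning-phase records missing; learned-error exclusion skipped",
            call. = FALSE)
    return(records)
  }
  key <- function(d) paste(d$participant, d$stimulus_id, d$hand,
                           d$target_position)
  lkeys <- unique(key(learning_records))
  rk <- key(records)
  for (k in intersect(lkeys, unique(rk))) {
    idx <- which(rk == k)
    n_trials_err <- length(unique(records$trial_index[idx]))
    if (n_trials_err >= n_test / 2) {
      records$excluded[idx] <- TRUE
      records$exclusion_reason[idx] <-
        ifelse(is.na(records$exclusion_reason[idx]), "learned",
               records$exclusion_reason[idx])
    }
  }
  records
}
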