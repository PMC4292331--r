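#' Construct a performance object
#'
#' A performance is the produced keystroke stream of one trial plus its
#' metadata.
#'
#' @param keystrokes Data frame with `onset_ms`, `pitch`, `velocity`,
#'   `hand` ("R"/"L").
#' @param participant,stimulus_id,context,tempo,ioi_ms,block,rep,trial_index
#'   Trial metadata; `ioi_ms` is the prescribed sixteenth-note IOI.
#' @return An object of class `performance`.
#' @export
new_performance <- function(keystrokes, participant = 1L, stimulus_id = 1L,
                            context = "long", tempo = "medium",
                            ioi_ms = 225, block = 1L, rep = 1L,
                            trial_index = 1L) {
  stopifnot(is.data.frame(keystrokes),
            all(c("onset_ms", "pitch", "velocity", "hand") %in% names(keystrokes)))
  if (is.unsorted(keystrokes$onset_ms)) {
    keystrokes <- keystrokes[order(keystrokes$onset_ms), ]
  }
  if (any(keystrokes$velocity < 0 | keystrokes$velocity > 127)) {
    stop("velocities must lie in 0..127", call. = FALSE)
  }
  structure(
    list(keystrokes = tibble::as_tibble(keystrokes),
         meta = list(participant = participant, stimulus_id = stimulus_id,
                     context = context, tempo = tempo, ioi_ms = ioi_ms,
                     block = block, rep = rep, trial_index = trial_index)),
    class = "performance"
  )
}

#' @export
print.performance <- function(x, ...) {
  m <- x$meta
  cat("Performance: participant", m$participant, "| stimulus", m$stimulus_id,
      "|", m$context, "/", m$tempo, "| block", m$block, "rep", m$rep, "|",
      nrow(x$keystrokes), "keystrokes\n")
  invisible(x)
}

#' Mean produced interonset interval of a performance
#'
#' Median-filtered mean of successive onset differences per hand (gaps
#' more than twice the prescribed IOI, e.g. around deletions or the
#' final note, are dropped). Used as the model's `t` parameter.
#'
#' @param performance A `performance`.
#' @return Mean produced IOI in milliseconds.
#' @export
mean_produced_ioi <- function(performance) {
  ks <- performance$keystrokes
  nominal <- performance$meta$ioi_ms
  d <- unlist(lapply(split(ks$onset_ms, ks$hand), function(o) diff(sort(o))))
  d <- d[d > 0.25 * nominal & d < 2 * nominal]
  if (!length(d)) return(nominal)
  mean(d)
}

#' Align a performed trial to its score
#'
#' Each hand's keystroke sequence is aligned to the score's event
#' sequence by dynamic programming with match cost 0 (pitch identity),
#' substitution cost 1, and insertion/deletion cost 1.4, plus a small
#' temporal term that resolves ambiguous alignments toward the
#' keystroke nearest its nominal onset -- deterministic
#' nearest-pitch-in-time coding. Unaligned score positions are
#' deletions. Unaligned keystrokes whose onsets fall within the chord
#' window of a substituted position are absorbed into that position, so
#' multiple incorrect pitches struck near-simultaneously are coded as a
#' single (chord) error; remaining unaligned keystrokes are additions
#' (themselves merged into chords within the window).
#'
#' @param score A `score`.
#' @param performance A `performance` of that score.
#' @param chord_window_ms Chord window (default 94 ms, roughly half the
#'   fastest prescribed IOI).
#' @return An object of class `alignment`: list with `matches` (one row
#'   per score position), `additions` (unmatched keystroke clusters),
#'   the performance `meta`, and `chord_window_ms`.
#' @export
align_performance <- function(score, performance, chord_window_ms = 94) {
  stopifnot(inherits(score, "score"), inherits(performance, "performance"))
  if (nrow(performance$keystrokes) == 0) {
    stop("empty performance", call. = FALSE)
  }
  out <- lapply(c("R", "L"), function(h) {
    sc <- score$events[score$events$hand == h, ]
    sc <- sc[order(sc$position), ]
    ks <- performance$keystrokes[performance$keystrokes$hand == h, ]
    .align_hand(sc, ks, performance$meta$ioi_ms, chord_window_ms)
  })
  matches <- dplyr::bind_rows(out[[1]]$matches, out[[2]]$matches)
  additions <- dplyr::bind_rows(out[[1]]$additions, out[[2]]$additions)
  frac <- mean(matches$matched & matches$correct)
  if (frac < 0.5) {
    stop("alignment failure: only ", round(100 * frac), "% of score positions ",
         "matched correctly (truncated or unrelated performance?)",
         call. = FALSE)
  }
  structure(list(matches = matches, additions = additions,
                 meta = performance$meta,
                 chord_window_ms = chord_window_ms),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", nrow(x$matches), "score positions;",
      sum(!x$matches$matched), "deletions;",
      nrow(x$additions), "additions;",
      sum(x$matches$matched & !x$matches$correct), "substituted positions\n")
  invisible(x)
}

.align_hand <- function(sc, ks, ioi_ms, chord_window_ms) {
  ks <- ks[order(ks$onset_ms), ]
  s <- sc$pitch
  nominal <- sc$onset_units * ioi_ms
  N <- length(s)
  M <- nrow(ks)
  gap <- 1.4
  # pairing cost: 0 for pitch identity, 1 for a substitution, plus a
  # small temporal term so ambiguous alignments resolve toward the
  # keystroke nearest its nominal onset
  PC <- outer(s, ks$pitch, "!=") * 1 +
    1e-3 * pmin(abs(outer(nominal, ks$onset_ms, "-")) / ioi_ms, 100)
  D <- matrix(0, N + 1L, M + 1L)
  D[, 1] <- gap * (0:N)
  D[1, ] <- gap * (0:M)
  for (i in seq_len(N)) {
    di <- D[i, ]
    dii <- D[i + 1L, ]
    for (j in seq_len(M)) {
      dii[j + 1L] <- min(di[j] + PC[i, j],   # match/substitute
                         di[j + 1L] + gap,   # score event deleted
                         dii[j] + gap)       # extra keystroke
    }
    D[i + 1L, ] <- dii
  }
  # traceback, preferring diagonal, then deletion, then insertion
  i <- N; j <- M
  pos_key <- rep(NA_integer_, N)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(D[i + 1L, j + 1L] - (D[i, j] + PC[i, j])) < 1e-9) {
      pos_key[i] <- j; i <- i - 1L; j <- j - 1L; next
    }
    if (i > 0 && abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + gap)) < 1e-9) {
      i <- i - 1L; next
    }
    j <- j - 1L
  }
  h <- sc$hand[1]
  matches <- tibble::tibble(
    hand = h,
    position = sc$position,
    score_pitch = s,
    in_excerpt = sc$in_excerpt,
    is_final = sc$is_final,
    accent_count = sc$accent_count,
    finger = sc$finger,
    nominal_onset = nominal,
    matched = !is.na(pos_key),
    onset_ms = NA_real_,
    correct = FALSE,
    velocity_correct = NA_real_,
    wrong_pitches = vector("list", N),
    wrong_velocities = vector("list", N)
  )
  for (i in seq_len(N)) {
    jj <- pos_key[i]
    if (is.na(jj)) next
    matches$onset_ms[i] <- ks$onset_ms[jj]
    if (ks$pitch[jj] == s[i]) {
      matches$correct[i] <- TRUE
      matches$velocity_correct[i] <- ks$velocity[jj]
    } else {
      matches$wrong_pitches[[i]] <- ks$pitch[jj]
      matches$wrong_velocities[[i]] <- ks$velocity[jj]
    }
  }
  # chord absorption: an unmatched keystroke near a substituted
  # position's onset is part of that (chord) error
  extra <- setdiff(seq_len(M), pos_key[!is.na(pos_key)])
  sub_pos <- which(matches$matched & !matches$correct)
  consumed <- logical(length(extra))
  for (k in seq_along(extra)) {
    j <- extra[k]
    if (!length(sub_pos)) break
    d <- abs(matches$onset_ms[sub_pos] - ks$onset_ms[j])
    b <- which.min(d)
    if (d[b] <= chord_window_ms) {
      i <- sub_pos[b]
      matches$wrong_pitches[[i]] <- c(matches$wrong_pitches[[i]], ks$pitch[j])
      matches$wrong_velocities[[i]] <- c(matches$wrong_velocities[[i]],
                                         ks$velocity[j])
      consumed[k] <- TRUE
    }
  }
  extra <- extra[!consumed]
  # merge remaining stray keystrokes into chord clusters within the window
  additions <- tibble::tibble(hand = character(), onset_ms = numeric(),
                              pitches = list(), velocities = list())
  if (length(extra)) {
    grp <- cumsum(c(1, diff(ks$onset_ms[extra]) > chord_window_ms))
    additions <- dplyr::bind_rows(lapply(split(extra, grp), function(idx) {
      tibble::tibble(hand = h, onset_ms = ks$onset_ms[idx[1]],
                     pitches = list(ks$pitch[idx]),
                     velocities = list(ks$velocity[idx]))
    }))
  }
  list(matches = matches, additions = additions)
}
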