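# Shared fixtures: tiny hand-built scores and perfect performances.

# A score with explicit per-hand pitch vectors (no final note unless
# given); excerpt defaults to the whole sequence.
make_score <- function(pitches_r, pitches_l = pitches_r - 12L,
                       excerpt = seq_along(pitches_r) - 1L,
                       context = "long", key = key_spec("C", "major"),
                       final = FALSE) {
  n <- length(pitches_r)
  mk_hand <- function(p, h) {
    d <- data.frame(position = seq.int(0L, n - 1L), hand = h, pitch = p,
                    onset_units = seq.int(0L, n - 1L), finger = NA_integer_,
                    in_excerpt = (seq.int(0L, n - 1L)) %in% excerpt,
                    is_final = FALSE)
    if (final) {
      d <- rbind(d, data.frame(position = n, hand = h, pitch = p[1],
                               onset_units = n, finger = NA_integer_,
                               in_excerpt = FALSE, is_final = TRUE))
    }
    d
  }
  new_score(rbind(mk_hand(pitches_r, "R"), mk_hand(pitches_l, "L")),
            key, context = context)
}

# Error-free performance of a score at a nominal IOI.
perfect_performance <- function(score, ioi_ms = 225, velocity = 64, ...) {
  ev <- score$events
  new_performance(
    data.frame(onset_ms = ev$onset_units * ioi_ms, pitch = ev$pitch,
               velocity = velocity, hand = ev$hand),
    ioi_ms = ioi_ms, stimulus_id = score$stimulus_id,
    context = score$context, ...)
}

# Quietly code one generated trial.
code_trial <- function(score, trial, window = 8L) {
  al <- align_performance(score, trial$performance)
  suppressWarnings(apply_exclusions(classify_errors(al, score, window)))
}

# Columns that identify an error record for round-trip comparison.
truth_key <- function(df) {
  k <- df[order(df$hand, df$target_position),
          c("hand", "target_position", "error_type", "intruder_pitch",
            "signed_source_distance")]
  rownames(k) <- NULL
  k
}
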