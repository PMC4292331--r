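#' Generate a long/short stimulus pair
#'
#' Composes one 8-event-per-hand excerpt and embeds it in a long context
#' (12 sixteenth events preceding, 13 following; 33 isochronous events
#' per hand) and a short context (4 preceding, 5 following; 17 events
#' per hand), each closed by a final held note on the tonic. The two
#' members of the pair share the excerpt and the flanking events
#' immediately surrounding it (2 before + 2 after), so pitch content
#' around the excerpt is controlled across context lengths.
#'
#' Pitch material is diatonic to the key, drawn per hand from a 6-tone
#' scale-step alphabet (right hand above middle C, left hand an octave
#' lower). Sequences are resampled until no pitch repeats successively
#' and the mean pitch-recurrence distance falls in [5, 7] events for
#' both contexts, matching the compositional constraints of the
#' stimulus set.
#'
#' @param key A `key_spec`.
#' @param seed Integer seed for this stimulus.
#' @param stimulus_id Identifier attached to both scores.
#' @param max_tries Resampling budget before giving up.
#' @return A list with elements `long` and `short`, both `score` objects.
#' @export
generate_stimulus_pair <- function(key, seed = 1L, stimulus_id = 1L,
                                   max_tries = 200L) {
  stopifnot(inherits(key, "key_spec"))
  set.seed(seed)
  alphabets <- list(R = .hand_alphabet(key, "R"), L = .hand_alphabet(key, "L"))
  for (try in seq_len(max_tries)) {
    hands_long <- lapply(alphabets, function(ab) .sample_melody(ab, 33L))
    hands_short <- lapply(c(R = "R", L = "L"), function(h) {
      .short_from_long(hands_long[[h]], alphabets[[h]])
    })
    long <- .assemble_score(hands_long, key, "long", stimulus_id,
                            pre = 12L, excerpt = 8L, post = 13L,
                            alphabets = alphabets)
    short <- .assemble_score(hands_short, key, "short", stimulus_id,
                             pre = 4L, excerpt = 8L, post = 5L,
                             alphabets = alphabets)
    ok <- mean_recurrence_distance(long) >= 5 &&
      mean_recurrence_distance(long) <= 7 &&
      mean_recurrence_distance(short) >= 5 &&
      mean_recurrence_distance(short) <= 7
    if (ok) return(list(long = long, short = short))
  }
  stop("stimulus generation failed after ", max_tries,
       " tries (seed ", seed, ", stimulus ", stimulus_id, ")", call. = FALSE)
}

# 6 consecutive scale tones starting on the tonic; RH near C5, LH lower.
.hand_alphabet <- function(key, hand) {
  steps <- if (key$mode == "major") c(0L, 2L, 4L, 5L, 7L, 9L)
           else c(0L, 2L, 3L, 5L, 7L, 8L)
  base <- if (hand == "R") 60L + key$tonic_pc else 48L + key$tonic_pc
  base + steps
}

.pick <- function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)]

# Uniform draws over the alphabet with no successive repeats.
.sample_melody <- function(alphabet, n) {
  out <- integer(n)
  out[1] <- .pick(alphabet)
  for (i in 2:n) out[i] <- .pick(setdiff(alphabet, out[i - 1L]))
  out
}

# Short context reuses the excerpt (long positions 12..19, 0-based) and
# the 2+2 flanking events; its outer context events are fresh material.
.short_from_long <- function(long, alphabet) {
  core <- long[11:22]                  # flank(2) + excerpt(8) + flank(2)
  pre <- integer(2)
  pre[2] <- .pick(setdiff(alphabet, core[1]))
  pre[1] <- .pick(setdiff(alphabet, pre[2]))
  post <- integer(3)
  post[1] <- .pick(setdiff(alphabet, core[12]))
  post[2] <- .pick(setdiff(alphabet, post[1]))
  post[3] <- .pick(setdiff(alphabet, post[2]))
  c(pre, core, post)                   # 2 + 12 + 3 = 17 events
}

.assemble_score <- function(hands, key, context, stimulus_id,
                            pre, excerpt, post, alphabets) {
  n <- pre + excerpt + post
  mask <- seq.int(pre, pre + excerpt - 1L)
  ev <- do.call(rbind, lapply(c("R", "L"), function(h) {
    data.frame(
      position = c(seq.int(0L, n - 1L), n),
      hand = h,
      pitch = c(hands[[h]], alphabets[[h]][1]),   # final note: tonic
      onset_units = c(seq.int(0L, n - 1L), n),
      finger = NA_integer_,
      in_excerpt = c(seq.int(0L, n - 1L) %in% mask, FALSE),
      is_final = c(rep(FALSE, n), TRUE)
    )
  }))
  new_score(ev, key, context = context, stimulus_id = stimulus_id)
}

#' Default key assignment for the 8 stimuli
#'
#' Half major (two in C major, one each in G and F major), half built on
#' harmonic minor scales (C, G, D, A minor).
#'
#' @return A list of 8 `key_spec` objects.
#' @export
stimulus_keys <- function() {
  list(
    key_spec("C", "major"), key_spec("C", "major"),
    key_spec("G", "major"), key_spec("F", "major"),
    key_spec("C", "minor"), key_spec("G", "minor"),
    key_spec("D", "minor"), key_spec("A", "minor")
  )
}

#' Generate the full stimulus set
#'
#' @param seed Cohort-level seed; stimulus s uses substream `seed + s`.
#' @return A list of 8 elements, each a list with `long` and `short`
#'   scores.
#' @export
generate_stimuli <- function(seed = 1L) {
  keys <- stimulus_keys()
  lapply(seq_along(keys), function(s) {
    generate_stimulus_pair(keys[[s]], seed = seed + s, stimulus_id = s)
  })
}
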