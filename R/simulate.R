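#' Generative ground truth for synthetic performances
#'
#' The parameter set the synthetic cohort is generated from. Error
#' placement follows the range model: the probability that event i goes
#' wrong is `base_error_rate * exp(-lambda * Event(0, i))`, so strongly
#' activated events (long contexts, slow tempi, strong accents under
#' heavy tactus weighting) are produced more accurately. Given an error,
#' with probability `p_contextual` the intruder is a context pitch whose
#' source position is sampled proportionally to its contextual
#' activation S_x * M_x over the signed window; otherwise the error is
#' noncontextual (a deletion with probability `deletion_share`, else an
#' out-of-stimulus intrusion). Velocities are linear in accent strength
#' with per-hand intercepts; onsets get Gaussian jitter; planted errors
#' are immediately corrected with probability `correction_prob`.
#'
#' @param a_true Memory parameter of the generating model.
#' @param w2_true Tactus (level-2) weight of the generating model; used
#'   for both layouts unless the context-specific weights are given.
#' @param w2_long,w2_short Optional context-specific tactus weights
#'   (defaults 0.48 and 0.40, the condition-level pattern of heavier
#'   tactus weighting in longer contexts); set both `NULL` to use
#'   `w2_true` everywhere.
#' @param meter Does the generating model include the metrical
#'   component? `FALSE` gives a serial-only (meter-off) cohort.
#' @param base_error_rate Baseline per-event error probability before
#'   activation scaling.
#' @param lambda Activation sensitivity of the error-probability link.
#' @param accent_rate_ratio Multiplicative change in error probability
#'   per accent level (default 0.8: each additional accent level makes
#'   an error 20% less likely, reproducing the observed decline of
#'   error rates with accent strength; the activation link alone does
#'   not produce it because Weber similarity penalizes locally isolated
#'   strong accents).
#' @param p_contextual Probability an error is contextual (0.81).
#' @param deletion_share Share of noncontextual errors that are
#'   deletions.
#' @param vel_right,vel_left Target mean velocities per hand (74.7 and
#'   58.8 MIDI units).
#' @param vel_slope Velocity increase per accent level.
#' @param vel_sd Gaussian velocity noise (MIDI units).
#' @param jitter_sd Gaussian onset jitter (ms).
#' @param correction_prob Probability a pitch error is immediately
#'   corrected.
#' @return A list of class `generative_truth`.
#' @export
generative_truth <- function(a_true = 0.92, w2_true = 0.48,
                             w2_long = 0.65, w2_short = 0.30, meter = TRUE,
                             base_error_rate = 0.28, lambda = 0.15,
                             accent_rate_ratio = 0.8,
                             p_contextual = 0.81, deletion_share = 0.6,
                             vel_right = 74.7, vel_left = 58.8,
                             vel_slope = 3.5, vel_sd = 4,
                             jitter_sd = 8, correction_prob = 0.02) {
  stopifnot(a_true > 0.8, a_true <= 1, w2_true >= 0.25, w2_true <= 0.99,
            is.null(w2_long) || (w2_long >= 0.25 && w2_long <= 0.99),
            is.null(w2_short) || (w2_short >= 0.25 && w2_short <= 0.99),
            accent_rate_ratio > 0, accent_rate_ratio <= 1,
            base_error_rate >= 0, base_error_rate < 1,
            p_contextual >= 0, p_contextual <= 1,
            deletion_share >= 0, deletion_share <= 1,
            jitter_sd >= 0, correction_prob >= 0, correction_prob <= 1)
  structure(as.list(environment()), class = "generative_truth")
}

#' Precompute the generative law for one score and tempo
#'
#' Event activations, per-event error probabilities, and the
#' source-sampling weights are identical across participants, blocks and
#' repetitions for a given score x tempo x truth, so they are computed
#' once and reused.
#'
#' @param score A `score`.
#' @param truth A `generative_truth`.
#' @param ioi_ms Prescribed IOI in ms.
#' @return A list with `p_err` (per position), `profile`, `params`, and
#'   `source_fields` (per position: signed distances and weights).
#' @export
precompute_generative <- function(score, truth, ioi_ms) {
  stopifnot(inherits(score, "score"), inherits(truth, "generative_truth"))
  w2 <- if (!truth$meter) 0.25
        else if (score$context == "long" && !is.null(truth$w2_long))
          truth$w2_long
        else if (score$context == "short" && !is.null(truth$w2_short))
          truth$w2_short
        else truth$w2_true
  profile <- score_profile(score, tactus_weight = w2)
  params <- range_params(a = truth$a_true, t = ioi_ms / 1000,
                         weights = profile$weights, window = 8L)
  n <- profile$n_positions
  E <- event_activation(profile, seq_len(n), params)
  acc <- score$grid$accent_counts
  p_err <- pmin(truth$base_error_rate * exp(-truth$lambda * E) *
                  truth$accent_rate_ratio^(acc - 1L), 1)
  source_fields <- lapply(seq_len(n), function(i) {
    f <- contextual_activations(profile, i, params)
    w <- if (truth$meter) f$activation else f$s
    list(x = f$x, w = w)
  })
  list(p_err = p_err, profile = profile, params = params,
       source_fields = source_fields, n = n)
}

#' Generate one synthetic performance with planted ground truth
#'
#' Produces the keystroke stream of one trial from the generative law in
#' `truth`, together with the planted error records. Ground truth
#' reports both the latent sampled source distance and the distance an
#' error coder must report (`coded_distance`: the nearest
#' octave-specific occurrence of the intruder pitch), which coincide
#' unless the sampled source is shadowed by a nearer occurrence of the
#' same pitch. Adjacent planted substitutions that swap two neighboring
#' pitches are normalized to a single exchange record, matching the
#' coding convention.
#'
#' @param score A `score`.
#' @param truth A `generative_truth`.
#' @param ioi_ms Prescribed sixteenth-note IOI in ms.
#' @param seed Integer seed for this trial.
#' @param meta Named list of trial metadata (participant, block, rep,
#'   trial_index, tempo).
#' @param precomp Optional result of [precompute_generative()].
#' @return A list with `performance` (a `performance`) and `truth`
#'   (a tibble of planted error records).
#' @export
generate_performance <- function(score, truth, ioi_ms, seed = 1L,
                                 meta = list(), precomp = NULL) {
  stopifnot(inherits(score, "score"), inherits(truth, "generative_truth"))
  if (is.null(precomp)) precomp <- precompute_generative(score, truth, ioi_ms)
  set.seed(seed)
  n <- precomp$n
  meta <- utils::modifyList(
    list(participant = 1L, block = 1L, rep = 1L, trial_index = 1L,
         tempo = names(which(tempo_table() == ioi_ms))[1] %||% "custom"),
    meta)
  mean_acc <- mean(score$grid$accent_counts)
  intercept <- c(R = truth$vel_right - truth$vel_slope * (mean_acc - 1),
                 L = truth$vel_left - truth$vel_slope * (mean_acc - 1))
  stim_set <- unique(stimulus_pitches(score))

  ks <- list()
  planted <- list()
  for (h in c("R", "L")) {
    pitches <- score_pitches(score, h, include_final = TRUE)
    for (i in seq_len(n)) {
      target <- pitches[i]
      acc <- score$grid$accent_counts[i]
      onset <- (i - 1) * ioi_ms + stats::rnorm(1, 0, truth$jitter_sd)
      vel <- .clamp_velocity(intercept[[h]] + truth$vel_slope * (acc - 1) +
                               stats::rnorm(1, 0, truth$vel_sd))
      if (stats::runif(1) >= precomp$p_err[i]) {
        ks[[length(ks) + 1L]] <- list(onset, target, vel, h)
        next
      }
      planted_rec <- NULL
      emit <- target
      if (stats::runif(1) < truth$p_contextual) {
        f <- precomp$source_fields[[i]]
        ok <- pitches[i + f$x] != target
        if (any(ok)) {
          xs <- f$x[ok]
          x <- xs[sample.int(length(xs), 1L, prob = f$w[ok])]
          emit <- pitches[i + x]
          src <- .nearest_source(emit, pitches, i, precomp$params$window)
          planted_rec <- list(type = "contextual_substitution", hand = h,
                              position = i - 1L, target = target,
                              intruder = emit, latent = x,
                              coded = src$distance)
        }
      }
      if (is.null(planted_rec)) {
        if (stats::runif(1) < truth$deletion_share) {
          planted <- c(planted, list(list(type = "deletion", hand = h,
                                          position = i - 1L, target = target,
                                          intruder = NA_integer_,
                                          latent = NA_integer_,
                                          coded = NA_integer_,
                                          corrected = FALSE)))
          next
        }
        emit <- .out_of_stimulus_pitch(target, stim_set)
        planted_rec <- list(type = "addition", hand = h, position = i - 1L,
                            target = target, intruder = emit,
                            latent = NA_integer_, coded = NA_integer_)
      }
      corrected <- stats::runif(1) < truth$correction_prob
      planted_rec$corrected <- corrected
      planted <- c(planted, list(planted_rec))
      ks[[length(ks) + 1L]] <- list(onset, emit, vel, h)
      if (corrected) {
        ks[[length(ks) + 1L]] <- list(onset + max(96, 0.45 * ioi_ms), target,
                                      .clamp_velocity(vel +
                                        stats::rnorm(1, 0, truth$vel_sd)), h)
      }
    }
    # final held note, always correct
    onset <- n * ioi_ms + stats::rnorm(1, 0, truth$jitter_sd)
    ks[[length(ks) + 1L]] <- list(onset, pitches[n + 1L],
                                  .clamp_velocity(intercept[[h]]), h)
  }
  keystrokes <- data.frame(
    onset_ms = vapply(ks, `[[`, numeric(1), 1),
    pitch = vapply(ks, function(k) as.integer(k[[2]]), integer(1)),
    velocity = vapply(ks, `[[`, numeric(1), 3),
    hand = vapply(ks, `[[`, character(1), 4)
  )
  perf <- new_performance(keystrokes,
                          participant = meta$participant,
                          stimulus_id = score$stimulus_id,
                          context = score$context, tempo = meta$tempo,
                          ioi_ms = ioi_ms, block = meta$block,
                          rep = meta$rep, trial_index = meta$trial_index)
  truth_df <- .planted_to_tibble(planted, meta, score)
  truth_df <- .collapse_planted_exchanges(truth_df, score)
  truth_df <- .merge_planted_sub_deletions(truth_df)
  list(performance = perf, truth = truth_df)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || is.na(a[1])) b else a

.clamp_velocity <- function(v) pmin(127, pmax(1, round(v)))

# nearest chromatic neighbor of the target absent from the stimulus
.out_of_stimulus_pitch <- function(target, stim_set) {
  for (d in c(1L, -1L, 2L, -2L, 3L, -3L, 6L, -6L)) {
    cand <- target + d
    if (!(cand %in% stim_set)) return(cand)
  }
  target + 13L
}

.planted_to_tibble <- function(planted, meta, score) {
  if (!length(planted)) {
    return(tibble::tibble(
      participant = integer(), stimulus_id = integer(), context = character(),
      tempo = character(), block = integer(), rep = integer(),
      trial_index = integer(), error_type = character(), hand = character(),
      target_position = integer(), target_pitch = integer(),
      intruder_pitch = integer(), latent_source_distance = integer(),
      signed_source_distance = integer(), in_excerpt = logical(),
      corrected = logical()))
  }
  excerpt <- excerpt_positions(score, base = 0L)
  tibble::tibble(
    participant = meta$participant, stimulus_id = score$stimulus_id,
    context = score$context, tempo = meta$tempo, block = meta$block,
    rep = meta$rep, trial_index = meta$trial_index,
    error_type = vapply(planted, `[[`, character(1), "type"),
    hand = vapply(planted, `[[`, character(1), "hand"),
    target_position = vapply(planted, function(p) as.integer(p$position),
                             integer(1)),
    target_pitch = vapply(planted, function(p) as.integer(p$target),
                          integer(1)),
    intruder_pitch = vapply(planted, function(p) as.integer(p$intruder),
                            integer(1)),
    latent_source_distance = vapply(planted,
                                    function(p) as.integer(p$latent),
                                    integer(1)),
    signed_source_distance = vapply(planted,
                                    function(p) as.integer(p$coded),
                                    integer(1)),
    in_excerpt = vapply(planted, function(p) p$position %in% excerpt,
                        logical(1)),
    corrected = vapply(planted, `[[`, logical(1), "corrected")
  )
}

# adjacent planted substitutions that swap neighboring pitches are what
# the coder reports as one exchange
.collapse_planted_exchanges <- function(truth, score) {
  if (nrow(truth) < 2) return(truth)
  drop <- logical(nrow(truth))
  ord <- order(truth$hand, truth$target_position)
  t2 <- truth[ord, ]
  for (k in seq_len(nrow(t2) - 1L)) {
    if (drop[ord[k]] || drop[ord[k + 1L]]) next
    a <- t2[k, ]; b <- t2[k + 1L, ]
    if (a$hand == b$hand &&
        a$error_type == "contextual_substitution" &&
        b$error_type == "contextual_substitution" &&
        b$target_position == a$target_position + 1L &&
        !a$corrected && !b$corrected &&
        identical(a$intruder_pitch, b$target_pitch) &&
        identical(b$intruder_pitch, a$target_pitch)) {
      truth$error_type[ord[k]] <- "exchange"
      truth$latent_source_distance[ord[k]] <- 1L
      truth$signed_source_distance[ord[k]] <- 1L
      drop[ord[k + 1L]] <- TRUE
    }
  }
  truth[!drop, ]
}

# an adjacent substitution+deletion pair where the intruder equals the
# deleted event's pitch is observationally a single deletion at the
# substituted position (the produced stream is identical), and that is
# what a coder reports; the observable ground truth says the same
.merge_planted_sub_deletions <- function(truth) {
  if (nrow(truth) < 2) return(truth)
  drop <- logical(nrow(truth))
  ord <- order(truth$hand, truth$target_position)
  t2 <- truth[ord, ]
  for (k in seq_len(nrow(t2) - 1L)) {
    if (drop[ord[k]] || drop[ord[k + 1L]]) next
    a <- t2[k, ]; b <- t2[k + 1L, ]
    if (a$hand != b$hand || b$target_position != a$target_position + 1L) next
    sub_first <- a$error_type == "contextual_substitution" &&
      b$error_type == "deletion" && identical(a$intruder_pitch, b$target_pitch)
    del_first <- a$error_type == "deletion" &&
      b$error_type == "contextual_substitution" &&
      identical(b$intruder_pitch, a$target_pitch) && !b$corrected
    if (sub_first && !a$corrected) {
      idx <- ord[k]                     # deletion lands on the sub position
      truth$error_type[idx] <- "deletion"
      truth$intruder_pitch[idx] <- NA_integer_
      truth$latent_source_distance[idx] <- NA_integer_
      truth$signed_source_distance[idx] <- NA_integer_
      drop[ord[k + 1L]] <- TRUE
    } else if (del_first) {
      idx <- ord[k + 1L]
      truth$error_type[idx] <- "deletion"
      truth$intruder_pitch[idx] <- NA_integer_
      truth$latent_source_distance[idx] <- NA_integer_
      truth$signed_source_distance[idx] <- NA_integer_
      drop[ord[k]] <- TRUE
    }
  }
  truth[!drop, ]
}

#' Generate a full synthetic cohort
#'
#' Generates the stimulus set, the trial roster, and every performance
#' with its planted ground truth. All randomness flows from the single
#' cohort seed through documented substreams (stimulus s uses
#' `seed + s`; the trial of participant p with index k uses
#' `seed + 1000 * p + k`), so any single trial can be regenerated in
#' isolation.
#'
#' @param n_participants Number of participants (default 26).
#' @param truth A `generative_truth`.
#' @param seed Cohort-level seed.
#' @param stimuli Optional pre-generated stimulus set (from
#'   [generate_stimuli()]).
#' @param design Optional pre-built roster (from [generate_design()]).
#' @return A list of class `cohort` with `stimuli`, `design`, `trials`
#'   (list of `generate_performance()` results, one per roster row),
#'   `truth`, `seed`.
#' @export
generate_cohort <- function(n_participants = 26L,
                            truth = generative_truth(), seed = 1L,
                            stimuli = NULL, design = NULL) {
  if (is.null(stimuli)) stimuli <- generate_stimuli(seed)
  if (is.null(design)) design <- generate_design(n_participants)
  pre <- list()
  trials <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    d <- design[r, ]
    sc <- stimuli[[d$stimulus_id]][[d$context]]
    key <- paste(d$stimulus_id, d$context, d$ioi_ms)
    if (is.null(pre[[key]])) pre[[key]] <- precompute_generative(sc, truth,
                                                                d$ioi_ms)
    trials[[r]] <- generate_performance(
      sc, truth, d$ioi_ms,
      seed = (seed + 1000L * d$participant + d$trial_index) %% 2147483629L,
      meta = list(participant = d$participant, block = d$block, rep = d$rep,
                  trial_index = d$trial_index, tempo = d$tempo),
      precomp = pre[[key]])
  }
  structure(list(stimuli = stimuli, design = design, trials = trials,
                 truth = truth, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$design$participant)),
      "participants,", nrow(x$design), "performances, seed", x$seed, "\n")
  invisible(x)
}

#' Code every trial of a cohort
#'
#' Runs alignment, error classification and the exclusion filters over
#' all performances of a cohort and pools the records.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param window Source window (default 8).
#' @param chord_window_ms Chord clustering window (default 94).
#' @return A tibble of pooled, exclusion-filtered error records.
#' @export
code_cohort <- function(cohort, window = 8L, chord_window_ms = 94) {
  recs <- lapply(seq_along(cohort$trials), function(r) {
    d <- cohort$design[r, ]
    sc <- cohort$stimuli[[d$stimulus_id]][[d$context]]
    al <- align_performance(sc, cohort$trials[[r]]$performance,
                            chord_window_ms)
    classify_errors(al, sc, window = window)
  })
  pooled <- dplyr::bind_rows(recs)
  suppressWarnings(apply_exclusions(pooled))
}
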