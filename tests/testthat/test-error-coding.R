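test_that("an error-free performance aligns with zero errors", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  al <- align_performance(sc, perfect_performance(sc))
  expect_true(all(al$matches$matched))
  expect_true(all(al$matches$correct))
  expect_equal(nrow(al$additions), 0)
  expect_equal(nrow(classify_errors(al, sc)), 0)
})

test_that("two wrong near-simultaneous keystrokes code as one chord error", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  # replace the right-hand event at position 3 with two wrong pitches
  # 40 ms apart
  idx <- which(ks$hand == "R" & ks$onset_ms == 3 * 225)
  ks$pitch[idx] <- 66L
  ks <- rbind(ks, data.frame(onset_ms = 3 * 225 + 40, pitch = 69L,
                             velocity = 64, hand = "R"))
  perf2 <- new_performance(ks, ioi_ms = 225)
  rec <- classify_errors(align_performance(sc, perf2), sc)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$error_type, "chord_error")
  expect_equal(rec$target_position, 3L)
  expect_equal(rec$chord_size, 2L)
})

test_that("a planted substitution is coded at exactly its position", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  idx <- which(ks$hand == "R" & ks$onset_ms == 5 * 225)
  ks$pitch[idx] <- 62L   # copy of the pitch at position 2 -> source -3
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$error_type, "contextual_substitution")
  expect_equal(rec$target_position, 5L)
  expect_equal(rec$signed_source_distance, -3L)
  expect_equal(rec$direction, "perseveratory")
})

test_that("swapped successive pitches collapse to a single exchange", {
  # intended A-E-D-C produced A-D-E-C
  sc <- make_score(c(69, 64, 62, 60, 65, 67, 64, 62))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  i1 <- which(ks$hand == "R" & ks$onset_ms == 1 * 225)
  i2 <- which(ks$hand == "R" & ks$onset_ms == 2 * 225)
  ks$pitch[c(i1, i2)] <- ks$pitch[c(i2, i1)]
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$error_type, "exchange")
  expect_equal(rec$target_position, 1L)
  expect_equal(rec$signed_source_distance, 1L)
  expect_equal(rec$direction, "anticipatory")
})

test_that("an intruder absent from the stimulus is noncontextual", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  idx <- which(ks$hand == "R" & ks$onset_ms == 4 * 225)
  ks$pitch[idx] <- 61L   # C#5 occurs nowhere in the stimulus
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$error_type, "addition")
  expect_false(rec$contextual)
  expect_true(is.na(rec$signed_source_distance))
})

test_that("anticipatory intrusions carry positive signed distance", {
  sc <- make_score(c(60, 64, 62, 65, 71, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  idx <- which(ks$hand == "R" & ks$onset_ms == 2 * 225)
  ks$pitch[idx] <- 71L   # copy from position 4, two events ahead
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(rec$signed_source_distance, 2L)
  expect_equal(rec$direction, "anticipatory")
})

test_that("equidistant sources prefer the anticipatory one and are flagged", {
  #          0   1   2   3   4   5   6
  sc <- make_score(c(67, 62, 64, 60, 65, 62, 64))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  idx <- which(ks$hand == "R" & ks$onset_ms == 3 * 225)
  ks$pitch[idx] <- 62L   # sources at -2 and +2
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(rec$signed_source_distance, 2L)
  expect_true(rec$source_tie)
})

test_that("deletions and additions are conserved by the alignment", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  drop_idx <- which(ks$hand == "L" & ks$onset_ms == 2 * 225)
  ks <- ks[-drop_idx, ]
  ks <- rbind(ks, data.frame(onset_ms = 6 * 225 + 110, pitch = 80L,
                             velocity = 64, hand = "R"))
  al <- align_performance(sc, new_performance(ks, ioi_ms = 225))
  # matched + deletions = score positions (per hand)
  expect_equal(sum(al$matches$matched) + sum(!al$matches$matched),
               nrow(sc$events))
  expect_equal(sum(!al$matches$matched), 1)
  expect_equal(nrow(al$additions), 1)
  rec <- classify_errors(al, sc)
  expect_setequal(rec$error_type, c("deletion", "addition"))
  del <- rec[rec$error_type == "deletion", ]
  expect_equal(del$hand, "L")
  expect_equal(del$target_position, 2L)
})

test_that("grossly truncated performances raise an alignment failure", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes[perf$keystrokes$onset_ms < 2 * 225, ]
  expect_error(align_performance(sc, new_performance(ks, ioi_ms = 225)),
               "alignment failure")
})

test_that("an immediately re-struck correct pitch is excluded as corrected", {
  sc <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  perf <- perfect_performance(sc)
  ks <- perf$keystrokes
  # wrong key at position 4, correct pitch re-struck 100 ms later
  idx <- which(ks$hand == "R" & ks$onset_ms == 4 * 225)
  ks$onset_ms[idx] <- 4 * 225 + 100
  ks <- rbind(ks, data.frame(onset_ms = 4 * 225, pitch = 62L,
                             velocity = 64, hand = "R"))
  rec <- classify_errors(align_performance(sc, new_performance(ks, ioi_ms = 225)),
                         sc)
  expect_equal(nrow(rec), 1)
  expect_true(rec$corrected)
  out <- suppressWarnings(apply_exclusions(rec))
  expect_true(out$excluded)
  expect_equal(out$exclusion_reason, "corrected")
})

test_that("the learned-error rule requires both conjuncts", {
  base <- make_score(c(60, 64, 62, 65, 60, 67, 64, 65))
  mk_rec <- function(trial) {
    perf <- perfect_performance(base, trial_index = trial)
    ks <- perf$keystrokes
    idx <- which(ks$hand == "R" & ks$onset_ms == 5 * 225)
    ks$pitch[idx] <- 62L
    classify_errors(
      align_performance(base, new_performance(ks, ioi_ms = 225,
                                              trial_index = trial)),
      base)
  }
  recs <- dplyr::bind_rows(lapply(1:5, mk_rec))  # error in 5 of 8 trials
  learning <- recs[1, c("participant", "stimulus_id", "hand",
                        "target_position")]
  out <- apply_exclusions(recs, learning_records = learning, n_test = 8)
  expect_true(all(out$excluded))
  expect_true(all(out$exclusion_reason == "learned"))
  # clean learning phase: retained despite 5/8 test errors
  clean <- apply_exclusions(recs,
                            learning_records = learning[0, ], n_test = 8)
  expect_false(any(clean$excluded))
  # missing learning data: rule skipped with a warning
  expect_warning(apply_exclusions(recs), "learning-phase")
})

test_that("coded records reproduce planted ground truth exactly", {
  truth <- generative_truth(jitter_sd = 0, correction_prob = 0,
                            base_error_rate = 0.25)
  keys <- stimulus_keys()
  for (s in 1:6) {
    pair <- generate_stimulus_pair(keys[[(s %% 8) + 1]], seed = 100 + s,
                                   stimulus_id = s)
    sc <- if (s %% 2 == 0) pair$long else pair$short
    tr <- generate_performance(sc, truth, ioi_ms = 225, seed = 200 + s)
    rec <- code_trial(sc, tr)
    expect_equal(truth_key(as.data.frame(rec)),
                 truth_key(as.data.frame(tr$truth)))
  }
})

test_that("coding is robust to timing jitter", {
  truth <- generative_truth(jitter_sd = 20, correction_prob = 0,
                            base_error_rate = 0.25)
  pair <- generate_stimulus_pair(key_spec("G", "major"), seed = 7)
  agree <- total <- 0
  for (s in 1:6) {
    tr <- generate_performance(pair$long, truth, ioi_ms = 187.5,
                               seed = 300 + s)
    rec <- code_trial(pair$long, tr)
    k1 <- truth_key(as.data.frame(rec))
    k2 <- truth_key(as.data.frame(tr$truth))
    total <- total + nrow(k2)
    agree <- agree + sum(do.call(paste, k1) %in% do.call(paste, k2))
  }
  expect_gte(agree / total, 0.99)
})

test_that("planted corrections are always caught by the filter", {
  truth <- generative_truth(jitter_sd = 0, correction_prob = 1,
                            base_error_rate = 0.2, deletion_share = 0)
  pair <- generate_stimulus_pair(key_spec("C", "minor"), seed = 9)
  tr <- generate_performance(pair$long, truth, ioi_ms = 225, seed = 17)
  stopifnot(nrow(tr$truth) > 0)
  rec <- code_trial(pair$long, tr)
  expect_true(all(rec$excluded))
  expect_true(all(rec$exclusion_reason == "corrected"))
  expect_equal(sum(rec$corrected), nrow(tr$truth))
})
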