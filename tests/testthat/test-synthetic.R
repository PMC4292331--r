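test_that("stimulus pairs satisfy the compositional constraints", {
  keys <- stimulus_keys()
  for (s in 1:8) {
    pair <- generate_stimulus_pair(keys[[s]], seed = s, stimulus_id = s)
    long <- pair$long; short <- pair$short
    expect_equal(long$n_positions, 33L)
    expect_equal(short$n_positions, 17L)
    expect_equal(excerpt_positions(long), 12:19)
    expect_equal(excerpt_positions(short), 4:11)
    scale <- scale_pitch_classes(keys[[s]])
    for (h in c("R", "L")) {
      pl <- score_pitches(long, h, include_final = FALSE)
      ps <- score_pitches(short, h, include_final = FALSE)
      # no successive repetitions
      expect_false(any(diff(pl) == 0))
      expect_false(any(diff(ps) == 0))
      # diatonic pitch material
      expect_true(all((c(pl, ps) %% 12) %in% scale))
      # shared excerpt and 2+2 flanking events
      expect_equal(pl[11:22], ps[3:14])
    }
    # pitch-recurrence spacing near 6 events
    expect_gte(mean_recurrence_distance(long), 5)
    expect_lte(mean_recurrence_distance(long), 7)
    expect_gte(mean_recurrence_distance(short), 5)
    expect_lte(mean_recurrence_distance(short), 7)
  }
})

test_that("the trial roster realizes the factorial design", {
  d <- generate_design(4)
  expect_equal(nrow(d), 4 * 64)
  for (p in 1:4) {
    dp <- d[d$participant == p, ]
    expect_equal(nrow(dp), 64L)
    # 4 excerpts x 2 tempi x 4 blocks x 2 repetitions
    expect_equal(length(unique(dp$stimulus_id)), 8L)
    expect_equal(as.integer(table(dp$context)), c(32L, 32L))
    expect_equal(as.integer(table(dp$tempo)), c(32L, 32L))
    # each stimulus keeps one context and one tempo, twice per block
    agg <- dplyr::count(dp, .data$stimulus_id, .data$context, .data$tempo,
                        .data$block)
    expect_true(all(agg$n == 2L))
    # tempo alternates every trial within a block
    for (b in 1:4) {
      db <- dp[dp$block == b & dp$rep == 1, ]
      db <- db[order(db$trial_in_block), ]
      expect_true(all(db$tempo[-1] != db$tempo[-nrow(db)]))
      # contexts are grouped within the block
      expect_equal(length(rle(db$context)$lengths), 2L)
    }
  }
  # context order counterbalanced across participants in block 1
  first_ctx <- vapply(1:4, function(p) {
    db <- d[d$participant == p & d$block == 1, ]
    db$context[which.min(db$trial_in_block)]
  }, character(1))
  expect_setequal(unique(first_ctx), c("long", "short"))
})

test_that("a zero-error truth reproduces the score", {
  pair <- generate_stimulus_pair(key_spec("F", "major"), seed = 3)
  truth <- generative_truth(base_error_rate = 0, jitter_sd = 0)
  tr <- generate_performance(pair$long, truth, 225, seed = 1)
  expect_equal(nrow(tr$truth), 0L)
  ks <- tr$performance$keystrokes
  ev <- pair$long$events
  for (h in c("R", "L")) {
    expect_equal(ks$pitch[ks$hand == h],
                 ev$pitch[ev$hand == h][order(ev$position[ev$hand == h])])
  }
})

test_that("velocities scale with accent and differ by hand", {
  pair <- generate_stimulus_pair(key_spec("C", "major"), seed = 6)
  truth <- generative_truth(base_error_rate = 0, jitter_sd = 0)
  als <- lapply(1:8, function(s) {
    tr <- generate_performance(pair$long, truth, 225, seed = s)
    align_performance(pair$long, tr$performance)
  })
  by_hand <- intensity_by_hand(als)
  expect_equal(by_hand$mean_velocity[by_hand$hand == "R"], 74.7,
               tolerance = 0.05)
  expect_equal(by_hand$mean_velocity[by_hand$hand == "L"], 58.8,
               tolerance = 0.05)
  by_acc <- intensity_by_accent(als, excerpt_only = FALSE)
  expect_true(all(diff(by_acc$mean_velocity) > 0))
})

test_that("a heavier tactus weight shifts planted sources to even distances", {
  pair <- generate_stimulus_pair(key_spec("D", "minor"), seed = 8)
  even_share <- function(truth) {
    d <- unlist(lapply(1:30, function(s) {
      tr <- generate_performance(pair$long, truth, 225, seed = 500 + s)
      tr$truth$latent_source_distance
    }))
    d <- d[!is.na(d)]
    mean(abs(d) %% 2 == 0)
  }
  hi <- even_share(generative_truth(w2_long = 0.65, jitter_sd = 0,
                                    correction_prob = 0))
  eq <- even_share(generative_truth(w2_long = 0.25, jitter_sd = 0,
                                    correction_prob = 0))
  expect_gt(hi, eq)
})

test_that("cohort generation is reproducible from its seed", {
  t0 <- generative_truth()
  a <- generate_cohort(n_participants = 1, truth = t0, seed = 77)
  b <- generate_cohort(n_participants = 1, truth = t0, seed = 77)
  expect_identical(a$trials[[5]]$performance$keystrokes,
                   b$trials[[5]]$performance$keystrokes)
  # any single trial is reproducible in isolation
  d <- a$design[5, ]
  sc <- a$stimuli[[d$stimulus_id]][[d$context]]
  tr <- generate_performance(
    sc, t0, d$ioi_ms,
    seed = (77 + 1000L * d$participant + d$trial_index) %% 2147483629L,
    meta = list(participant = d$participant, block = d$block, rep = d$rep,
                trial_index = d$trial_index, tempo = d$tempo))
  expect_identical(tr$performance$keystrokes,
                   a$trials[[5]]$performance$keystrokes)
})
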