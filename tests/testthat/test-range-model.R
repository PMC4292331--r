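flat_profile <- function(n) accent_profile(metrical_grid(1, 1, n),
                                           metrical_weights(1, 1, 0.99))

test_that("serial activation follows the exponential-decay law", {
  expect_equal(serial_activation(0, 0.85, 0.225), 1)
  expect_equal(serial_activation(1, 0.85, 0.225), 0.4856309, tolerance = 1e-6)
  expect_equal(serial_activation(-3, 0.9, 0.5), serial_activation(3, 0.9, 0.5))
  expect_error(serial_activation(1, 0.75, 0.3), "a must")
  expect_error(serial_activation(1, 0.9, 2.5), "t must")
})

test_that("metrical similarity is a symmetric Weber ratio", {
  expect_equal(metrical_similarity(0.5, 0.5), 1)
  expect_equal(metrical_similarity(1, 0.25), 0.4)
  expect_equal(metrical_similarity(0.25, 1), 0.4)
  # decreasing in |difference| at fixed sum
  expect_gt(metrical_similarity(0.6, 0.4), metrical_similarity(0.8, 0.2))
  expect_error(metrical_similarity(0, 0.5), "positive")
})

test_that("contextual activations multiply serial and metrical parts", {
  p <- accent_profile(metrical_grid(8, 4, 33), metrical_weights(4))
  params <- range_params(0.85, 0.225, metrical_weights(4))
  f <- contextual_activations(p, 17, params)
  # where accents match, activation equals the serial part exactly
  same <- f$m == 1
  expect_true(any(same))
  expect_equal(f$activation[same], f$s[same])
  # flat profile: strictly decreasing in |x|
  fp <- flat_profile(33)
  ff <- contextual_activations(fp, 17, range_params(0.85, 0.225,
                                                    fp$weights))
  ord <- order(abs(ff$x))
  expect_true(all(diff(ff$activation[ord][seq(2, 16, 2)]) < 0))
  expect_error(contextual_activations(p, 40, params), "outside")
})

test_that("activations match a brute-force per-pair oracle", {
  # independent evaluation: a^(|x|/t) * (1 - |mi-mj|/(mi+mj)) pair by pair
  for (w2 in c(0.25, 0.48)) {
    grid <- metrical_grid(8, 4, 33)
    w <- metrical_weights(4, 2, w2)
    p <- accent_profile(grid, w)
    a <- 0.85; t <- 0.225
    m <- as.numeric(t(grid$presence) %*% w$weights)  # oracle m_i
    params <- range_params(a, t, w)
    for (i in c(1, 5, 17, 30, 33)) {
      f <- contextual_activations(p, i, params)
      for (r in seq_len(nrow(f))) {
        j <- i + f$x[r]
        expected <- a^(abs(f$x[r]) / t) * (1 - abs(m[i] - m[j]) / (m[i] + m[j]))
        expect_equal(f$activation[r], expected, tolerance = 1e-12)
      }
      e_expected <- sum(vapply(setdiff(seq(-8, 8), 0), function(x) {
        j <- i + x
        if (j < 1 || j > 33) return(0)
        a^(abs(x) / t) * (1 - abs(m[i] - m[j]) / (m[i] + m[j]))
      }, numeric(1)))^2
      expect_equal(event_activation(p, i, params), e_expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("event activation reflects context amount and rate", {
  w <- metrical_weights(4)
  long <- accent_profile(metrical_grid(8, 4, 33), w)
  short <- accent_profile(metrical_grid(8, 4, 17), w)
  # single event: no context, zero activation
  single <- accent_profile(metrical_grid(1, 1, 1), metrical_weights(1, 1, 0.99))
  expect_equal(event_activation(single, 1, range_params(0.85, 0.225,
                                                        single$weights)), 0)
  for (a in c(0.81, 0.85, 0.95)) {
    for (t in c(0.19, 0.25, 0.43)) {
      params <- range_params(a, t, w)
      e_long <- mean(event_activation(long, 13:20, params))
      e_short <- mean(event_activation(short, 5:12, params))
      expect_gt(e_long, e_short)
    }
  }
  # non-decreasing in t at fixed a
  ts <- seq(0.15, 0.6, by = 0.05)
  es <- vapply(ts, function(t)
    mean(event_activation(long, 13:20, range_params(0.85, t, w))),
    numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("contextual activation is symmetric fore and aft", {
  w <- metrical_weights(4, 2, 0.4)
  p <- accent_profile(metrical_grid(8, 4, 33), w)
  params <- range_params(0.88, 0.3, w)
  for (i in 13:20) {   # edge-free positions
    f <- contextual_activations(p, i, params)
    # serial part is symmetric position by position; at the full
    # metrical period the similarity matches too
    expect_equal(f$s[f$x > 0][order(f$x[f$x > 0])],
                 f$s[f$x < 0][order(-f$x[f$x < 0])])
    expect_equal(f$activation[f$x == 8], f$activation[f$x == -8])
  }
  # averaged over a full cycle the signed field is symmetric
  bins_pos <- bins_neg <- numeric(8)
  for (i in 13:20) {
    f <- contextual_activations(p, i, params)
    for (d in 1:8) {
      bins_pos[d] <- bins_pos[d] + sum(f$activation[f$x == d])
      bins_neg[d] <- bins_neg[d] + sum(f$activation[f$x == -d])
    }
  }
  expect_equal(bins_pos, bins_neg, tolerance = 1e-12)
})

test_that("predicted gradients normalize and show meter alternation", {
  w <- metrical_weights(4)
  p <- accent_profile(metrical_grid(8, 4, 33), w)
  params <- range_params(0.85, 0.225, w)
  g <- predicted_gradient(p, params, 13:20)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  # flat profile: strictly decreasing decay-only gradient
  fp <- flat_profile(33)
  gs <- predicted_gradient(fp, range_params(0.85, 0.225, fp$weights), 13:20)
  expect_true(all(diff(as.numeric(gs)) < 0))
  # metrical component elevates bin 2 relative to the serial-only gradient
  g_serial <- predicted_gradient(p, params, 13:20, meter = FALSE)
  expect_gt(g[2] / g_serial[2], 1)
  expect_gt(meter_alternation(g), meter_alternation(g_serial))
})

test_that("predicted gradient matches a brute-force fold", {
  w <- metrical_weights(4, 2, 0.6)
  p <- accent_profile(metrical_grid(8, 4, 17), w)
  params <- range_params(0.9, 0.19, w)
  pos <- 5:12
  bins <- numeric(8)
  for (i in pos) {
    f <- contextual_activations(p, i, params)
    for (d in 1:8) bins[d] <- bins[d] + sum(f$activation[abs(f$x) == d])
  }
  expect_equal(as.numeric(predicted_gradient(p, params, pos)),
               bins / sum(bins), tolerance = 1e-12)
})

test_that("gradient objects validate their invariants", {
  expect_error(new_movement_gradient(rep(0.2, 8)), "sum to 1")
  expect_error(new_movement_gradient(c(-0.1, 1.1, rep(0, 6))),
               "non-negative")
  und <- new_movement_gradient(rep(NA_real_, 8), n_errors = 0L)
  expect_false(is_defined_gradient(und))
  expect_true(is_defined_gradient(new_movement_gradient(c(1, rep(0, 7)),
                                                        n_errors = 3L)))
})

test_that("parameter bounds are enforced", {
  w <- metrical_weights(4)
  expect_error(range_params(a = 0.8, t = 0.2, weights = w), "a must")
  expect_error(range_params(a = 1.01, t = 0.2, weights = w), "a must")
  expect_error(range_params(a = 0.9, t = 0.1, weights = w), "t must")
  expect_silent(range_params(a = 1.0, t = 2.0, weights = w))
})
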