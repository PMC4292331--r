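eq4 <- metrical_weights(4, 2, 0.25)

test_that("VAF is the squared correlation with its critical value", {
  obs <- c(0.5, 0.25, 0.12, 0.06, 0.03, 0.02, 0.01, 0.01)
  expect_equal(vaf(obs, obs), 1)
  expect_equal(vaf(obs, 2 * obs + 0.1), 1)      # scale/shift invariant
  expect_lt(vaf(obs, rev(obs) * 0 + c(0.1, -0.1)), 0.2)
  expect_warning(v <- vaf(rep(0.125, 8), obs), "zero-variance")
  expect_true(is.na(v))
  # critical value for an 8-point gradient is 0.50 at alpha = .05
  expect_equal(critical_vaf(8), 0.50, tolerance = 0.002)
})

test_that("the SSE form of AIC rewards fit and penalizes parameters", {
  expect_equal(aic_sse(0.01, 8, 1) - aic_sse(0.02, 8, 1), 8 * log(1 / 2))
  expect_equal(aic_sse(0.01, 8, 2) - aic_sse(0.01, 8, 1), 2)
  expect_error(aic_sse(0.01, 2, 2))
})

test_that("fit_a recovers itself from noise-free model gradients", {
  profile <- accent_profile(metrical_grid(8, 4, 33), eq4)
  for (a_true in c(0.83, 0.85, 0.9)) {
    params <- range_params(a_true, 0.215, eq4)
    obs <- new_movement_gradient(
      as.numeric(predicted_gradient(profile, params, 13:20)),
      n_errors = 1000L)
    fit <- fit_a(obs, profile, 0.215, 13:20)
    expect_equal(fit$a_hat, a_true, tolerance = 0.005)
    expect_gte(fit$vaf, 0.999)
    expect_true(fit$significant)
  }
})

test_that("degenerate gradients pin a at its bounds and are flagged", {
  profile <- accent_profile(metrical_grid(8, 4, 33), eq4)
  flat <- new_movement_gradient(rep(1 / 8, 8), n_errors = 100L)
  # flat observed gradients have zero variance: VAF is undefined by design
  f_flat <- suppressWarnings(fit_a(flat, profile, 0.215, 13:20))
  expect_gte(f_flat$a_hat, 0.99)   # slowest decay the meter term allows
  expect_true(is.na(f_flat$vaf))
  f_flat_s <- suppressWarnings(fit_a(flat, profile, 0.215, 13:20,
                                     meter = FALSE))
  expect_gte(f_flat_s$a_hat, 0.998)
  expect_true(f_flat_s$at_bound)
  steep <- new_movement_gradient(c(1, rep(0, 7)), n_errors = 100L)
  f_steep <- fit_a(steep, profile, 0.215, 13:20)
  expect_lte(f_steep$a_hat, 0.805)
  expect_true(f_steep$at_bound)
  # undefined gradient -> no-fit signal
  expect_null(fit_a(new_movement_gradient(rep(NA_real_, 8), n_errors = 0L),
                    profile, 0.215, 13:20))
})

test_that("fit_w2 recovers the tactus weight given a", {
  grid <- metrical_grid(8, 4, 33)
  for (w2_true in c(0.4, 0.5, 0.7)) {
    w <- metrical_weights(4, 2, w2_true)
    profile <- accent_profile(grid, w)
    params <- range_params(0.85, 0.215, w)
    obs <- new_movement_gradient(
      as.numeric(predicted_gradient(profile, params, 13:20)),
      n_errors = 1000L)
    fit <- fit_w2(obs, grid, 0.215, a = 0.85, positions = 13:20)
    expect_equal(fit$w2_hat, w2_true, tolerance = 0.01)
  }
  # equal-weight truth lands on the 0.25 boundary
  profile_eq <- accent_profile(grid, eq4)
  obs_eq <- new_movement_gradient(
    as.numeric(predicted_gradient(profile_eq, range_params(0.85, 0.215, eq4),
                                  13:20)), n_errors = 1000L)
  fit_eq <- fit_w2(obs_eq, grid, 0.215, a = 0.85, positions = 13:20)
  expect_equal(fit_eq$w2_hat, 0.25, tolerance = 0.01)
  expect_true(fit_eq$at_bound)
})

test_that("fits are deterministic", {
  grid <- metrical_grid(8, 4, 33)
  profile <- accent_profile(grid, metrical_weights(4, 2, 0.48))
  set.seed(5)
  obs <- sample_gradient(profile, range_params(0.87, 0.2, profile$weights),
                         200, 13:20)
  f1 <- fit_a(obs, accent_profile(grid, eq4), 0.2, 13:20)
  f2 <- fit_a(obs, accent_profile(grid, eq4), 0.2, 13:20)
  expect_identical(f1$a_hat, f2$a_hat)
  w1 <- fit_w2(obs, grid, 0.2, a = f1$a_hat, positions = 13:20)
  w2 <- fit_w2(obs, grid, 0.2, a = f1$a_hat, positions = 13:20)
  expect_identical(w1$w2_hat, w2$w2_hat)
})

test_that("model comparison is structurally complete and nested", {
  grid <- metrical_grid(8, 4, 33)
  profile <- accent_profile(grid, metrical_weights(4, 2, 0.6))
  set.seed(11)
  for (k in 1:5) {
    obs <- sample_gradient(profile, range_params(0.86, 0.21, profile$weights),
                           150, 13:20)
    cmp <- compare_models(obs, grid, 0.21, 13:20)
    expect_equal(nrow(cmp), 3L)
    expect_setequal(cmp$model_tag, c("S", "SxM_fixed", "SxM_w2"))
    expect_equal(sum(cmp$best), 1L)
    # the free tactus weight can never fit worse than the fixed one
    expect_lte(cmp$sse[cmp$model_tag == "SxM_w2"],
               cmp$sse[cmp$model_tag == "SxM_fixed"] + 1e-12)
    expect_equal(cmp$n_free, c(1L, 1L, 2L))
  }
})

test_that("the two-step procedure averages a across conditions", {
  grid_l <- context_grid("long")
  grid_s <- context_grid("short")
  prof_l <- accent_profile(grid_l, eq4)
  prof_s <- accent_profile(grid_s, eq4)
  set.seed(21)
  gradients <- list(
    "long-medium" = sample_gradient(prof_l, range_params(0.86, 0.23, eq4),
                                    300, 13:20),
    "short-medium" = sample_gradient(prof_s, range_params(0.86, 0.23, eq4),
                                     300, 5:12),
    "short-fast" = new_movement_gradient(rep(NA_real_, 8), n_errors = 0L))
  grids <- list("long-medium" = grid_l, "short-medium" = grid_s,
                "short-fast" = grid_s)
  ts <- c("long-medium" = 0.23, "short-medium" = 0.23, "short-fast" = 0.19)
  out <- fit_participant(gradients, grids, ts)
  expect_equal(nrow(out$fits), 2L)    # the empty condition is skipped
  expect_equal(out$a_mean, mean(out$fits$a_hat))
  expect_equal(out$fits$a_hat[1], 0.86, tolerance = 0.03)
})
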