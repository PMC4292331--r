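#' Variance accounted for by a model gradient
#'
#' VAF is the squared Pearson correlation between observed and predicted
#' gradient bins. For 8-point gradients the critical value at alpha =
#' 0.05 is 0.50 (the squared critical correlation for n = 8).
#'
#' @param observed,predicted Numeric vectors (or `movement_gradient`s) of
#'   equal length.
#' @return VAF in [0, 1]; NA with a warning if the observed vector has
#'   zero variance.
#' @export
vaf <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  stopifnot(length(observed) == length(predicted))
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero-variance gradient: VAF undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(observed, predicted)^2
}

#' Critical VAF for an 8-point gradient
#'
#' Squared critical Pearson correlation at the given alpha for n points
#' (0.50 for n = 8, alpha = 0.05).
#'
#' @param n Number of gradient points (default 8).
#' @param alpha Significance level (default 0.05).
#' @return Critical VAF.
#' @export
critical_vaf <- function(n = 8L, alpha = 0.05) {
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2L)
  r2 <- tcrit^2 / (tcrit^2 + n - 2L)
  r2
}

#' Gaussian-SSE Akaike information criterion
#'
#' `AIC = n * ln(SSE / n) + 2p`; lower is better. With small SSE on
#' proportion-scale gradients the values are negative.
#'
#' @param sse Residual sum of squares.
#' @param n Number of fitted points.
#' @param p Number of free parameters.
#' @return AIC value.
#' @export
aic_sse <- function(sse, n, p) {
  stopifnot(n > p, sse >= 0)
  n * log(sse / n) + 2 * p
}

# deterministic bounded 1-d minimization: exhaustive grid then
# golden-section refinement between the grid neighbors of the minimum
.grid_golden <- function(f, lower, upper, step = 1e-3, tol = 1e-6) {
  grid <- seq(lower, upper, by = step)
  vals <- vapply(grid, f, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), tol = tol)
  if (opt$objective <= vals[k]) opt$minimum else grid[k]
}

.fit_result <- function(model_tag, a_hat, w2_hat, t_used, observed,
                        predicted, n_free) {
  sse <- sum((as.numeric(observed) - as.numeric(predicted))^2)
  v <- vaf(observed, predicted)
  n <- length(observed)
  structure(
    list(model_tag = model_tag, a_hat = a_hat, w2_hat = w2_hat,
         t_used = t_used, sse = sse, vaf = v,
         significant = !is.na(v) && v >= critical_vaf(n),
         aic = aic_sse(sse, n, n_free), n_points = n, n_free_params = n_free,
         predicted = as.numeric(predicted),
         at_bound = isTRUE(a_hat <= 0.803) || isTRUE(a_hat >= 0.998) ||
           isTRUE(w2_hat <= 0.252) || isTRUE(w2_hat >= 0.988)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Range model fit [", x$model_tag, "]: a =", round(x$a_hat, 4))
  if (!is.na(x$w2_hat)) cat(", w2 =", round(x$w2_hat, 4))
  cat(", t =", x$t_used, "s | VAF =", round(x$vaf, 3),
      if (x$significant) "(significant)" else "(n.s.)",
      "| AIC =", round(x$aic, 2), "\n")
  invisible(x)
}

#' Fit the memory parameter a to a movement gradient
#'
#' Step 1 of the two-step fitting procedure: with metrical weights held
#' fixed (equal weights by default), `a` is chosen to minimize the sum
#' of squared errors between the observed gradient and the model's
#' predicted gradient, over 0.8 < a <= 1.0 (exhaustive 1e-3 grid with
#' golden-section refinement; fully deterministic).
#'
#' @param gradient An observed `movement_gradient`.
#' @param profile The stimulus `accent_profile` (with the weights the
#'   fit should hold fixed).
#' @param t Event duration in seconds (mean produced IOI per trial).
#' @param positions Evaluation positions (default: the full sequence;
#'   pass excerpt positions for stimulus-level fits).
#' @param meter Include the metrical component (default TRUE; FALSE fits
#'   the serial-only model).
#' @return A `fit_result` with `model_tag` "S" or "SxM_fixed". Returns
#'   NULL (no-fit signal) for an undefined gradient.
#' @export
fit_a <- function(gradient, profile, t,
                  positions = seq_len(profile$n_positions), meter = TRUE) {
  if (!is_defined_gradient(gradient)) return(NULL)
  obs <- as.numeric(gradient)
  f <- function(a) {
    params <- range_params(a = a, t = t, weights = profile$weights,
                           window = attr(gradient, "window"))
    pred <- predicted_gradient(profile, params, positions, meter = meter)
    sum((obs - as.numeric(pred))^2)
  }
  a_hat <- .grid_golden(f, 0.801, 1.0, step = 1e-3)
  params <- range_params(a = a_hat, t = t, weights = profile$weights,
                         window = attr(gradient, "window"))
  pred <- predicted_gradient(profile, params, positions, meter = meter)
  .fit_result(if (meter) "SxM_fixed" else "S", a_hat, NA_real_, t, obs, pred,
              n_free = 1L)
}

#' Fit the tactus weight w2 to a movement gradient
#'
#' Step 2 of the two-step procedure: with `a` fixed (at the
#' participant's mean from step 1), the tactus weight is chosen to
#' minimize the SSE over w2 in [0.25, 0.99]; the remaining level
#' weights follow (1 - w2) / (k - 1).
#'
#' @param gradient An observed `movement_gradient`.
#' @param grid The stimulus `metrical_grid`.
#' @param t Event duration in seconds.
#' @param a Fixed memory parameter from step 1.
#' @param positions Evaluation positions.
#' @return A `fit_result` with `model_tag` "SxM_w2" (two free
#'   parameters counting the inherited a), or NULL for an undefined
#'   gradient.
#' @export
fit_w2 <- function(gradient, grid, t, a,
                   positions = seq_len(grid$n_positions)) {
  if (!is_defined_gradient(gradient)) return(NULL)
  obs <- as.numeric(gradient)
  pred_for <- function(w2) {
    w <- metrical_weights(grid$n_levels, grid$tactus_level, w2)
    profile <- accent_profile(grid, w)
    params <- range_params(a = a, t = t, weights = w,
                           window = attr(gradient, "window"))
    predicted_gradient(profile, params, positions, meter = TRUE)
  }
  f <- function(w2) sum((obs - as.numeric(pred_for(w2)))^2)
  w2_hat <- .grid_golden(f, 0.25, 0.99, step = 1e-3)
  .fit_result("SxM_w2", a, w2_hat, t, obs, pred_for(w2_hat), n_free = 2L)
}

#' Compare the serial, serial x metrical, and weighted-tactus models
#'
#' Fits three nested accounts of one observed gradient: the serial-only
#' model S (one free parameter, a), the serial x metrical model with
#' equal level weights S x M (also one free parameter, so the comparison
#' with S is like-for-like), and the S x M model with the tactus weight
#' w2 free (two parameters; a is carried over from the S x M fit). The
#' best model is flagged by AIC.
#'
#' @param gradient An observed `movement_gradient`.
#' @param grid The stimulus `metrical_grid`.
#' @param t Event duration in seconds.
#' @param positions Evaluation positions.
#' @param a_fixed Optional fixed a (e.g. a participant mean); if NULL, a
#'   is fitted per model.
#' @return A tibble with one row per model: `model_tag`, `a_hat`,
#'   `w2_hat`, `vaf`, `sse`, `aic`, `n_free`, `best`.
#' @export
compare_models <- function(gradient, grid, t,
                           positions = seq_len(grid$n_positions),
                           a_fixed = NULL) {
  if (!is_defined_gradient(gradient)) return(NULL)
  eq <- metrical_weights(grid$n_levels, grid$tactus_level, 0.25)
  profile_eq <- accent_profile(grid, eq)
  fit_for <- function(meter) {
    if (is.null(a_fixed)) {
      fit_a(gradient, profile_eq, t, positions, meter = meter)
    } else {
      params <- range_params(a = a_fixed, t = t, weights = eq,
                             window = attr(gradient, "window"))
      pred <- predicted_gradient(profile_eq, params, positions, meter = meter)
      .fit_result(if (meter) "SxM_fixed" else "S", a_fixed, NA_real_, t,
                  as.numeric(gradient), pred, n_free = 1L)
    }
  }
  fs <- fit_for(meter = FALSE)
  fm <- fit_for(meter = TRUE)
  fw <- fit_w2(gradient, grid, t, a = fm$a_hat, positions)
  fits <- list(fs, fm, fw)
  out <- tibble::tibble(
    model_tag = vapply(fits, `[[`, character(1), "model_tag"),
    a_hat = vapply(fits, `[[`, numeric(1), "a_hat"),
    w2_hat = vapply(fits, `[[`, numeric(1), "w2_hat"),
    vaf = vapply(fits, `[[`, numeric(1), "vaf"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    n_free = vapply(fits, `[[`, integer(1), "n_free_params")
  )
  out$best = out$aic == min(out$aic)
  out
}

#' Two-step fits for one participant
#'
#' Implements the published fitting procedure over a participant's
#' per-condition gradients: step 1 fits `a` to every condition with
#' errors (equal weights) and averages the estimates over the available
#' conditions; step 2 re-fits each condition's tactus weight w2 with
#' `a` fixed at that mean. Conditions with undefined gradients are
#' skipped.
#'
#' @param gradients Named list of observed `movement_gradient`s, one per
#'   condition.
#' @param grids Named list (same names) of stimulus `metrical_grid`s.
#' @param ts Named numeric (same names): mean produced IOI in seconds
#'   per condition.
#' @return A list with `a_mean` and `fits` (tibble keyed by condition
#'   with a_hat, w2_hat, vaf, aic per model).
#' @export
fit_participant <- function(gradients, grids, ts) {
  stopifnot(identical(names(gradients), names(grids)),
            identical(names(gradients), names(ts)))
  defined <- vapply(gradients, is_defined_gradient, logical(1))
  if (!any(defined)) return(list(a_mean = NA_real_, fits = NULL))
  step1 <- lapply(names(gradients)[defined], function(cond) {
    eq <- metrical_weights(grids[[cond]]$n_levels,
                           grids[[cond]]$tactus_level, 0.25)
    fit_a(gradients[[cond]], accent_profile(grids[[cond]], eq), ts[[cond]])
  })
  a_mean <- mean(vapply(step1, `[[`, numeric(1), "a_hat"))
  fits <- lapply(seq_along(step1), function(k) {
    cond <- names(gradients)[defined][k]
    fw <- fit_w2(gradients[[cond]], grids[[cond]], ts[[cond]], a = a_mean)
    tibble::tibble(condition = cond, a_hat = step1[[k]]$a_hat,
                   a_mean = a_mean, w2_hat = fw$w2_hat,
                   vaf_step1 = step1[[k]]$vaf, vaf_w2 = fw$vaf,
                   aic_w2 = fw$aic, significant = fw$significant)
  })
  list(a_mean = a_mean, fits = dplyr::bind_rows(fits))
}
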