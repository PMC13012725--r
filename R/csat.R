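#' Average DAmFRET curve
#'
#' Mean AmFRET per expression bin, keeping only bins with at least
#' `min_cells` cells (default 100).
#'
#' @param profile a [bin_log64()] profile
#' @param min_cells minimal bin occupancy
#' @return data.frame with `c` (bin center, p.d.u.) and `amfret` (bin mean)
#' @export
average_damfret_curve <- function(profile, min_cells = 100L) {
  stopifnot(inherits(profile, "damfret_profile"))
  keep <- profile$count >= min_cells
  if (!any(keep))
    stop("no bins with at least ", min_cells, " cells", call. = FALSE)
  cells <- profile$cells
  mean_amfret <- vapply(which(keep), function(b)
    mean(cells$amfret[cells$bin == b]), numeric(1))
  data.frame(c = profile$bin_center[keep], amfret = mean_amfret,
             n = profile$count[keep])
}

#' Automated fit window for the assembly curve
#'
#' A reproducible surrogate for choosing curve limits by eye: the window
#' starts one bin before the first point exceeding the baseline (median of
#' the first three points) by three times their MAD, and ends where the
#' Gaussian-smoothed slope first falls below 5% of its maximum (after the
#' maximum). The window always contains at least 4 points. A curve with no
#' detectable rise is flagged and no window returned.
#'
#' @param curve data.frame from [average_damfret_curve()] (>= 6 points)
#' @param rise_mad baseline exceedance multiple (default 3)
#' @param slope_frac slope cutoff as a fraction of the peak slope
#' @return list with `window` (`c(c_begin, c_end)`), index range `idx`, and
#'   `flat` flag
#' @export
fit_window <- function(curve, rise_mad = 3, slope_frac = 0.05) {
  y <- curve$amfret
  n <- length(y)
  if (n < 6) stop_config("fit_window needs a curve with >= 6 points")
  base <- median(y[1:3])
  noise <- max(mad(y[1:3]), 1e-6)
  above <- which(y > base + rise_mad * noise)
  if (!length(above))
    return(list(window = NULL, idx = NULL, flat = TRUE))
  i_begin <- max(1L, above[1] - 1L)
  sm <- gauss_smooth(y, sd_pts = 2)
  slope <- diff(sm)
  ipk <- which.max(slope)
  post <- which(slope < slope_frac * slope[ipk])
  post <- post[post > ipk]
  i_end <- if (length(post)) min(post[1] + 1L, n) else n
  if (i_end - i_begin + 1L < 4L) i_end <- min(n, i_begin + 3L)
  if (i_end - i_begin + 1L < 4L) i_begin <- max(1L, i_end - 3L)
  list(window = c(curve$c[i_begin], curve$c[i_end]),
       idx = c(i_begin, i_end), flat = FALSE)
}

#' Fit the Weibull assembly curve (saturation-concentration estimate)
#'
#' Least-squares fit of [amfret_weibull()] to an average DAmFRET curve over
#' a fit window. Initial values come from a Gaussian-smoothed version of the
#' curve (plateau, half-plateau abscissa, steepness 2); `Amp` and `C50` are
#' constrained to within twofold of their initial guesses and `a` to
#' \[0.1, 10\]. On a curve from a seeded run the fitted `C50` approximates
#' the saturation concentration C_sat; on an unseeded run of a
#' nucleation-limited protein it estimates the median spontaneous-nucleation
#' concentration (C50_stochastic).
#'
#' @param curve data.frame with columns `c` and `amfret`
#' @param window optional `c(c_begin, c_end)`; default from [fit_window()]
#' @param rng_seed seed (only consumed by [mc_fit_errors()] downstream)
#' @return object of class `"weibull_fit"` with components `coefficients`
#'   (`amp`, `c50`, `a`), `window`, `converged`, `fitted`, `residuals`,
#'   `data`, `param_sd` (filled by [mc_fit_errors()])
#' @export
fit_weibull <- function(curve, window = NULL, rng_seed = NULL) {
  if (is.null(window)) {
    fw <- fit_window(curve)
    if (fw$flat)
      stop("curve has no detectable rise; nothing to fit", call. = FALSE)
    window <- fw$window
  }
  sel <- curve$c >= window[1] & curve$c <= window[2]
  if (sum(sel) < 4) stop_config("fit window must contain >= 4 points")
  d <- curve[sel, , drop = FALSE]
  sm <- gauss_smooth(d$amfret, sd_pts = 2)
  amp0 <- max(sm)
  if (amp0 <= 0) stop_config("non-positive plateau guess")
  i_half <- which(sm >= amp0 / 2)[1]
  c50_0 <- if (is.na(i_half)) median(d$c) else d$c[i_half]
  start <- list(amp = amp0, c50 = c50_0, a = 2)
  lower <- c(amp = amp0 / 2, c50 = c50_0 / 2, a = 0.1)
  upper <- c(amp = amp0 * 2, c50 = c50_0 * 2, a = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(amfret ~ amp * (1 - exp(-log(2) * (c / c50)^a)),
                      data = d, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- unlist(start)
    converged <- FALSE
    fitted <- amfret_weibull(d$c, co["amp"], co["c50"], co["a"])
  } else {
    co <- coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
    fitted <- as.numeric(predict(fit))
  }
  structure(list(coefficients = co, window = window, converged = converged,
                 fitted = fitted, residuals = d$amfret - fitted, data = d,
                 start = unlist(start), param_sd = NULL,
                 rng_seed = rng_seed),
            class = "weibull_fit")
}

#' @export
coef.weibull_fit <- function(object, ...) object$coefficients

#' @export
predict.weibull_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$c
  else if (is.data.frame(newdata)) newdata$c else as.numeric(newdata)
  co <- object$coefficients
  amfret_weibull(cc, co["amp"], co["c50"], co["a"])
}

#' @export
residuals.weibull_fit <- function(object, ...) object$residuals

#' @export
print.weibull_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Weibull assembly-curve fit%s\n",
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  Amp = %.4g   C50 = %.4g p.d.u.   a = %.3g\n",
              co["amp"], co["c50"], co["a"]))
  if (!is.null(x$param_sd))
    cat(sprintf("  Monte-Carlo SD: amp %.3g, c50 %.3g, a %.3g\n",
                x$param_sd["amp"], x$param_sd["c50"], x$param_sd["a"]))
  cat(sprintf("  window: [%.4g, %.4g], %d points, residual SD %.3g\n",
              x$window[1], x$window[2], nrow(x$data), sd(x$residuals)))
  invisible(x)
}

#' @export
summary.weibull_fit <- function(object, ...) {
  print(object)
  invisible(list(coefficients = object$coefficients,
                 param_sd = object$param_sd,
                 converged = object$converged,
                 rss = sum(object$residuals^2), n = nrow(object$data)))
}

#' @export
plot.weibull_fit <- function(x, ...) {
  d <- x$data
  plot(d$c, d$amfret, log = "x", xlab = "acceptor (p.d.u.)",
       ylab = "mean AmFRET", pch = 16, col = "grey40", ...)
  grid_c <- exp(seq(log(min(d$c)), log(max(d$c)), length.out = 200))
  lines(grid_c, predict(x, grid_c), col = "red3", lwd = 2)
  abline(v = x$coefficients["c50"], lty = 3)
  invisible(x)
}

#' @export
simulate.weibull_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    r <- object$residuals
    replicate(nsim,
              object$fitted + sample(r, length(r), replace = TRUE),
              simplify = FALSE)
  })
}

#' Monte-Carlo parameter errors by residual resampling
#'
#' Builds `n_mc` synthetic curves (fitted curve plus residuals resampled
#' with replacement), refits each with the same window and bounds, and
#' stores the SD of the refit parameters in the returned fit.
#'
#' @param fit a [fit_weibull()] object
#' @param n_mc number of Monte-Carlo refits (default 100)
#' @param rng_seed integer seed
#' @return the fit with `param_sd` (named numeric) and `mc` (matrix) filled
#' @export
mc_fit_errors <- function(fit, n_mc = 100L, rng_seed = 1L) {
  stopifnot(inherits(fit, "weibull_fit"))
  d <- fit$data
  res <- fit$residuals
  mc <- with_seed(rng_seed, {
    m <- matrix(NA_real_, n_mc, 3,
                dimnames = list(NULL, c("amp", "c50", "a")))
    for (i in seq_len(n_mc)) {
      y <- fit$fitted + sample(res, length(res), replace = TRUE)
      dd <- data.frame(c = d$c, amfret = y)
      rf <- tryCatch(fit_weibull(dd, window = fit$window),
                     error = function(e) NULL)
      if (!is.null(rf)) m[i, ] <- rf$coefficients
    }
    m
  })
  fit$mc <- mc
  fit$param_sd <- apply(mc, 2, sd, na.rm = TRUE)
  fit
}

#' Supersaturability: fold reduction of C50 by seeding
#'
#' The ratio of the C50 estimated without seed (stochastic nucleation) to
#' the C50 with seed (which approximates C_sat). A ratio above 1 means the
#' protein persists soluble above its saturation concentration, i.e. it is
#' supersaturable. Ratios are only meaningful between fits from the same
#' batch run; with mismatched batches the score is suppressed with a
#' warning.
#'
#' @param fit_stochastic,fit_seeded converged [fit_weibull()] objects
#' @param batch length-2 vector of batch labels (default: same batch)
#' @return object of class `"supersat_score"` with `fold_reduction`,
#'   `c50_stochastic`, `c50_seeded`, `same_batch`
#' @export
supersaturability <- function(fit_stochastic, fit_seeded,
                              batch = c("batch1", "batch1")) {
  stopifnot(inherits(fit_stochastic, "weibull_fit"),
            inherits(fit_seeded, "weibull_fit"))
  same <- length(unique(batch)) == 1L
  c50_st <- unname(coef(fit_stochastic)["c50"])
  c50_se <- unname(coef(fit_seeded)["c50"])
  fold <- if (same) c50_st / c50_se else NA_real_
  if (!same)
    warning("C50 ratio suppressed: fits come from different batches",
            call. = FALSE)
  if (!fit_stochastic$converged || !fit_seeded$converged)
    warning("supersaturability from a non-converged fit", call. = FALSE)
  structure(list(c50_stochastic = c50_st, c50_seeded = c50_se,
                 fold_reduction = fold, same_batch = same),
            class = "supersat_score")
}

#' @export
print.supersat_score <- function(x, ...) {
  if (x$same_batch)
    cat(sprintf(
      "Supersaturability: C50_stochastic / C50_seeded = %.4g / %.4g = %.3g\n",
      x$c50_stochastic, x$c50_seeded, x$fold_reduction))
  else cat("Supersaturability: suppressed (batch mismatch)\n")
  invisible(x)
}

#' Profile-to-C50 convenience wrapper
#'
#' Runs [average_damfret_curve()], [fit_window()] and [fit_weibull()] (plus
#' optional Monte-Carlo errors) in one call.
#'
#' @param profile a [bin_log64()] profile
#' @param min_cells bin-occupancy threshold for the average curve
#' @param n_mc Monte-Carlo refits (0 to skip)
#' @param rng_seed integer seed
#' @return a `"weibull_fit"`
#' @export
fit_damfret_csat <- function(profile, min_cells = 100L, n_mc = 0L,
                             rng_seed = 1L) {
  curve <- average_damfret_curve(profile, min_cells = min_cells)
  fit <- fit_weibull(curve, rng_seed = rng_seed)
  if (n_mc > 0) fit <- mc_fit_errors(fit, n_mc = n_mc, rng_seed = rng_seed)
  fit
}
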