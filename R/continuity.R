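#' Scott's rule bin count
#'
#' Bin width `h = 3.49 s n^(-1/3)` (s = sample SD); the count is
#' `ceiling(range / h)`, at least 1. A constant sample yields a single bin.
#'
#' @param x numeric sample
#' @return integer bin count
#' @export
scott_bin_count <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(1L)
  s <- sd(x)
  if (s == 0) return(1L)
  h <- 3.49 * s * n^(-1 / 3)
  max(1L, as.integer(ceiling(diff(range(x)) / h)))
}

#' Bin quality filter for the continuity analysis
#'
#' A bin enters the spline fit iff it holds at least `min_count` cells, its
#' cell density (count divided by the AmFRET IQR of the bin) is at least
#' `min_density`, and at most `max_outlier` of its cells are Tukey-fence
#' outliers. A zero IQR counts as a density pass.
#'
#' @param count,iqr,outlier_fraction per-bin statistics
#' @param min_count,min_density,max_outlier thresholds (defaults 20, 500,
#'   0.25)
#' @return logical mask of kept bins
#' @export
bin_quality_filter <- function(count, iqr, outlier_fraction,
                               min_count = 20, min_density = 500,
                               max_outlier = 0.25) {
  density <- ifelse(is.na(iqr) | iqr <= 0, Inf, count / iqr)
  ok <- count >= min_count & density >= min_density &
    (is.na(outlier_fraction) | outlier_fraction <= max_outlier)
  ok & !is.na(ok)
}

#' Zero-phase low-pass smoothing
#'
#' Forward-backward application of a 2nd-order Butterworth low-pass
#' (normalized critical frequency `critical`), with odd-reflection padding
#' of the series ends so that constants and linear trends pass through
#' essentially unchanged and no phase shift is introduced.
#'
#' @param y numeric series on a uniform grid
#' @param critical normalized critical frequency in (0, 1)
#' @param order filter order
#' @return smoothed series, same length
#' @export
smooth_lowpass <- function(y, critical = 0.1, order = 2L) {
  n <- length(y)
  if (n < 4) return(y)
  bf <- signal::butter(order, critical)
  p <- 100L  # padding long enough for start-up transients to die out
  z <- .odd_extension(y, (1L - p):(n + p))
  z <- as.numeric(signal::filter(bf, z))
  z <- rev(as.numeric(signal::filter(bf, rev(z))))
  z[(p + 1L):(p + n)]
}

# odd-periodic extension of a series by repeated point reflection about its
# end points; exact for constants and linear trends at any distance
.odd_extension <- function(y, k) {
  n <- length(y)
  m <- n - 1L
  M <- 2L * m
  D <- 2 * (y[n] - y[1])
  t <- (k - 1L) %% M
  q <- ((k - 1L) - t) %/% M
  base <- ifelse(t <= m, y[1L + t], 2 * y[n] - y[2L * n - 1L - t])
  base + q * D
}

# Scott-rule binning of per-cell (acceptor, amfret) pairs on the log axis
.continuity_bins <- function(cells) {
  x <- log10(cells$acceptor)
  nb <- scott_bin_count(x)
  edges <- seq(min(x), max(x), length.out = nb + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nb)
  count <- tabulate(bin, nb)
  med <- iqr <- outl <- rep(NA_real_, nb)
  for (b in which(count > 0)) {
    v <- cells$amfret[bin == b]
    med[b] <- median(v)
    iqr[b] <- iqr7(v)
    outl[b] <- mean(tukey_outlier(v))
  }
  list(center = (edges[-1] + edges[-(nb + 1L)]) / 2, edges = edges,
       bin = bin, count = count, median = med, iqr = iqr, outlier = outl)
}

#' Bootstrap spline fit to per-bin median AmFRET
#'
#' Concentrations (log10 acceptor) are binned by Scott's rule; bins passing
#' [bin_quality_filter()] contribute their median AmFRET. Within each kept
#' bin, cells are resampled with replacement `n_boot` times; each
#' replicate's medians are denoised with the zero-phase low-pass filter
#' ([smooth_lowpass()]), and the final curve is the pointwise mean of the
#' replicates.
#'
#' @param x a `"damfret_profile"` or a data.frame with columns `acceptor`
#'   and `amfret`
#' @param n_boot bootstrap replicates (default 100)
#' @param rng_seed integer seed
#' @param min_count,min_density,max_outlier bin-quality thresholds
#' @param critical low-pass critical frequency
#' @return object of class `"damfret_spline"`; if fewer than 4 bins pass the
#'   filter, the object has `insufficient = TRUE`
#' @export
fit_median_spline <- function(x, n_boot = 100L, rng_seed = NULL,
                              min_count = 20, min_density = 500,
                              max_outlier = 0.25, critical = 0.1) {
  cells <- if (inherits(x, "damfret_profile")) x$cells else x
  stopifnot(all(c("acceptor", "amfret") %in% names(cells)))
  cells <- cells[is.finite(cells$acceptor) & cells$acceptor > 0 &
                   is.finite(cells$amfret), , drop = FALSE]
  bins <- .continuity_bins(cells)
  keep <- bin_quality_filter(bins$count, bins$iqr, bins$outlier,
                             min_count, min_density, max_outlier)
  out <- list(centers = bins$center[keep], fitted = NULL, boot = NULL,
              kept_mask = keep, bins = bins, n_boot = as.integer(n_boot),
              insufficient = sum(keep) < 4L)
  class(out) <- "damfret_spline"
  if (out$insufficient) return(out)
  kept_idx <- which(keep)
  vals <- lapply(kept_idx, function(b) cells$amfret[bins$bin == b])
  nk <- length(kept_idx)
  boot <- with_seed(rng_seed, {
    m <- matrix(NA_real_, n_boot, nk)
    for (r in seq_len(n_boot)) {
      med <- vapply(vals, function(v)
        median(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      m[r, ] <- smooth_lowpass(med, critical = critical)
    }
    m
  })
  out$boot <- boot
  out$fitted <- colMeans(boot)
  out
}

#' @export
print.damfret_spline <- function(x, ...) {
  if (x$insufficient)
    cat("DAmFRET median spline: insufficient data (<4 bins pass filter)\n")
  else
    cat(sprintf(
      "DAmFRET median spline: %d kept bins (of %d), %d bootstrap replicates\n",
      length(x$centers), length(x$kept_mask), x$n_boot))
  invisible(x)
}

# transition landmarks of a single curve on a uniform grid
.transition_one <- function(x, y, flat_tol = 1e-10) {
  d1 <- diff(y)
  mid <- (x[-1] + x[-length(x)]) / 2
  if (max(d1) <= flat_tol)
    return(list(t_point = NA_real_, t_start = NA_real_, t_end = NA_real_,
                flat = TRUE, tied = FALSE))
  # ties (up to floating-point jitter) break to the first index, flagged
  near_max <- which(d1 >= max(d1) - 1e-9 * max(abs(d1)))
  imax <- near_max[1]
  tied <- length(near_max) > 1L
  t_point <- mid[imax]
  d2 <- diff(d1)                     # at interior grid points x[2..n-1]
  xi <- x[2:(length(x) - 1L)]
  before <- xi < t_point
  after <- xi > t_point
  t_start <- if (any(before)) xi[before][which.max(d2[before])] else x[1]
  t_end <- if (any(after)) xi[after][which.min(d2[after])] else
    x[length(x)]
  list(t_point = t_point, t_start = t_start, t_end = t_end, flat = FALSE,
       tied = tied)
}

#' Locate the assembly transition of a fitted spline
#'
#' The transition point is the concentration with the greatest change in
#' AmFRET: the maximum of the first finite-difference derivative of the
#' fitted curve. The transition start is the maximum of the second
#' derivative before the transition point, the end is the minimum of the
#' second derivative after it. Landmarks are computed on every bootstrap
#' replicate and the medians reported. Flat curves yield an undefined
#' transition (`flat = TRUE`); derivative ties break to the smallest index
#' and are flagged.
#'
#' @param spline a [fit_median_spline()] object
#' @return object of class `"damfret_transition"` with `t_point`, `t_start`,
#'   `t_end` (log10 acceptor), per-bootstrap values, and flags
#' @export
locate_transition <- function(spline) {
  stopifnot(inherits(spline, "damfret_spline"))
  if (spline$insufficient)
    stop("cannot locate a transition: insufficient data", call. = FALSE)
  x <- spline$centers
  per_boot <- apply(spline$boot, 1L, function(y) .transition_one(x, y))
  tp <- vapply(per_boot, `[[`, numeric(1), "t_point")
  ts <- vapply(per_boot, `[[`, numeric(1), "t_start")
  te <- vapply(per_boot, `[[`, numeric(1), "t_end")
  flat <- vapply(per_boot, `[[`, logical(1), "flat")
  mean_tr <- .transition_one(x, spline$fitted)
  structure(list(
    t_point = median(tp, na.rm = TRUE),
    t_start = median(ts, na.rm = TRUE),
    t_end = median(te, na.rm = TRUE),
    boot = data.frame(t_point = tp, t_start = ts, t_end = te, flat = flat),
    flat = mean_tr$flat || all(flat),
    tied = mean_tr$tied), class = "damfret_transition")
}

#' @export
print.damfret_transition <- function(x, ...) {
  if (x$flat) cat("DAmFRET transition: undefined (flat curve)\n")
  else cat(sprintf(
    "DAmFRET transition (log10 acceptor): start %.3f  point %.3f  end %.3f\n",
    x$t_start, x$t_point, x$t_end))
  invisible(x)
}

#' Hartigan & Hartigan's dip statistic
#'
#' The dip is the minimum over all unimodal distribution functions of the
#' supremum distance to the empirical CDF; it satisfies `dip >= 1/(2n)`.
#' Computed by the classical iterative convex-minorant / concave-majorant
#' algorithm (compiled).
#'
#' @param x numeric sample, `n >= 4`
#' @return the dip statistic (scalar)
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("dip statistic requires n >= 4", call. = FALSE)
  .dip_stat_sorted(sort(x))
}

# cache of Monte-Carlo null dip distributions, keyed by (n, n_mc, seed)
.dip_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the dip statistic
#'
#' Dips of `n_mc` uniform(0,1) samples of size `n` (the standard null
#' calibration of the dip test). Sorted uniform samples are generated
#' directly from normalized cumulative exponential spacings. Results are
#' cached per `(n, n_mc, rng_seed)` within a session.
#'
#' @param n sample size
#' @param n_mc number of Monte-Carlo draws
#' @param rng_seed integer seed (required for caching)
#' @return numeric vector of `n_mc` null dip values
#' @export
dip_null <- function(n, n_mc = 10000L, rng_seed = 1L) {
  key <- sprintf("%d_%d_%d", n, n_mc, as.integer(rng_seed))
  if (!is.null(.dip_cache[[key]])) return(.dip_cache[[key]])
  nd <- with_seed(rng_seed, .dip_null_mc(as.integer(n), as.integer(n_mc)))
  .dip_cache[[key]] <- nd
  nd
}

#' Dip test p-value
#'
#' `p` is the fraction of Monte-Carlo uniform null samples of the same size
#' whose dip is at least the observed dip. Monotone nonincreasing in the
#' observed dip at fixed `n`.
#'
#' @param x numeric sample, `n >= 4`
#' @param n_mc Monte-Carlo draws for the null (default 10000)
#' @param rng_seed seed for the null simulation
#' @return list with `statistic`, `p_value`, `n`, `n_mc`
#' @export
dip_pvalue <- function(x, n_mc = 10000L, rng_seed = 1L) {
  x <- x[is.finite(x)]
  d <- dip_statistic(x)
  nd <- dip_null(length(x), n_mc, rng_seed)
  list(statistic = d, p_value = mean(nd >= d), n = length(x), n_mc = n_mc)
}

#' Reference AmFRET level from a monomer control
#'
#' The sub-classification of continuous profiles (low / high / low-to-high)
#' compares the fitted spline against the AmFRET level at which a high-FRET
#' state begins. With a monomeric control this level is taken as a robust
#' upper bound of the control's AmFRET distribution,
#' `median + 4 * MAD` of the per-cell control AmFRET.
#'
#' @param control a `"damfret_profile"`, an event table, or a numeric vector
#'   of control AmFRET values
#' @return scalar reference AmFRET
#' @export
amfret_reference <- function(control) {
  v <- if (inherits(control, "damfret_profile")) control$cells$amfret
  else if (is.data.frame(control)) {
    if (is.null(control$amfret)) control <- compute_amfret(control)
    control$amfret
  } else as.numeric(control)
  v <- v[is.finite(v)]
  median(v) + 4 * mad(v)
}

#' Classify a DAmFRET profile as discontinuous or continuous
#'
#' The complete continuity pipeline: Scott-rule binning, bin quality
#' filtering, bootstrap spline fit, transition localization, then Hartigan's
#' dip test on the AmFRET values of all cells whose acceptor lies within the
#' transition range `[t_start, t_end]`. `p < alpha` classifies the profile
#' as discontinuous (nucleation barrier); otherwise it is continuous and
#' sub-classified against `reference_amfret`: spline minimum and ending
#' value both below the reference = `continuous_low`, both above =
#' `continuous_high`, minimum below and ending above =
#' `continuous_low_to_high`. Profiles whose fitted curve is flat (no
#' detectable transition) are continuous by construction and sub-classified
#' the same way.
#'
#' @param x a `"damfret_profile"` or data.frame with `acceptor` and `amfret`
#' @param reference_amfret scalar reference (see [amfret_reference()])
#' @param alpha dip-test significance level (default 0.05)
#' @param n_boot bootstrap replicates for the spline
#' @param rng_seed integer seed (spline bootstrap and dip null)
#' @param n_mc Monte-Carlo draws for the dip null (default 1000; see
#'   [dip_pvalue()] for the standalone test at 10000)
#' @param ... bin-filter arguments passed to [fit_median_spline()]
#' @return object of class `"continuity_call"`
#' @export
classify_continuity <- function(x, reference_amfret, alpha = 0.05,
                                n_boot = 100L, rng_seed = 1L,
                                n_mc = 1000L, ...) {
  cells <- if (inherits(x, "damfret_profile")) x$cells else x
  spline <- fit_median_spline(x, n_boot = n_boot, rng_seed = rng_seed, ...)
  call <- list(label = "insufficient_data", dip_stat = NA_real_,
               dip_p = NA_real_, transition = NULL, spline = spline,
               reference_amfret = reference_amfret, alpha = alpha,
               n_window = 0L)
  class(call) <- "continuity_call"
  if (spline$insufficient) return(call)
  tr <- locate_transition(spline)
  call$transition <- tr
  sub_label <- function() {
    smin <- min(spline$fitted)
    send <- spline$fitted[length(spline$fitted)]
    if (smin < reference_amfret && send < reference_amfret)
      "continuous_low"
    else if (smin >= reference_amfret && send >= reference_amfret)
      "continuous_high"
    else "continuous_low_to_high"
  }
  if (tr$flat) { call$label <- sub_label(); return(call) }
  la <- log10(cells$acceptor)
  win <- is.finite(la) & la >= tr$t_start & la <= tr$t_end &
    is.finite(cells$amfret)
  call$n_window <- sum(win)
  if (call$n_window < 4L) { call$label <- "insufficient_data"; return(call) }
  dp <- dip_pvalue(cells$amfret[win], n_mc = n_mc, rng_seed = rng_seed)
  call$dip_stat <- dp$statistic
  call$dip_p <- dp$p_value
  call$label <- if (dp$p_value < alpha) "discontinuous" else sub_label()
  call
}

#' @export
print.continuity_call <- function(x, ...) {
  cat(sprintf("DAmFRET continuity call: %s\n", x$label))
  if (!is.na(x$dip_p))
    cat(sprintf("  dip = %.5f, p = %.4g (alpha = %g, n_window = %d)\n",
                x$dip_stat, x$dip_p, x$alpha, x$n_window))
  if (!is.null(x$transition) && !x$transition$flat)
    cat(sprintf("  transition (log10 acceptor): [%.3f, %.3f], point %.3f\n",
                x$transition$t_start, x$transition$t_end,
                x$transition$t_point))
  invisible(x)
}

#' Majority classification over replicates
#'
#' @param calls list of `"continuity_call"` objects (or character labels)
#' @return list with the modal `label`, the replicate `labels`, and a
#'   `tied` flag (ties resolve to the first-seen label)
#' @export
majority_call <- function(calls) {
  labels <- vapply(calls, function(x)
    if (inherits(x, "continuity_call")) x$label else as.character(x),
    character(1))
  tab <- table(factor(labels, levels = unique(labels)))
  list(label = names(tab)[which.max(tab)], labels = labels,
       tied = sum(tab == max(tab)) > 1L)
}
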