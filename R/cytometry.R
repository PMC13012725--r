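#' Load a per-cell event table
#'
#' CSV is the primary interchange format; the header must contain (or map
#' to, via `channel_map`) the channels `fsc_a`, `fsc_h`, `fsc_w`, `ssc_a`,
#' `autofluor`, `donor`, `acceptor`, `fret`.
#'
#' @param path file path
#' @param format `"csv"`; `"fcs3"` is reserved and currently unsupported
#' @param channel_map optional named character vector mapping file column
#'   names to the canonical channel names (`c(FL09.A = "acceptor", ...)`)
#' @return event table (data.frame)
#' @export
load_events <- function(path, format = c("csv", "fcs3"), channel_map = NULL) {
  format <- match.arg(format)
  if (format == "fcs3")
    stop("FCS 3.0 reading is not supported in this build; export events ",
         "to CSV (see write_events) and use format = 'csv'", call. = FALSE)
  if (!file.exists(path)) stop("cannot read event file: ", path,
                               call. = FALSE)
  ev <- read.csv(path, check.names = FALSE)
  if (!is.null(channel_map)) {
    hit <- names(ev) %in% names(channel_map)
    names(ev)[hit] <- unname(channel_map[names(ev)[hit]])
  }
  required <- c("fsc_a", "fsc_h", "fsc_w", "ssc_a", "autofluor", "donor",
                "acceptor", "fret")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("event table is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ev
}

# solve the logicle parameter d from 2 log(d/b) + w (b + d) = 0
.logicle_params <- function(T, W, M, A) {
  if (!all(is.finite(c(T, W, M, A)))) stop_config(
    "logicle parameters must be finite")
  if (T <= 0 || M <= 0 || W < 0) stop_config(
    "logicle requires T > 0, M > 0, W >= 0")
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- if (w == 0) b else
    uniroot(function(d) 2 * log(d / b) + w * (b + d),
            interval = c(1e-12 * b, b), tol = 1e-14)$root
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / (exp(b) - c_a * exp(-d) - mf_a)
  list(a = a, b = b, c = c_a * a, d = d, f = mf_a * a, w = w, x1 = x1,
       T = T, M = M, A = A)
}

# biexponential scale function: data value at normalized scale position y
.logicle_scale <- function(y, p) {
  p$a * exp(p$b * y) - p$c * exp(-p$d * y) - p$f
}

#' Logicle transform
#'
#' The biexponential display transform standard in flow cytometry: linear
#' around zero (half-width `W` decades), logarithmic at high intensity.
#' `logicle_transform()` maps raw intensities to display decades so that
#' `x = T` maps exactly to `M`; it is strictly monotone and inverted exactly
#' by `inverse_logicle()`. The forward direction is computed by
#' Newton-solving the closed-form inverse to full precision.
#'
#' Used for gating-space coordinates only; binning and all downstream fits
#' operate on raw intensities.
#'
#' @param x raw intensity values (may be negative after compensation)
#' @param y transformed values in decades
#' @param T top of scale (maximal expected data value)
#' @param W linearization half-width in decades
#' @param M number of display decades
#' @param A additional negative decades
#' @return transformed (resp. back-transformed) numeric vector
#' @export
logicle_transform <- function(x, T = 262144, W = 0.5, M = 4.5, A = 0) {
  p <- .logicle_params(T, W, M, A)
  y <- rep(p$x1, length(x))
  y[!is.finite(x)] <- NA_real_
  pos <- is.finite(x)
  if (any(pos)) {
    for (i in 1:100) {
      s <- .logicle_scale(y[pos], p)
      ds <- p$a * p$b * exp(p$b * y[pos]) + p$c * p$d * exp(-p$d * y[pos])
      step <- (s - x[pos]) / ds
      # clamp keeps the iterate in the region where S() cannot overflow
      y[pos] <- pmin(pmax(y[pos] - step, -5), 5)
      if (max(abs(step)) < 1e-13 * max(1, max(abs(y[pos])))) break
    }
  }
  y * (M + A) - A
}

#' @rdname logicle_transform
#' @export
inverse_logicle <- function(y, T = 262144, W = 0.5, M = 4.5, A = 0) {
  p <- .logicle_params(T, W, M, A)
  .logicle_scale((y + A) / (M + A), p)
}

#' Arcsinh transform (fallback display transform)
#'
#' @param x raw intensities
#' @param cofactor linearization cofactor
#' @return transformed vector with attribute `transform = "arcsinh"`
#' @export
arcsinh_transform <- function(x, cofactor = 150) {
  structure(asinh(x / cofactor), transform = "arcsinh", cofactor = cofactor)
}

# even-odd rule point-in-polygon, vectorized over points
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    hit <- cross & (px < xint)
    hit[is.na(hit)] <- FALSE
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

.apply_gate <- function(x, y, gate, what) {
  if (is.matrix(gate) || is.data.frame(gate)) {
    gate <- as.matrix(gate)
    if (nrow(gate) < 3) stop_config(
      "%s: polygon gate needs at least 3 vertices", what)
    .in_polygon(x, y, gate[, 1], gate[, 2])
  } else if (is.numeric(gate) && length(gate) == 4) {
    x >= gate[1] & x <= gate[2] & y >= gate[3] & y <= gate[4]
  } else stop_config(
    "%s: gate must be a polygon matrix or c(xmin, xmax, ymin, ymax)", what)
}

#' Gate single unbudded cells
#'
#' Applies two gates: an FSC-A vs SSC-A gate for intact cells and an
#' FSC-H vs FSC-W gate that excludes doublets (which have roughly twice the
#' singlet width). Each gate is a rectangle `c(xmin, xmax, ymin, ymax)` or a
#' polygon (matrix of vertices, columns x and y).
#'
#' @param events event table
#' @param gate_config list with elements `fsc_ssc` and `hw`
#' @return gated subset, with attribute `gated_fraction`
#' @export
gate_single_cells <- function(events, gate_config) {
  keep <- .apply_gate(events$fsc_a, events$ssc_a, gate_config$fsc_ssc,
                      "fsc_ssc") &
    .apply_gate(events$fsc_h, events$fsc_w, gate_config$hw, "hw")
  out <- events[keep, , drop = FALSE]
  attr(out, "gated_fraction") <- if (nrow(events)) mean(keep) else NA_real_
  out
}

#' Gate expressing cells
#'
#' Retains cells whose donor fluorescence exceeds an
#' autofluorescence-conditional boundary
#' `donor > intercept + slope * autofluor`. An intercept of `-Inf` keeps
#' everything.
#'
#' @param events event table
#' @param gate_config list with `donor_intercept` and optional `donor_slope`
#'   (default 1)
#' @return gated subset, with attribute `gated_fraction`
#' @export
gate_expressing <- function(events, gate_config) {
  icpt <- gate_config$donor_intercept
  if (is.null(icpt)) stop_config("gate_config$donor_intercept is required")
  slope <- gate_config$donor_slope %||% 1
  keep <- events$donor > icpt + slope * events$autofluor
  out <- events[keep, , drop = FALSE]
  attr(out, "gated_fraction") <- if (nrow(events)) mean(keep) else NA_real_
  out
}

#' Compute per-cell AmFRET
#'
#' `amfret = fret / acceptor`. Rows with non-positive acceptor are flagged
#' (`acceptor_ok = FALSE`, `amfret = NA`) and excluded from binning rather
#' than causing failure.
#'
#' @param events event table with `fret` and `acceptor`
#' @return events with added columns `amfret`, `acceptor_ok`
#' @export
compute_amfret <- function(events) {
  ok <- is.finite(events$acceptor) & events$acceptor > 0
  events$amfret <- ifelse(ok, events$fret / events$acceptor, NA_real_)
  events$acceptor_ok <- ok
  events
}

#' Bin events into a 64-bin logarithmic expression profile
#'
#' Divides the acceptor axis into `n_bins` logarithmically spaced bins over
#' a predetermined range (constant log10 step). Bins are half-open
#' `[edge_i, edge_{i+1})`: a cell exactly on an interior edge belongs to the
#' upper bin. Events with non-positive acceptor or outside the range are
#' excluded. Per bin, the count, median AmFRET, IQR and Tukey-fence outlier
#' fraction are recorded; the per-cell values are retained for gating and
#' resampling.
#'
#' @param events event table (AmFRET computed on the fly if absent)
#' @param range_lo,range_hi positive acceptor range bounds
#' @param n_bins number of bins (default 64)
#' @return object of class `"damfret_profile"`
#' @seealso [control_gate()], [fraction_assembled()], [default_bin_range()]
#' @export
bin_log64 <- function(events, range_lo, range_hi, n_bins = 64L) {
  if (!is.finite(range_lo) || !is.finite(range_hi) || range_lo <= 0 ||
      range_hi <= range_lo)
    stop_config("binning requires 0 < range_lo < range_hi")
  if (is.null(events$amfret)) events <- compute_amfret(events)
  edges <- 10^seq(log10(range_lo), log10(range_hi), length.out = n_bins + 1L)
  keep <- events$acceptor_ok & !is.na(events$amfret) &
    events$acceptor >= range_lo & events$acceptor < range_hi
  cells <- data.frame(acceptor = events$acceptor[keep],
                      amfret = events$amfret[keep])
  # half-open bins; findInterval on log axis avoids edge rounding issues
  cells$bin <- findInterval(log10(cells$acceptor), log10(edges),
                            rightmost.closed = FALSE)
  cells$bin <- pmin(cells$bin, n_bins)  # numeric guard at the top edge
  count <- tabulate(cells$bin, n_bins)
  med <- iqr <- outl <- rep(NA_real_, n_bins)
  for (b in which(count > 0)) {
    v <- cells$amfret[cells$bin == b]
    med[b] <- median(v)
    iqr[b] <- iqr7(v)
    outl[b] <- mean(tukey_outlier(v))
  }
  structure(list(
    bin_edges = edges,
    bin_center = sqrt(edges[-1] * edges[-(n_bins + 1L)]),
    count = count, median_amfret = med, iqr_amfret = iqr,
    outlier_fraction = outl,
    cells = cells, n_events = nrow(events), n_binned = nrow(cells),
    range = c(range_lo, range_hi), n_bins = n_bins,
    gate_99 = NULL, frac_assembled = NULL, fgate = NA_real_),
    class = "damfret_profile")
}

#' Default binning range from pooled acceptor intensities
#'
#' The binning range is fixed per experiment; by default it spans the 1st to
#' 99.9th percentile of the pooled positive acceptor intensities of all
#' supplied event tables (control and samples).
#'
#' @param ... event tables
#' @return numeric `c(range_lo, range_hi)`
#' @export
default_bin_range <- function(...) {
  acc <- unlist(lapply(list(...), function(e) e$acceptor), use.names = FALSE)
  acc <- acc[is.finite(acc) & acc > 0]
  if (!length(acc)) stop_config("no positive acceptor values")
  quantile7(acc, c(0.01, 0.999))
}

#' Control-derived per-bin AmFRET gate
#'
#' The no-assembly region of a DAmFRET plot is delineated from a monomer
#' control (mEos alone): the gate in each bin is the `q`-quantile (default
#' 99th percentile, linear-interpolation definition) of the control AmFRET
#' in that bin. Bins without control cells inherit the threshold of the
#' nearest populated bin.
#'
#' @param control_profile [bin_log64()] profile of the monomer control
#' @param q quantile (default 0.99)
#' @return numeric vector of per-bin thresholds (class `"damfret_gate"`)
#' @export
control_gate <- function(control_profile, q = 0.99) {
  stopifnot(inherits(control_profile, "damfret_profile"))
  nb <- control_profile$n_bins
  thr <- rep(NA_real_, nb)
  cells <- control_profile$cells
  if (!nrow(cells)) stop("control profile contains no cells", call. = FALSE)
  for (b in unique(cells$bin))
    thr[b] <- quantile7(cells$amfret[cells$bin == b], q)
  pop <- which(!is.na(thr))
  for (b in which(is.na(thr)))
    thr[b] <- thr[pop[which.min(abs(pop - b))]]
  structure(thr, q = q, class = "damfret_gate")
}

#' Fraction of assembled (FRET-positive) cells
#'
#' Cells strictly above the per-bin control gate are considered to contain
#' assemblies. Adds the per-bin assembled fraction and the overall `fgate`
#' (gross fraction of binned expressing cells above the gate) to the
#' profile.
#'
#' @param profile a [bin_log64()] profile
#' @param gate a [control_gate()] threshold vector
#' @return the profile with `frac_assembled`, `fgate` and `gate_99` filled
#' @export
fraction_assembled <- function(profile, gate) {
  stopifnot(inherits(profile, "damfret_profile"))
  if (length(gate) != profile$n_bins)
    stop_config("gate does not cover the profile bins")
  cells <- profile$cells
  above <- cells$amfret > unclass(gate)[cells$bin]
  frac <- rep(NA_real_, profile$n_bins)
  for (b in which(profile$count > 0)) frac[b] <- mean(above[cells$bin == b])
  profile$gate_99 <- unclass(gate)
  profile$frac_assembled <- frac
  profile$fgate <- if (nrow(cells)) sum(above) / nrow(cells) else NA_real_
  profile
}

#' @export
print.damfret_profile <- function(x, ...) {
  cat(sprintf(
    "DAmFRET profile: %d bins over acceptor [%.3g, %.3g], %d / %d events binned\n",
    x$n_bins, x$range[1], x$range[2], x$n_binned, x$n_events))
  if (!is.na(x$fgate)) cat(sprintf("  fgate = %.4f\n", x$fgate))
  invisible(x)
}

#' @export
plot.damfret_profile <- function(x, ...) {
  ok <- x$count > 0
  plot(x$bin_center[ok], x$median_amfret[ok], log = "x",
       xlab = "acceptor (p.d.u.)", ylab = "median AmFRET",
       pch = 16, col = "grey30", ...)
  if (!is.null(x$gate_99))
    lines(x$bin_center, x$gate_99, col = "red3", lty = 2)
  invisible(x)
}

#' Profile summary as a per-bin data frame
#'
#' @param profile a [bin_log64()] profile
#' @return data.frame with one row per bin
#' @export
profile_table <- function(profile) {
  data.frame(bin = seq_len(profile$n_bins),
             edge_lo = profile$bin_edges[-(profile$n_bins + 1L)],
             edge_hi = profile$bin_edges[-1],
             center = profile$bin_center,
             count = profile$count,
             median_amfret = profile$median_amfret,
             iqr_amfret = profile$iqr_amfret,
             outlier_fraction = profile$outlier_fraction,
             gate = profile$gate_99 %||% rep(NA_real_, profile$n_bins),
             frac_assembled = profile$frac_assembled %||%
               rep(NA_real_, profile$n_bins))
}
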