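# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# All quantiles in the pipeline use one pinned definition: linear
# interpolation between order statistics (R's default type 7).
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

iqr7 <- function(x) {
  q <- quantile7(x, c(0.25, 0.75))
  q[2] - q[1]
}

# Tukey-fence outlier flags (1.5 x IQR beyond the quartiles)
tukey_outlier <- function(x) {
  q <- quantile7(x, c(0.25, 0.75))
  f <- 1.5 * (q[2] - q[1])
  x < q[1] - f | x > q[2] + f
}

# geometric mean over strictly positive values
geometric_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  exp(mean(log(x)))
}

# Gaussian kernel smoothing on an index grid (sd in grid steps)
gauss_smooth <- function(y, sd_pts = 2) {
  n <- length(y)
  if (n < 3 || sd_pts <= 0) return(y)
  half <- min(n - 1L, ceiling(4 * sd_pts))
  k <- stats::dnorm(-half:half, sd = sd_pts)
  idx <- seq_len(n)
  vapply(idx, function(i) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    sum(y[j[ok]] * k[ok]) / sum(k[ok])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
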