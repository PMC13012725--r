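#' Quality-control filter for screen records
#'
#' Drops records with fewer than `min_events` mEos-positive events or mean
#' acceptor intensity below `min_acceptor` p.d.u. (strictly less than), then
#' removes every record of any DFD or seed whose surviving fraction of
#' original instances falls below `min_instance_frac`.
#'
#' @param records screen record table (columns `dfd_id`, `seed_id`,
#'   `n_mEos_pos`, `mean_acceptor`, ...)
#' @param min_events minimal mEos-positive event count (default 2500)
#' @param min_acceptor minimal mean acceptor (default 3.5 p.d.u.)
#' @param min_instance_frac minimal surviving-instance fraction (default
#'   0.25)
#' @return filtered records, with attribute `qc_log` recording counts
#' @export
qc_filter <- function(records, min_events = 2500, min_acceptor = 3.5,
                      min_instance_frac = 0.25) {
  n0 <- nrow(records)
  keep <- records$n_mEos_pos >= min_events &
    records$mean_acceptor >= min_acceptor
  kept <- records[keep, , drop = FALSE]
  orig_dfd <- table(records$dfd_id)
  orig_seed <- table(records$seed_id)
  surv_dfd <- table(factor(kept$dfd_id, levels = names(orig_dfd)))
  surv_seed <- table(factor(kept$seed_id, levels = names(orig_seed)))
  bad_dfd <- names(orig_dfd)[surv_dfd / orig_dfd < min_instance_frac]
  bad_seed <- names(orig_seed)[surv_seed / orig_seed < min_instance_frac]
  kept <- kept[!(kept$dfd_id %in% bad_dfd) & !(kept$seed_id %in% bad_seed), ,
               drop = FALSE]
  if (!nrow(kept))
    stop("all screen records removed by quality control", call. = FALSE)
  attr(kept, "qc_log") <- list(n_input = n0, n_after_thresholds = sum(keep),
                               n_output = nrow(kept),
                               dropped_dfds = bad_dfd,
                               dropped_seeds = bad_seed)
  kept
}

#' Per-batch standardization
#'
#' Standardizes values within each experimental batch to mean 0 and
#' variance 1 (sample SD, n-1 denominator). Single-record batches cannot be
#' standardized; their z is `NA` and a warning names them.
#'
#' @param values numeric vector
#' @param batch_labels batch label per value
#' @return numeric vector of z-scores
#' @export
standardize_batch <- function(values, batch_labels) {
  z <- rep(NA_real_, length(values))
  singles <- character(0)
  for (b in unique(batch_labels)) {
    i <- which(batch_labels == b)
    if (length(i) < 2L || !all(is.finite(values[i]))) {
      singles <- c(singles, b)
      next
    }
    z[i] <- (values[i] - mean(values[i])) / sd(values[i])
  }
  if (length(singles))
    warning("batch(es) with a single record left unstandardized: ",
            paste(singles, collapse = ", "), call. = FALSE)
  z
}

#' Directional outlier degree
#'
#' The number of interquartile ranges a value lies below (direction
#' `"lower_is_seeded"`, used for C50) or above (`"higher_is_seeded"`, used
#' for fgate) the median of all values of one DFD.
#'
#' @param values values of one DFD across seeds (>= 4)
#' @param direction `"lower_is_seeded"` or `"higher_is_seeded"`
#' @return numeric vector of outlier degrees (`NA` with a warning when the
#'   IQR is zero)
#' @export
outlier_degree <- function(values,
                           direction = c("lower_is_seeded",
                                         "higher_is_seeded")) {
  direction <- match.arg(direction)
  if (length(values) < 4)
    stop_config("outlier_degree needs >= 4 values per DFD")
  m <- median(values, na.rm = TRUE)
  iq <- iqr7(values)
  if (!is.finite(iq) || iq == 0) {
    warning("zero IQR: outlier degrees undefined", call. = FALSE)
    return(rep(NA_real_, length(values)))
  }
  if (direction == "lower_is_seeded") (m - values) / iq
  else (values - m) / iq
}

#' Seedability scores for a screen table
#'
#' Standardizes C50 and fgate within each batch, computes per-DFD
#' directional outlier degrees (C50: lower is seeded; fgate: higher is
#' seeded), and averages them into the seedability score.
#'
#' @param records screen records with `dfd_id`, `batch`, `c50`, `fgate`
#' @return records with added `z_c50`, `z_fgate`, `deg_c50`, `deg_fgate`,
#'   `seedability`
#' @export
screen_seedability <- function(records) {
  records$z_c50 <- standardize_batch(records$c50, records$batch)
  records$z_fgate <- standardize_batch(records$fgate, records$batch)
  records$deg_c50 <- NA_real_
  records$deg_fgate <- NA_real_
  for (d in unique(records$dfd_id)) {
    i <- which(records$dfd_id == d)
    records$deg_c50[i] <- outlier_degree(records$z_c50[i], "lower_is_seeded")
    records$deg_fgate[i] <- outlier_degree(records$z_fgate[i],
                                           "higher_is_seeded")
  }
  records$seedability <- (records$deg_c50 + records$deg_fgate) / 2
  records
}

#' Call nucleating-interaction hits
#'
#' A record is a hit when its seedability is at least `n_sd` standard
#' deviations above the mean of all seedability values (default 3 SD,
#' global threshold). With zero spread the threshold is degenerate: no hits
#' are called and the result is flagged.
#'
#' @param records output of [screen_seedability()] (computed on the fly if
#'   the `seedability` column is absent)
#' @param n_sd threshold in SD units (default 3)
#' @param per_dfd compute the threshold per mEos DFD instead of globally
#' @return records with `is_hit`; attributes `hit_threshold` and
#'   `degenerate`
#' @export
call_hits <- function(records, n_sd = 3, per_dfd = FALSE) {
  if (is.null(records$seedability)) records <- screen_seedability(records)
  if (nrow(records) < 10)
    warning("fewer than 10 records: hit threshold unreliable",
            call. = FALSE)
  thr_of <- function(s) mean(s, na.rm = TRUE) + n_sd * sd(s, na.rm = TRUE)
  if (per_dfd) {
    records$is_hit <- FALSE
    thr <- numeric(0)
    for (d in unique(records$dfd_id)) {
      i <- which(records$dfd_id == d)
      t_d <- thr_of(records$seedability[i])
      thr[d] <- t_d
      records$is_hit[i] <- !is.na(records$seedability[i]) &
        records$seedability[i] >= t_d
    }
    degenerate <- FALSE
  } else {
    s <- records$seedability
    sdev <- sd(s, na.rm = TRUE)
    degenerate <- !is.finite(sdev) || sdev == 0
    thr <- if (degenerate) Inf else thr_of(s)
    records$is_hit <- !degenerate & !is.na(s) & s >= thr
  }
  attr(records, "hit_threshold") <- thr
  attr(records, "degenerate") <- degenerate
  records
}

#' Wald confidence interval for an assay consistency rate
#'
#' @param n_pairs number of re-assessed pairs
#' @param n_inconsistent pairs with discordant hit calls
#' @param conf confidence level (default 0.95)
#' @param method `"wald"` (default) or `"wilson"`
#' @return list with `consistency` (percent), `ci95` (percent), `n_pairs`,
#'   `n_inconsistent`
#' @export
consistency_rate <- function(n_pairs, n_inconsistent, conf = 0.95,
                             method = c("wald", "wilson")) {
  method <- match.arg(method)
  p <- (n_pairs - n_inconsistent) / n_pairs
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- if (method == "wald") {
    se <- sqrt(p * (1 - p) / n_pairs)
    c(p - z * se, p + z * se)
  } else {
    den <- 1 + z^2 / n_pairs
    ctr <- (p + z^2 / (2 * n_pairs)) / den
    hw <- z * sqrt(p * (1 - p) / n_pairs + z^2 / (4 * n_pairs^2)) / den
    c(ctr - hw, ctr + hw)
  }
  list(consistency = 100 * p, ci95 = 100 * pmin(pmax(ci, 0), 1),
       n_pairs = n_pairs, n_inconsistent = n_inconsistent)
}

#' Replicate consistency of hit calling
#'
#' Matches two replicate screen tables on (dfd_id, seed_id), counts pairs
#' with discordant `is_hit` flags, and reports the consistency percentage
#' with its Wald 95% CI plus the Pearson correlation of the seedability
#' values (optionally excluding pairs negative in both replicates, which
#' otherwise dominate the correlation with noise).
#'
#' @param report_a,report_b screen tables with `dfd_id`, `seed_id`,
#'   `is_hit`, `seedability`
#' @param exclude_double_negative drop both-negative pairs from the Pearson
#'   correlation (the consistency count always uses all pairs)
#' @param method CI method passed to [consistency_rate()]
#' @return object of class `"screen_consistency"`
#' @export
hit_consistency <- function(report_a, report_b,
                            exclude_double_negative = FALSE,
                            method = "wald") {
  key_a <- paste(report_a$dfd_id, report_a$seed_id)
  key_b <- paste(report_b$dfd_id, report_b$seed_id)
  common <- intersect(key_a, key_b)
  if (!length(common))
    stop("replicates share no (dfd, seed) pairs", call. = FALSE)
  a <- report_a[match(common, key_a), ]
  b <- report_b[match(common, key_b), ]
  disc <- xor(a$is_hit, b$is_hit)
  rate <- consistency_rate(length(common), sum(disc), method = method)
  sel <- if (exclude_double_negative) !(a$is_hit == FALSE & b$is_hit == FALSE)
  else rep(TRUE, length(common))
  r <- if (sum(sel) > 2 && sd(a$seedability[sel]) > 0 &&
           sd(b$seedability[sel]) > 0)
    cor(a$seedability[sel], b$seedability[sel]) else NA_real_
  structure(c(rate, list(pearson_r = r,
                         exclude_double_negative = exclude_double_negative)),
            class = "screen_consistency")
}

#' @export
print.screen_consistency <- function(x, ...) {
  cat(sprintf(
    "Assay consistency: %.2f%% (%d of %d pairs concordant), 95%% CI [%.2f%%, %.2f%%]\n",
    x$consistency, x$n_pairs - x$n_inconsistent, x$n_pairs,
    x$ci95[1], x$ci95[2]))
  if (!is.na(x$pearson_r))
    cat(sprintf("Pearson R (seedability%s) = %.3f\n",
                if (x$exclude_double_negative)
                  ", double negatives excluded" else "", x$pearson_r))
  invisible(x)
}

#' Ward clustering of a seedability matrix
#'
#' Seedability values are floored at 0, shifted by a pseudo-count and
#' log10-transformed, then rows and columns are clustered independently
#' with Ward's variance-minimization linkage on Euclidean distances.
#' Missing cells are imputed as 0 seedability before the transform.
#'
#' @param mat numeric DFD x seed matrix of seedability values
#' @param pseudo pseudo-count (default 1)
#' @return list with `row_hclust`, `col_hclust` (stats::hclust merge trees),
#'   `row_order`, `col_order`, the transformed `matrix`, and a `flagged`
#'   note for degenerate all-equal input
#' @export
cluster_seedability <- function(mat, pseudo = 1) {
  mat[is.na(mat)] <- 0
  lv <- log10(pmax(mat, 0) + pseudo)
  flagged <- length(unique(as.vector(lv))) == 1L
  rh <- hclust(dist(lv), method = "ward.D2")
  ch <- hclust(dist(t(lv)), method = "ward.D2")
  list(row_hclust = rh, col_hclust = ch, row_order = rh$order,
       col_order = ch$order, matrix = lv, flagged = flagged)
}
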