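#' Classify imaged objects by coefficient of variation and aspect ratio
#'
#' Threshold rules, applied in order (primary set): CV > 55 and AR > 1.159
#' = fibrillar; CV > 55 and AR < 1.16 = punctate; CV < 55 and AR < 1.16 =
#' diffuse. The alternate set (for acquisitions at different laser power)
#' uses CV 17/18 and AR 1.4/1.41. All inequalities are strict; CV/AR
#' combinations covered by no rule (including exact boundary values and
#' elongated-but-uniform objects) are left `"unclassified"` rather than
#' forced into a class.
#'
#' @param cv coefficient of variation in percent (100 * SD / mean)
#' @param ar aspect ratio
#' @param threshold_set `"primary"` or `"alternate"`
#' @return character vector of labels
#' @export
classify_morphology <- function(cv, ar,
                                threshold_set = c("primary", "alternate")) {
  threshold_set <- match.arg(threshold_set)
  t <- if (threshold_set == "primary")
    list(fib_cv = 55, fib_ar = 1.159, pun_cv = 55, pun_ar = 1.16,
         dif_cv = 55, dif_ar = 1.16)
  else
    list(fib_cv = 17, fib_ar = 1.4, pun_cv = 17, pun_ar = 1.41,
         dif_cv = 18, dif_ar = 1.41)
  out <- rep("unclassified", length(cv))
  out[cv > t$fib_cv & ar > t$fib_ar] <- "fibrillar"
  pun <- out == "unclassified" & cv > t$pun_cv & ar < t$pun_ar
  out[pun] <- "punctate"
  dif <- out == "unclassified" & cv < t$dif_cv & ar < t$dif_ar
  out[dif] <- "diffuse"
  out[!is.finite(cv) | !is.finite(ar)] <- "unclassified"
  out
}

#' Expected morphology counts under pooled frequencies
#'
#' `expected[class, morph] = n_class * freq_morph`. The pooled frequencies
#' may be rounded values; they must sum to 1 within 0.01.
#'
#' @param group_sizes named vector of group sizes
#' @param pooled_freqs named vector of pooled morphology frequencies
#' @return list with `expected` (matrix) and `expected_rounded` (one
#'   decimal, half rounds up)
#' @export
expected_counts <- function(group_sizes, pooled_freqs) {
  if (abs(sum(pooled_freqs) - 1) > 0.01)
    stop_config("pooled frequencies must sum to 1 (within 0.01)")
  e <- outer(group_sizes, pooled_freqs)
  dimnames(e) <- list(names(group_sizes), names(pooled_freqs))
  # half-up at one decimal (floor(10x + 0.5)/10), the convention of the
  # reported tables; round() would take 7.35 down to 7.3
  list(expected = e, expected_rounded = floor(e * 10 + 0.5) / 10)
}

#' Exact multinomial goodness-of-fit test
#'
#' For observed counts over three categories, `p` is the total probability
#' of all outcomes (compositions of `n` into 3 parts) whose multinomial
#' probability does not exceed that of the observed outcome (ties
#' included). Above `enumeration_max` a seeded Monte-Carlo estimate is used
#' and flagged.
#'
#' @param observed integer vector of 3 counts
#' @param probs expected frequencies (renormalized to sum to 1)
#' @param enumeration_max largest `n` enumerated exactly (default 200)
#' @param n_mc Monte-Carlo draws for larger `n`
#' @param rng_seed seed for the Monte-Carlo fallback
#' @return p-value in (0, 1]; attribute `method` is `"exact"` or
#'   `"monte-carlo"`
#' @export
exact_multinomial_test <- function(observed, probs, enumeration_max = 200L,
                                   n_mc = 100000L, rng_seed = 1L) {
  stopifnot(length(observed) == 3, length(probs) == 3)
  observed <- as.integer(observed)
  probs <- probs / sum(probs)
  n <- sum(observed)
  if (n == 0) return(structure(1, method = "exact"))
  p_obs <- dmultinom(observed, prob = probs)
  tie_tol <- 1 + 1e-7
  if (n <= enumeration_max) {
    total <- 0
    for (i in 0:n) {
      j <- 0:(n - i)
      pj <- vapply(j, function(jj)
        dmultinom(c(i, jj, n - i - jj), prob = probs), numeric(1))
      total <- total + sum(pj[pj <= p_obs * tie_tol])
    }
    structure(min(1, total), method = "exact")
  } else {
    draws <- with_seed(rng_seed,
                       stats::rmultinom(n_mc, size = n, prob = probs))
    pd <- apply(draws, 2, dmultinom, prob = probs)
    structure(mean(pd <= p_obs * tie_tol), method = "monte-carlo")
  }
}

#' Morphology-by-continuity contingency analysis
#'
#' Counts classified objects (or wells) per DAmFRET continuity group,
#' computes expected counts under pooled morphology frequencies, and tests
#' each group against those frequencies with the exact multinomial test,
#' Bonferroni-adjusting across groups. Unclassified objects are excluded
#' from the three-way counts but reported.
#'
#' @param objects data.frame with columns `group` and either `label` or
#'   `cv` + `ar` (classified on the fly)
#' @param pooled_freqs pooled frequencies for `diffuse`, `punctate`,
#'   `fibrillar`; default: pooled over all classified objects
#' @param threshold_set passed to [classify_morphology()]
#' @return object of class `"morph_contingency"`
#' @export
morphology_contingency <- function(objects, pooled_freqs = NULL,
                                   threshold_set = "primary") {
  if (is.null(objects$label))
    objects$label <- classify_morphology(objects$cv, objects$ar,
                                         threshold_set)
  morphs <- c("diffuse", "punctate", "fibrillar")
  cls <- objects[objects$label %in% morphs, , drop = FALSE]
  n_unclassified <- sum(objects$label == "unclassified")
  if (is.null(pooled_freqs)) {
    tab <- table(factor(cls$label, levels = morphs))
    pooled_freqs <- as.numeric(tab) / sum(tab)
    names(pooled_freqs) <- morphs
  }
  groups <- unique(as.character(cls$group))
  observed <- t(vapply(groups, function(g)
    as.integer(table(factor(cls$label[cls$group == g], levels = morphs))),
    integer(3)))
  dimnames(observed) <- list(groups, morphs)
  sizes <- rowSums(observed)
  exp <- expected_counts(sizes, pooled_freqs)
  p_raw <- vapply(groups, function(g)
    as.numeric(exact_multinomial_test(observed[g, ], pooled_freqs)),
    numeric(1))
  structure(list(observed = observed, group_sizes = sizes,
                 pooled_freqs = pooled_freqs,
                 expected = exp$expected,
                 expected_rounded = exp$expected_rounded,
                 p_raw = p_raw,
                 p_adjusted = pmin(1, p_raw * length(groups)),
                 n_unclassified = n_unclassified),
            class = "morph_contingency")
}

#' @export
print.morph_contingency <- function(x, ...) {
  cat("Morphology x continuity contingency\n")
  cat(sprintf("pooled frequencies: %s\n",
              paste(sprintf("%s %.2f", names(x$pooled_freqs),
                            x$pooled_freqs), collapse = ", ")))
  for (g in rownames(x$observed))
    cat(sprintf(
      "  %-22s n=%3d  observed (%s)  expected (%s)  p=%.3g (adj %.3g)\n",
      g, x$group_sizes[g],
      paste(x$observed[g, ], collapse = ", "),
      paste(format(x$expected_rounded[g, ], nsmall = 1), collapse = ", "),
      x$p_raw[g], x$p_adjusted[g]))
  if (x$n_unclassified)
    cat(sprintf("  (%d unclassified objects excluded)\n", x$n_unclassified))
  invisible(x)
}
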