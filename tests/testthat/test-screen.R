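toy_records <- function() {
  data.frame(dfd_id = rep(c("A", "B"), each = 10),
             seed_id = rep(sprintf("s%d", 1:10), 2),
             batch = "b1", replicate = 1L,
             n_mEos_pos = 5000L, mean_acceptor = 10,
             c50 = 100 + rep(0:9, 2), fgate = 0.02)
}

test_that("QC filter applies event, acceptor and instance thresholds", {
  r <- toy_records()
  r$n_mEos_pos[1] <- 2499L            # below the 2500-event threshold
  r$mean_acceptor[2] <- 3.5           # exactly 3.5 is kept (strict less)
  r$mean_acceptor[3] <- 3.4999        # below: dropped
  out <- qc_filter(r)
  expect_false(paste(r$dfd_id[1], r$seed_id[1]) %in%
                 paste(out$dfd_id, out$seed_id))
  expect_true(paste(r$dfd_id[2], r$seed_id[2]) %in%
                 paste(out$dfd_id, out$seed_id))
  expect_false(paste(r$dfd_id[3], r$seed_id[3]) %in%
                 paste(out$dfd_id, out$seed_id))
  # a DFD left with 2/10 instances is removed entirely at stage two
  r2 <- toy_records()
  r2$n_mEos_pos[r2$dfd_id == "A"][1:8] <- 0L
  out2 <- qc_filter(r2)
  expect_false("A" %in% out2$dfd_id)
  expect_equal(sum(out2$dfd_id == "B"), 10)
  r3 <- toy_records(); r3$n_mEos_pos <- 0L
  expect_error(qc_filter(r3), "removed")
})

test_that("per-batch standardization uses the sample-SD convention", {
  z <- standardize_batch(c(1, 2, 3), rep("b", 3))
  expect_equal(z, c(-1, 0, 1))
  x <- c(rnorm(20, 5), rnorm(30, -2, 3))
  b <- rep(c("b1", "b2"), c(20, 30))
  z2 <- standardize_batch(x, b)
  for (bb in c("b1", "b2")) {
    expect_equal(mean(z2[b == bb]), 0, tolerance = 1e-12)
    expect_equal(var(z2[b == bb]), 1, tolerance = 1e-12)
  }
  # shifting one whole batch leaves its z-scores unchanged
  x3 <- x; x3[b == "b1"] <- x3[b == "b1"] + 100
  expect_equal(standardize_batch(x3, b), z2, tolerance = 1e-12)
  expect_warning(standardize_batch(c(1, 2, 3), c("a", "a", "solo")),
                 "single record")
})

test_that("directional outlier degrees", {
  v <- c(4, 9, 10, 11, 12)  # median 10
  iq <- unname(diff(quantile(v, c(0.25, 0.75))))
  d <- outlier_degree(v, "lower_is_seeded")
  expect_equal(d[1], (10 - 4) / iq)
  expect_equal(d[3], 0)                      # value at the median
  expect_equal((10 - 4) / 2, 3)              # iqr 2 gives degree 3
  # negating data with flipped direction gives identical degrees
  expect_equal(outlier_degree(-v, "higher_is_seeded"), d)
  expect_error(outlier_degree(c(1, 2, 3), "lower_is_seeded"), ">= 4")
  expect_warning(outlier_degree(rep(5, 6), "lower_is_seeded"), "zero IQR")
})

test_that("hit calling is threshold-invariant and handles degeneracy", {
  tr <- screen_truth(sprintf("D%02d", 1:10), sprintf("S%02d", 1:10),
                     data.frame(dfd_id = "D01", seed_id = "S05"),
                     rng_seed = 5)
  rec <- screen_seedability(simulate_screen(tr))
  hits <- call_hits(rec)
  # adding a constant to every seedability leaves the hit set unchanged
  rec2 <- rec; rec2$seedability <- rec2$seedability + 10
  expect_equal(call_hits(rec2)$is_hit, hits$is_hit)
  # record order invariance
  perm <- sample(nrow(rec))
  hits_perm <- call_hits(rec[perm, ])
  expect_equal(hits_perm$is_hit, hits$is_hit[perm])
  # all-equal seedability is degenerate: zero hits, flagged
  rec3 <- rec; rec3$seedability <- 1
  deg <- call_hits(rec3)
  expect_true(attr(deg, "degenerate"))
  expect_equal(sum(deg$is_hit), 0)
})

test_that("planted hits are recovered at the 3-SD rule", {
  dfds <- sprintf("D%03d", 1:40)
  seeds <- sprintf("S%03d", 1:40)
  set.seed(61)
  hits <- data.frame(dfd_id = sample(dfds, 20, replace = TRUE),
                     seed_id = sample(seeds, 20, replace = TRUE))
  hits <- hits[!duplicated(hits), ][1:15, ]
  tr <- screen_truth(dfds, seeds, hits, c50_effect = 6, fgate_effect = 6,
                     rng_seed = 62)
  rec <- call_hits(qc_filter(simulate_screen(tr)))
  recall <- sum(rec$is_hit & rec$true_hit) / sum(rec$true_hit)
  fp <- sum(rec$is_hit & !rec$true_hit)
  expect_gte(recall, 0.9)
  expect_lte(fp, 5)
})

test_that("consistency arithmetic and its confidence interval", {
  # half-width of the Wald CI at p = 0.5, n = 100 is 9.8 points
  r <- consistency_rate(100, 50)
  expect_equal(diff(r$ci95) / 2, 9.8, tolerance = 0.002)
  # identical replicates are 100% consistent
  a <- data.frame(dfd_id = "A", seed_id = sprintf("s%d", 1:50),
                  is_hit = rep(c(TRUE, FALSE), 25),
                  seedability = rnorm(50))
  self <- hit_consistency(a, a)
  expect_equal(self$consistency, 100)
  expect_equal(self$n_inconsistent, 0)
  expect_equal(self$pearson_r, 1)
  # a flipped call is counted once
  b <- a; b$is_hit[3] <- !b$is_hit[3]
  expect_equal(hit_consistency(a, b)$n_inconsistent, 1)
  expect_error(hit_consistency(a, data.frame(dfd_id = "Z", seed_id = "q",
                                             is_hit = TRUE,
                                             seedability = 1)),
               "no \\(dfd, seed\\) pairs")
  # double-negative exclusion only affects the correlation
  cc <- hit_consistency(a, b, exclude_double_negative = TRUE)
  expect_equal(cc$n_inconsistent, 1)
})

test_that("Ward clustering groups planted structure", {
  # two identical rows merge first at height 0
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9), c(5, 1, 0))
  cl <- cluster_seedability(m, pseudo = 1)
  expect_equal(sort(cl$row_hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$row_hclust$height[1], 0)
  # 6x6 block matrix: leaf order keeps the two planted blocks contiguous
  blk <- rbind(matrix(8, 3, 6), matrix(0, 3, 6))
  blk[, 4:6] <- blk[, 4:6] + 1
  set.seed(8); blk <- blk + matrix(runif(36, 0, 0.05), 6)
  ord <- cluster_seedability(blk)$row_order
  grp <- (ord <= 3)
  expect_true(all(grp[1:3]) || all(!grp[1:3]))
  # Ward merge sequence equals the greedy minimal-variance oracle
  set.seed(9)
  x <- matrix(rnorm(8), 4, 2)
  lv <- log10(pmax(x, 0) + 1)
  got <- hclust_partitions(cluster_seedability(x)$row_hclust)
  want <- oracle_ward_partitions(lv)
  expect_equal(vapply(got, partition_key, character(1)),
               vapply(want, partition_key, character(1)))
})
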