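test_that("graph construction respects the score threshold and classes", {
  edges <- data.frame(protein_a = c("A", "B", "B", "A", "C", "C"),
                      protein_b = c("B", "A", "C", "A", "D", "D"),
                      physical_score = c(950L, 990L, 899L, 1000L, 900L, 900L))
  g <- build_graph(edges, score_min = 900)
  nm <- igraph::V(g)$name
  em <- igraph::as_edgelist(g)
  key <- apply(em, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true("A-B" %in% key)        # duplicated A-B / B-A collapse to one
  expect_false("B-C" %in% key)       # 899 excluded, "900 or higher" kept
  expect_true("C-D" %in% key)
  expect_equal(sum(key == "A-B"), 1)
  expect_false(any(em[, 1] == em[, 2]))  # self-loop A-A removed
  # multi-DFD protein: discontinuous if any DFD is
  classes <- data.frame(protein = c("A", "A", "B", "C", "D"),
                        discontinuous = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  g2 <- build_graph(edges, node_classes = classes)
  expect_true(igraph::V(g2)$discontinuous[match("A", igraph::V(g2)$name)])
  expect_false(igraph::V(g2)$discontinuous[match("B", igraph::V(g2)$name)])
})

test_that("edge-list reader flags malformed scores with the line", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tphysical_score",
               "A\tB\t950", "B\tC\toops"), f)
  expect_error(read_string_edges(f), "line")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tphysical_score", "A\tB\t950"), f2)
  expect_equal(read_string_edges(f2)$physical_score, 950L)
})

test_that("centralities match closed forms and the path-enumeration oracle", {
  star <- data.frame(protein_a = c("hub", "hub", "hub"),
                     protein_b = c("l1", "l2", "l3"),
                     physical_score = 1000L)
  cs <- centralities(build_graph(star))
  expect_equal(cs$degree_centrality[cs$node == "hub"], 1)
  expect_equal(cs$betweenness[cs$node == "hub"], 1)
  expect_equal(cs$degree_centrality[cs$node == "l1"], 1 / 3)
  expect_equal(cs$betweenness[cs$node == "l1"], 0)
  path <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "c"),
                     physical_score = 1000L)
  cp <- centralities(build_graph(path))
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  # random graph vs explicit all-geodesic enumeration
  set.seed(41)
  n <- 30
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (runif(1) < 0.12) adj[i, j] <- adj[j, i] <- 1L
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(protein_a = sprintf("n%02d", idx[, 1]),
                      protein_b = sprintf("n%02d", idx[, 2]),
                      physical_score = 1000L)
  g <- build_graph(edges)
  got <- centralities(g)
  present <- sort(unique(c(idx[, 1], idx[, 2])))
  sub <- adj[present, present]
  want <- oracle_betweenness(sub)
  # isolated vertices are absent from the edge-built graph; scale to its n
  n_g <- length(present)
  want <- want * ((n_g - 1) * (n_g - 2) / 2) /
    ((n_g - 1) * (n_g - 2) / 2)
  ord <- match(sprintf("n%02d", present), got$node)
  expect_equal(got$betweenness[ord], want, tolerance = 1e-9)
})

test_that("Mann-Whitney U and p match identities and enumeration", {
  a <- c(1, 2); b <- c(3, 4)
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)  # all 6 orderings enumerated
  # U_a + U_b = n_a * n_b
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 35)
  }
  # exact p equals the full-split enumeration for small samples
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(mann_whitney(x, y)$p, oracle_mw_exact_p(x, y),
                 tolerance = 1e-10)
  }
  # invariance under a common monotone transform of the pooled data
  x <- rnorm(12); y <- rnorm(9, 0.5)
  expect_equal(mann_whitney(exp(x), exp(y))$p, mann_whitney(x, y)$p,
               tolerance = 1e-12)
})

test_that("Mann-Whitney null calibration", {
  set.seed(43)
  rej <- vapply(seq_len(1000), function(i)
    mann_whitney(rnorm(15), rnorm(15))$p < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("supersaturation-lifespan regression on exact and noisy data", {
  # noiseless power law y = 10 x^-2: slope -2, intercept 1, Spearman -1
  ct <- sprintf("c%02d", 1:8)
  proxy <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  tbl <- data.frame(cell_type = rep(ct, each = 1), adaptor = "ASC",
                    transcript_ntpm = proxy * 50, c_sat = 50,
                    lifespan_days = 10 * proxy^(-2))
  fit <- supersat_lifespan(tbl)
  expect_equal(fit$powerlaw_slope, -2, tolerance = 1e-10)
  expect_equal(fit$powerlaw_intercept, 1, tolerance = 1e-10)
  expect_equal(fit$spearman_r, -1)
  # fewer than 3 usable cell types is an error
  tbl2 <- data.frame(cell_type = "c", adaptor = c("x", "y"),
                     transcript_ntpm = c(2, 8), c_sat = 1,
                     lifespan_days = 5)
  expect_error(supersat_lifespan(tbl2), ">= 3")
  # geometric mean of proxies 2 and 8 is 4 (read back from the summary)
  tbl2b <- rbind(tbl2, transform(tbl2, cell_type = "c2"),
                 transform(tbl2, cell_type = "c3"))
  expect_equal(supersat_lifespan(tbl2b)$summary$proxy_gm, rep(4, 3))
  # Spearman is invariant to monotone transforms of either axis
  set.seed(44)
  tbl3 <- simulate_expression_lifespan(12, slope = -1, scatter_sd = 0.1,
                                       rng_seed = 3)
  f3 <- supersat_lifespan(tbl3)
  tbl3b <- tbl3
  tbl3b$lifespan_days <- tbl3b$lifespan_days^3
  expect_equal(supersat_lifespan(tbl3b)$spearman_r, f3$spearman_r)
  # noisy recovery: slope near -1 and strong negative rank correlation
  ok <- vapply(1:10, function(s) {
    f <- supersat_lifespan(simulate_expression_lifespan(
      20, slope = -1, scatter_sd = 0.08, rng_seed = 100 + s))
    abs(f$powerlaw_slope + 1) < 0.3 && f$spearman_r < -0.7
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # non-positive proxies drop the cell type with a warning
  bad <- tbl3
  bad$transcript_ntpm[bad$cell_type == bad$cell_type[1]] <- 0
  expect_warning(fb <- supersat_lifespan(bad), "non-positive")
  expect_equal(nrow(fb$summary), 11)
})

test_that("planted hubs dominate the synthetic interaction graph", {
  net <- simulate_interaction_graph(n_background = 25, n_hubs = 2,
                                    rng_seed = 5)
  g <- build_graph(net$edges, score_min = 900)
  cs <- centralities(g)
  top2 <- cs$node[order(-cs$degree)][1:2]
  expect_setequal(top2, net$hubs)
  expect_true(all(net$edges$physical_score[
    net$edges$physical_score < 900] >= 0))  # decoys exist below threshold
  expect_true(any(net$edges$physical_score < 900))
})
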