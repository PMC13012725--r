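make_events <- function(n = 1000, seed = 1) {
  simulate_events(damfret_model("continuous", n_cells = n, rng_seed = seed))
}

test_that("event loading validates the schema", {
  ev <- make_events(5)
  f <- tempfile(fileext = ".csv")
  write_events(ev, f)
  got <- load_events(f)
  expect_equal(nrow(got), 5)
  expect_equal(got$acceptor, ev$acceptor, tolerance = 1e-12)
  # missing channel is a schema error naming the channel
  broken <- read.csv(f)
  broken$acceptor <- NULL
  f2 <- tempfile(fileext = ".csv")
  write.csv(broken, f2, row.names = FALSE)
  expect_error(load_events(f2), "acceptor")
  # channel mapping renames instrument columns
  renamed <- read.csv(f)
  names(renamed)[names(renamed) == "acceptor"] <- "FL09.A"
  f3 <- tempfile(fileext = ".csv")
  write.csv(renamed, f3, row.names = FALSE)
  got3 <- load_events(f3, channel_map = c(FL09.A = "acceptor"))
  expect_equal(got3$acceptor, ev$acceptor, tolerance = 1e-12)
  expect_error(load_events(f, format = "fcs3"), "not supported")
  expect_error(load_events(tempfile()), "cannot read")
})

test_that("logicle transform is monotone, anchored at T, and invertible", {
  T <- 262144; M <- 4.5; W <- 0.5
  expect_equal(logicle_transform(T, T, W, M), M, tolerance = 1e-9)
  set.seed(4)
  x <- sort(runif(1000, -0.1 * T, T))
  y <- logicle_transform(x, T, W, M)
  expect_true(all(diff(y) > 0))
  # round trip to 1e-9 relative over [-0.1 T, T]
  back <- inverse_logicle(y, T, W, M)
  expect_equal(back, x, tolerance = 1e-9)
  expect_error(logicle_transform(1, T = -5), "T > 0")
  expect_error(logicle_transform(1, T = Inf), "finite")
})

test_that("gates subset events as configured", {
  ev <- make_events(2000, seed = 2)
  all_rect <- list(fsc_ssc = c(-Inf, Inf, -Inf, Inf),
                   hw = c(-Inf, Inf, -Inf, Inf))
  expect_equal(nrow(gate_single_cells(ev, all_rect)), nrow(ev))
  none <- list(fsc_ssc = c(0, 1, 0, 1), hw = c(-Inf, Inf, -Inf, Inf))
  expect_equal(nrow(gate_single_cells(ev, none)), 0)
  # planted doublets at twice the singlet width are excluded by the H/W gate
  doublets <- ev
  doublets$fsc_w <- 140
  mixed <- rbind(ev, doublets)
  g <- gate_single_cells(mixed, list(fsc_ssc = c(-Inf, Inf, -Inf, Inf),
                                     hw = c(-Inf, Inf, 0, 100)))
  expect_equal(nrow(g), nrow(ev))
  expect_equal(attr(g, "gated_fraction"), 0.5)
  # polygon gate: triangle covering the whole fsc/ssc cloud
  tri <- cbind(c(0, 1e6, 0), c(0, 0, 1e6))
  g2 <- gate_single_cells(ev, list(fsc_ssc = tri,
                                   hw = c(-Inf, Inf, -Inf, Inf)))
  expect_equal(nrow(g2), nrow(ev))
  expect_error(gate_single_cells(ev, list(fsc_ssc = tri[1:2, ],
                                          hw = c(-Inf, Inf, -Inf, Inf))),
               "3 vertices")
})

test_that("expression gate removes non-expressing cells", {
  ev <- make_events(1000, seed = 3)
  expect_equal(nrow(gate_expressing(ev, list(donor_intercept = -Inf))),
               nrow(ev))
  # planted non-expressing population with donor at autofluorescence level
  dark <- ev
  dark$donor <- dark$autofluor
  mixed <- rbind(ev, dark)
  g <- gate_expressing(mixed, list(donor_intercept = 100, donor_slope = 1))
  expect_true(nrow(g) <= nrow(ev) + 5)
  expect_identical(gate_expressing(ev, list(donor_intercept = 100)),
                   gate_expressing(ev, list(donor_intercept = 100)))
})

test_that("AmFRET arithmetic and division guard", {
  ev <- data.frame(fret = c(0, 2, 3, 5), acceptor = c(10, 4, 6, 0))
  out <- compute_amfret(ev)
  expect_equal(out$amfret[1:3], c(0, 0.5, 0.5))
  expect_true(is.na(out$amfret[4]) && !out$acceptor_ok[4])
})

test_that("log binning uses 64 constant-log-step half-open bins", {
  ev <- make_events(5000, seed = 4)
  p <- bin_log64(ev, 1, 1e4)
  expect_equal(length(p$bin_edges), 65)
  steps <- diff(log10(p$bin_edges))
  expect_equal(steps, rep(4 / 64, 64), tolerance = 1e-12)  # step 0.0625
  expect_lte(p$n_binned, nrow(ev))
  # a cell exactly on the edge between bins i and i+1 lands in bin i+1
  edge_val <- p$bin_edges[11]
  ev2 <- data.frame(fret = 0.1, acceptor = edge_val)
  p2 <- bin_log64(compute_amfret(ev2), 1, 1e4)
  expect_equal(which(p2$count == 1), 11)
  expect_error(bin_log64(ev, -1, 10), "range")
  # uniform-in-log acceptor fills bins evenly (chi-square vs uniform)
  set.seed(9)
  evu <- data.frame(acceptor = 10^runif(64000, 0, 4), fret = 1)
  pu <- bin_log64(compute_amfret(evu), 1, 1e4)
  chi <- sum((pu$count - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 63))
})

test_that("control gate uses the pinned quantile and inherits into gaps", {
  # constant control AmFRET: every threshold equals that constant
  evc <- data.frame(acceptor = 10^runif(2000, 0, 4))
  evc$fret <- 0.1 * evc$acceptor
  pc <- bin_log64(compute_amfret(evc), 1, 1e4)
  g <- control_gate(pc)
  expect_equal(as.numeric(g), rep(0.1, 64), tolerance = 1e-12)
  # a bin holding 1..100 has 99th percentile 99.01 under type-7 quantiles
  ev1 <- data.frame(acceptor = rep(2, 100), fret = 2 * (1:100))
  p1 <- bin_log64(compute_amfret(ev1), 1, 1e4)
  g1 <- control_gate(p1)
  b <- which(p1$count == 100)
  expect_equal(as.numeric(g1)[b], 99.01, tolerance = 1e-9)
  # q = 1 gives the bin maximum; empty bins inherit the nearest threshold
  gmax <- control_gate(p1, q = 1)
  expect_equal(as.numeric(gmax)[b], 100)
  expect_equal(as.numeric(g1), rep(as.numeric(g1)[b], 64))
})

test_that("fraction assembled counts strictly-above cells", {
  ev <- data.frame(acceptor = rep(10, 100), fret = c(rep(5, 30), rep(0.1, 70)))
  p <- bin_log64(compute_amfret(ev), 1, 1e4)
  gate <- structure(rep(0.2, 64), class = "damfret_gate")
  p <- fraction_assembled(p, gate)
  expect_equal(p$fgate, 0.30)
  gate0 <- structure(rep(10, 64), class = "damfret_gate")
  expect_equal(fraction_assembled(p, gate0)$fgate, 0)
  gate1 <- structure(rep(-1, 64), class = "damfret_gate")
  expect_equal(fraction_assembled(p, gate1)$fgate, 1)
})

test_that("fgate is invariant under common monotone acceptor rescaling", {
  ev <- make_events(20000, seed = 6)
  ctrl <- simulate_events(damfret_model("monomer", n_cells = 20000,
                                        rng_seed = 7))
  build <- function(scale) {
    e <- ev; c <- ctrl
    e$acceptor <- e$acceptor * scale; e$fret <- e$fret * scale
    c$acceptor <- c$acceptor * scale; c$fret <- c$fret * scale
    rng <- default_bin_range(e, c) # quantiles scale with the data
    p <- bin_log64(e, rng[1], rng[2])
    fraction_assembled(p, control_gate(bin_log64(c, rng[1], rng[2])))$fgate
  }
  expect_equal(build(1), build(37.5), tolerance = 1e-12)
})

test_that("seeding raises fgate and monomer stays within the gate budget", {
  n <- 30000
  ctrl <- simulate_events(damfret_model("monomer", n_cells = n,
                                        rng_seed = 8))
  disc <- simulate_events(damfret_model("discontinuous", n_cells = n,
                                        rng_seed = 9))
  seeded <- simulate_events(damfret_model("seeded", c50_seeded = 100,
                                          n_cells = n, rng_seed = 10))
  rng <- default_bin_range(ctrl, disc, seeded)
  gate <- control_gate(bin_log64(ctrl, rng[1], rng[2]))
  f <- function(e) fraction_assembled(bin_log64(e, rng[1], rng[2]),
                                      gate)$fgate
  expect_gt(f(seeded), f(disc))   # seeds move all cells above the gate
  # the control against its own 99th-percentile gate: ~1% positives
  expect_lte(f(ctrl), 0.02)
})
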