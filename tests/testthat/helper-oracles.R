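# Independent oracles used to validate package implementations. Each is a
# direct, slow restatement of the defining computation and shares no code
# with the implementation it checks.

# ---- dip statistic: definitional band-feasibility oracle -------------------
# dip(x) = min over unimodal cdfs G of sup |F_n - G|. Feasibility of a
# unimodal cdf within a sup-norm band of half-width rho around the ecdf is
# decided exactly (convex piece, optional atom at the mode, concave piece),
# and rho is bisected. Suitable for small n only.

oracle_hull_lower <- function(v, y) {
  K <- length(v)
  if (K == 1L) return(y)
  h <- integer(0)
  for (i in seq_len(K)) {
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]; b <- h[length(h)]
      if ((y[b] - y[a]) * (v[i] - v[a]) >= (y[i] - y[a]) * (v[b] - v[a]))
        h <- h[-length(h)]
      else break
    }
    h <- c(h, i)
  }
  stats::approx(v[h], y[h], xout = v, rule = 2)$y
}

oracle_convex_feasible <- function(v, lo, hi, eps = 1e-12) {
  if (any(hi < lo - eps)) return(FALSE)
  all(oracle_hull_lower(v, hi) >= lo - eps)
}

oracle_convex_inf_terminal <- function(v, lo, hi, eps = 1e-12, iters = 60L) {
  m <- length(v)
  if (!oracle_convex_feasible(v, lo, hi, eps)) return(Inf)
  if (m == 1L) return(lo[1])
  a <- lo[m]; b <- hi[m]
  for (i in seq_len(iters)) {
    t <- (a + b) / 2
    hi2 <- hi; hi2[m] <- t
    if (oracle_convex_feasible(v, lo, hi2, eps)) b <- t else a <- t
  }
  b
}

oracle_concave_sup_initial <- function(v, lo, hi, eps = 1e-12) {
  1 - oracle_convex_inf_terminal(rev(-v), rev(1 - hi), rev(1 - lo), eps)
}

oracle_concave_feasible <- function(v, lo, hi, eps = 1e-12) {
  oracle_convex_feasible(rev(-v), rev(1 - hi), rev(1 - lo), eps)
}

oracle_band_feasible <- function(v, Fk, Fl, rho, eps = 1e-12) {
  K <- length(v)
  lo <- pmax(0, Fk - rho)
  hi <- pmin(1, Fl + rho)
  if (oracle_concave_feasible(v, lo, hi, eps)) return(TRUE)
  if (oracle_convex_feasible(v, lo, hi, eps)) return(TRUE)
  for (m in seq_len(K)) {   # atom at node m
    loL <- lo[seq_len(m)]; hiL <- hi[seq_len(m)]
    loL[m] <- max(0, Fl[m] - rho); hiL[m] <- min(1, Fl[m] + rho)
    loR <- lo[m:K]; hiR <- hi[m:K]
    loR[1] <- max(0, Fk[m] - rho); hiR[1] <- min(1, Fk[m] + rho)
    gi <- oracle_convex_inf_terminal(v[seq_len(m)], loL, hiL, eps)
    if (!is.finite(gi)) next
    hs <- oracle_concave_sup_initial(v[m:K], loR, hiR, eps)
    if (gi <= hs + 1e-10) return(TRUE)
  }
  for (m in seq_len(K - 1)) {   # mode in the open gap (v_m, v_{m+1})
    idxL <- seq_len(m); idxR <- (m + 1):K
    gapU <- min(1, Fk[m] + rho); gapL <- max(0, Fk[m] - rho)
    giext <- oracle_convex_inf_terminal(c(v[idxL], v[m + 1]),
                                        c(lo[idxL], 0),
                                        c(hi[idxL], gapU), eps)
    if (is.finite(giext)) {
      hs <- oracle_concave_sup_initial(v[idxR], lo[idxR], hi[idxR], eps)
      if (giext <= hs + 1e-10) return(TRUE)
    }
    gi <- oracle_convex_inf_terminal(v[idxL], lo[idxL], hi[idxL], eps)
    if (is.finite(gi)) {
      hsext <- oracle_concave_sup_initial(c(v[m], v[idxR]),
                                          c(gapL, lo[idxR]),
                                          c(1, hi[idxR]), eps)
      if (gi <= hsext + 1e-10) return(TRUE)
    }
  }
  FALSE
}

oracle_dip <- function(x, iters = 50L) {
  x <- sort(x)
  n <- length(x)
  v <- unique(x)
  if (length(v) == 1L) return(0)
  cnt <- cumsum(tabulate(match(x, v), length(v)))
  Fk <- cnt / n
  Fl <- c(0, Fk[-length(Fk)])
  a <- 0; b <- 0.5
  for (i in seq_len(iters)) {
    rho <- (a + b) / 2
    if (oracle_band_feasible(v, Fk, Fl, rho)) b <- rho else a <- rho
  }
  b
}

# ---- betweenness centrality: explicit shortest-path enumeration ------------
# BFS per source builds the shortest-path DAG; all geodesics are enumerated
# recursively and each interior node credited its fraction per pair.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(dag_parents, s, t) {
    if (t == s) return(list(s))
    out <- list()
    for (p in dag_parents[[t]])
      for (pp in all_paths(dag_parents, s, p)) out <- c(out, list(c(pp, t)))
    out
  }
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    parents <- vector("list", n)
    q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in which(adj[u, ] > 0)) {
        if (dist[v] == Inf) { dist[v] <- dist[u] + 1; q <- c(q, v) }
        if (dist[v] == dist[u] + 1) parents[[v]] <- c(parents[[v]], u)
      }
    }
    for (t in seq_len(n)) {
      if (t <= s || !is.finite(dist[t])) next
      paths <- all_paths(parents, s, t)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# ---- exact multinomial test: outcome-sequence enumeration ------------------
# Enumerates all 3^n category sequences with their probabilities; p is the
# total probability of sequences whose outcome composition is no more
# probable than the observed one.
oracle_multinomial_p <- function(observed, probs) {
  probs <- probs / sum(probs)
  n <- sum(observed)
  seqs <- as.matrix(expand.grid(rep(list(1:3), n)))
  comp <- t(apply(seqs, 1, function(s) tabulate(s, 3)))
  seq_p <- apply(seqs, 1, function(s) prod(probs[s]))
  comp_p <- apply(comp, 1, function(k)
    factorial(n) / prod(factorial(k)) * prod(probs^k))
  p_obs <- factorial(n) / prod(factorial(observed)) *
    prod(probs^observed)
  sum(seq_p[comp_p <= p_obs * (1 + 1e-9)])
}

# ---- Ward clustering: greedy minimal-variance merge oracle -----------------
# Repeatedly merges the pair of clusters with the smallest increase in
# within-cluster sum of squares; returns the sequence of merged partitions.
oracle_ward_partitions <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  partitions <- list()
  dESS <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
    length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- dESS(clusters[[i]], clusters[[j]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions <- c(partitions,
                    list(lapply(clusters, function(cl) sort(cl))))
  }
  partitions
}

hclust_partitions <- function(hc) {
  n <- length(hc$order)
  partitions <- list()
  for (k in (n - 1):1) {
    cut <- stats::cutree(hc, k = k)
    partitions <- c(partitions,
                    list(unname(lapply(split(seq_len(n), cut), sort))))
  }
  partitions
}

partition_key <- function(p) {
  paste(sort(vapply(p, function(cl) paste(cl, collapse = ","),
                    character(1))), collapse = " | ")
}

# ---- Mann-Whitney exact p: full split enumeration --------------------------
# Two-sided exact p under the null that every assignment of the pooled
# values to the two groups is equally likely.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  splits <- utils::combn(length(pooled), na)
  u_all <- apply(splits, 2, u_of)
  mu <- na * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# ---- shared synthetic panel evaluation -------------------------------------
panel_labels <- function(rng_seed, n_cells = 50000L) {
  models <- damfret_panel_models(n_cells = n_cells, rng_seed = rng_seed)
  events <- lapply(models, simulate_events)
  rng <- do.call(default_bin_range, unname(events))
  profiles <- lapply(events, function(e) bin_log64(e, rng[1], rng[2]))
  gate <- control_gate(profiles$monomer)
  profiles <- lapply(profiles, fraction_assembled, gate = gate)
  ref <- amfret_reference(profiles$monomer)
  vapply(names(profiles), function(nm)
    classify_continuity(profiles[[nm]], reference_amfret = ref,
                        rng_seed = rng_seed)$label, character(1))
}

panel_expected_labels <- c(monomer = "continuous_low",
                           continuous = "continuous_low_to_high",
                           discontinuous = "discontinuous",
                           seeded = "continuous_high")
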