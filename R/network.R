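#' Read a STRING-style physical-interaction edge list
#'
#' Tab-separated columns `protein_a`, `protein_b`, `physical_score`
#' (integer 0-1000). Malformed rows raise an error naming the line.
#'
#' @param path file path
#' @return data.frame edge list
#' @export
read_string_edges <- function(path) {
  e <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "physical_score")
  if (!all(need %in% names(e)))
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  score <- suppressWarnings(as.numeric(e$physical_score))
  bad <- which(!is.finite(score) | score < 0 | score > 1000 |
                 score != round(score))
  if (length(bad))
    stop("malformed physical_score at line(s) ",
         paste(head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  e$physical_score <- as.integer(score)
  e
}

#' Build the physical-interaction subnetwork
#'
#' Keeps edges with score at least `score_min` (default 900), removes
#' self-loops and duplicate / reversed pairs, and annotates nodes with
#' continuity and seedability classes. A protein with several DFDs is
#' classified discontinuous (resp. seedable) if any of its DFDs is.
#'
#' @param edge_list data.frame with `protein_a`, `protein_b`,
#'   `physical_score`
#' @param score_min minimal physical score (default 900, "900 or higher")
#' @param node_classes optional data.frame with columns `protein`,
#'   `discontinuous` (logical) and/or `seedable` (logical); one row per DFD
#'   is allowed and aggregated by any()
#' @return an igraph undirected simple graph
#' @export
build_graph <- function(edge_list, score_min = 900, node_classes = NULL) {
  keep <- edge_list$physical_score >= score_min
  e <- edge_list[keep, c("protein_a", "protein_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(node_classes)) {
    for (cl in intersect(c("discontinuous", "seedable"),
                         names(node_classes))) {
      agg <- tapply(node_classes[[cl]], node_classes$protein, any)
      val <- unname(agg[igraph::V(g)$name])
      g <- igraph::set_vertex_attr(g, cl, value = val)
    }
  }
  g
}

#' Degree and betweenness centrality
#'
#' Degree centrality is degree / (n - 1); betweenness is normalized
#' shortest-path betweenness (equal-length paths split evenly, undirected
#' normalization 2 / ((n-1)(n-2))).
#'
#' @param graph an igraph graph
#' @return data.frame with `node`, `degree`, `degree_centrality`,
#'   `betweenness`
#' @export
centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(graph)
  dc <- if (n > 1) deg / (n - 1) else 0 * deg
  btw <- if (n > 2) igraph::betweenness(graph, normalized = TRUE)
  else 0 * deg
  data.frame(node = igraph::V(graph)$name, degree = as.integer(deg),
             degree_centrality = unname(dc), betweenness = unname(btw),
             row.names = NULL)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midrank ties; the p-value is exact for small
#' samples without ties and uses the tie-corrected normal approximation
#' (with continuity correction) otherwise.
#'
#' @param sample_a,sample_b numeric samples
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return list with `U` (for sample_a), `p`, `n_a`, `n_b`
#' @export
mann_whitney <- function(sample_a, sample_b, alternative = "two.sided") {
  if (!length(sample_a) || !length(sample_b))
    stop_config("both samples must be non-empty")
  r <- rank(c(sample_a, sample_b))
  na <- length(sample_a)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = alternative,
                correct = TRUE))
  list(U = unname(U), p = wt$p.value, n_a = na, n_b = length(sample_b))
}

#' Supersaturation-lifespan power-law regression
#'
#' Per cell type, the supersaturation proxy of each adaptor is its
#' transcript level divided by its saturation concentration; the geometric
#' mean across adaptors (strictly positive proxies only; non-positive
#' proxies drop the cell type with a warning) summarizes the cell type.
#' Mean lifespan is regressed on the proxy in log10-log10 space (a power
#' law), with a 95% confidence band, and the Spearman rank correlation is
#' reported with its two-sided p-value (exact for small n without ties).
#'
#' @param table data.frame with `cell_type`, `adaptor`, `transcript_ntpm`,
#'   `c_sat`, `lifespan_days` (see [simulate_expression_lifespan()])
#' @return object of class `"supersat_lifespan_fit"` with `spearman_r`,
#'   `spearman_p`, `powerlaw_slope`, `powerlaw_intercept`, `ci_band`,
#'   `summary` (per-cell-type table), `lm`
#' @export
supersat_lifespan <- function(table) {
  need <- c("cell_type", "adaptor", "transcript_ntpm", "c_sat",
            "lifespan_days")
  stopifnot(all(need %in% names(table)))
  cts <- unique(table$cell_type)
  rows <- lapply(cts, function(ct) {
    d <- table[table$cell_type == ct, ]
    proxy <- d$transcript_ntpm / d$c_sat
    if (any(!is.finite(proxy) | proxy <= 0)) {
      warning("cell type '", ct, "' dropped: non-positive proxy",
              call. = FALSE)
      return(NULL)
    }
    data.frame(cell_type = ct, proxy_gm = geometric_mean(proxy),
               lifespan = d$lifespan_days[1])
  })
  s <- do.call(rbind, rows)
  if (is.null(s) || nrow(s) < 3)
    stop("need >= 3 cell types with positive proxies", call. = FALSE)
  s$log_proxy <- log10(s$proxy_gm)
  s$log_life <- log10(s$lifespan)
  fit <- lm(log_life ~ log_proxy, data = s)
  grid <- data.frame(log_proxy = seq(min(s$log_proxy), max(s$log_proxy),
                                     length.out = 100))
  band <- cbind(grid, predict(fit, grid, interval = "confidence",
                              level = 0.95))
  ct <- suppressWarnings(cor.test(s$proxy_gm, s$lifespan,
                                  method = "spearman"))
  structure(list(spearman_r = unname(ct$estimate),
                 spearman_p = ct$p.value,
                 powerlaw_slope = unname(coef(fit)[2]),
                 powerlaw_intercept = unname(coef(fit)[1]),
                 ci_band = band, summary = s, lm = fit),
            class = "supersat_lifespan_fit")
}

#' @export
print.supersat_lifespan_fit <- function(x, ...) {
  cat(sprintf(
    "Supersaturation-lifespan power law: lifespan ~ proxy^%.3f (log10 intercept %.3f)\n",
    x$powerlaw_slope, x$powerlaw_intercept))
  cat(sprintf("Spearman R = %.4f (two-tailed p = %.3g), %d cell types\n",
              x$spearman_r, x$spearman_p, nrow(x$summary)))
  invisible(x)
}

#' @export
plot.supersat_lifespan_fit <- function(x, ...) {
  s <- x$summary
  plot(s$proxy_gm, s$lifespan, log = "xy",
       xlab = "geometric-mean adaptor supersaturation (transcript / C_sat)",
       ylab = "mean lifespan (days)", pch = 16, ...)
  b <- x$ci_band
  lines(10^b$log_proxy, 10^b$fit, col = "red3", lwd = 2)
  lines(10^b$log_proxy, 10^b$lwr, col = "red3", lty = 3)
  lines(10^b$log_proxy, 10^b$upr, col = "red3", lty = 3)
  invisible(x)
}
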