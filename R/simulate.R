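#' Stretched-exponential (Weibull) assembly curve
#'
#' The mean AmFRET of assembled cells as a function of concentration,
#' \deqn{AmFRET(c) = Amp (1 - e^{-\ln 2 \, (c/C50)^a}),}
#' where `Amp` is the asymptotic AmFRET plateau, `C50` the concentration at
#' which the curve reaches half its plateau (so `AmFRET(C50) = Amp/2`
#' exactly), and `a` the steepness of the stretched exponential.
#'
#' @param c concentration (acceptor intensity, procedure-defined units)
#' @param amp AmFRET plateau (dimensionless, > 0)
#' @param c50 half-plateau concentration (> 0)
#' @param a steepness exponent
#' @return numeric vector of AmFRET values
#' @export
#' @examples
#' amfret_weibull(100, amp = 0.6, c50 = 100, a = 2) # = 0.3 = amp/2
amfret_weibull <- function(c, amp, c50, a) {
  amp * (1 - exp(-log(2) * (c / c50)^a))
}

#' Generative model for synthetic DAmFRET event tables
#'
#' Defines the per-cell data-generating process for one construct. Expression
#' (acceptor intensity) is log-normal across cells; AmFRET follows one of
#' four regimes:
#' \describe{
#'   \item{monomer}{no self-assembly: `AmFRET ~ N(0, noise_sd)`.}
#'   \item{continuous}{barrier-free assembly tracking concentration:
#'     `AmFRET = amp * c / (c50_seeded + c) + noise`.}
#'   \item{discontinuous}{nucleation-limited: each cell nucleates with
#'     probability `1 - exp(-ln2 (c / c50_stochastic)^shape_a)` (so
#'     `c50_stochastic` is the median spontaneous-nucleation concentration);
#'     nucleated cells lie on the assembled branch
#'     [amfret_weibull()] with `C50 = c50_seeded`, the rest at baseline.
#'     Cells between `c50_seeded` and nucleation are supersaturated.}
#'   \item{seeded}{a constitutive seed removes the barrier: every cell lies
#'     on the assembled branch with `C50 = c50_seeded`.}
#' }
#'
#' @param kind one of `"monomer"`, `"continuous"`, `"discontinuous"`,
#'   `"seeded"`
#' @param amp AmFRET plateau of the assembled branch (> 0)
#' @param c50_seeded saturation-concentration proxy (p.d.u.)
#' @param c50_stochastic median spontaneous-nucleation concentration
#'   (p.d.u.); must be `>= c50_seeded` for `kind = "discontinuous"`
#' @param shape_a Weibull steepness, in \[0.1, 10\]
#' @param noise_sd Gaussian AmFRET noise SD (>= 0)
#' @param expr_log_mean,expr_log_sd mean and SD of log10 acceptor intensity
#' @param n_cells number of cells (>= 1)
#' @param rng_seed integer seed; identical seeds give identical tables
#' @return an object of class `"damfret_model"`
#' @seealso [simulate_events()], [damfret_panel_models()]
#' @export
damfret_model <- function(kind = c("monomer", "continuous", "discontinuous",
                                   "seeded"),
                          amp = 0.6, c50_seeded = 100, c50_stochastic = 400,
                          shape_a = 2, noise_sd = 0.05,
                          expr_log_mean = 2, expr_log_sd = 0.6,
                          n_cells = 50000L, rng_seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(amp) || amp <= 0) stop_config("amp must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!is.finite(n_cells) || n_cells < 1) stop_config("n_cells must be >= 1")
  if (c50_seeded <= 0 || c50_stochastic <= 0)
    stop_config("c50 parameters must be > 0")
  if (shape_a < 0.1 || shape_a > 10)
    stop_config("shape_a must lie in [0.1, 10]")
  if (kind == "discontinuous" && c50_stochastic < c50_seeded)
    stop_config(
      "c50_stochastic must be >= c50_seeded for a discontinuous model")
  structure(list(kind = kind, amp = amp, c50_seeded = c50_seeded,
                 c50_stochastic = c50_stochastic, shape_a = shape_a,
                 noise_sd = noise_sd, expr_log_mean = expr_log_mean,
                 expr_log_sd = expr_log_sd, n_cells = as.integer(n_cells),
                 rng_seed = as.integer(rng_seed)),
            class = "damfret_model")
}

#' @export
print.damfret_model <- function(x, ...) {
  cat(sprintf("DAmFRET generative model: %s\n", x$kind))
  cat(sprintf("  amp=%.3g  c50_seeded=%.3g  c50_stochastic=%.3g  a=%.3g\n",
              x$amp, x$c50_seeded, x$c50_stochastic, x$shape_a))
  cat(sprintf("  noise_sd=%.3g  expr log10 ~ N(%.3g, %.3g)  n=%d  seed=%d\n",
              x$noise_sd, x$expr_log_mean, x$expr_log_sd, x$n_cells,
              x$rng_seed))
  invisible(x)
}

#' The four-regime synthetic study panel
#'
#' Default model set used throughout validation: a monomeric control, a
#' barrier-free continuous assembler, a nucleation-limited (discontinuous)
#' assembler with a fourfold supersaturation window, and a deeply seeded
#' construct whose C50 lies below the observable expression range so that
#' every expressing cell sits on the assembled branch (the "continuous high"
#' phenotype).
#'
#' @param n_cells cells per dataset
#' @param rng_seed base seed; each panel member gets a distinct derived seed
#' @return named list of four [damfret_model()] objects
#' @export
damfret_panel_models <- function(n_cells = 50000L, rng_seed = 1L) {
  s <- as.integer(rng_seed)
  list(
    monomer = damfret_model("monomer", noise_sd = 0.05,
                            n_cells = n_cells, rng_seed = s),
    continuous = damfret_model("continuous", amp = 0.3, c50_seeded = 100,
                               noise_sd = 0.1, n_cells = n_cells,
                               rng_seed = s + 1L),
    discontinuous = damfret_model("discontinuous", amp = 0.6,
                                  c50_seeded = 100, c50_stochastic = 400,
                                  shape_a = 2, noise_sd = 0.05,
                                  n_cells = n_cells, rng_seed = s + 2L),
    seeded = damfret_model("seeded", amp = 0.6, c50_seeded = 1,
                           shape_a = 2, noise_sd = 0.05, n_cells = n_cells,
                           rng_seed = s + 3L))
}

#' Simulate a per-cell DAmFRET event table
#'
#' Draws one flow-cytometry event per cell: scatter channels for a singlet
#' population, autofluorescence, log-normal acceptor (expression), donor
#' tracking acceptor, and FRET computed as `amfret * acceptor` so that
#' [compute_amfret()] recovers the generated AmFRET exactly. The column
#' `nucleated` records the ground-truth branch for discontinuous models.
#'
#' @param model a [damfret_model()]
#' @return data.frame with columns `event_id`, `fsc_a`, `fsc_h`, `fsc_w`,
#'   `ssc_a`, `autofluor`, `donor`, `acceptor`, `fret`, `nucleated`
#' @export
simulate_events <- function(model) {
  stopifnot(inherits(model, "damfret_model"))
  n <- model$n_cells
  with_seed(model$rng_seed, {
    acceptor <- 10^rnorm(n, model$expr_log_mean, model$expr_log_sd)
    noise <- rnorm(n, 0, model$noise_sd)
    nucleated <- rep(NA, n)
    amfret <- switch(model$kind,
      monomer = noise,
      continuous = model$amp * acceptor / (model$c50_seeded + acceptor) +
        noise,
      discontinuous = {
        p_nuc <- 1 - exp(-log(2) *
                           (acceptor / model$c50_stochastic)^model$shape_a)
        nucleated <- runif(n) < p_nuc
        ifelse(nucleated,
               amfret_weibull(acceptor, model$amp, model$c50_seeded,
                              model$shape_a) + noise,
               noise)
      },
      seeded = amfret_weibull(acceptor, model$amp, model$c50_seeded,
                              model$shape_a) + noise)
    fsc_a <- rlnorm(n, log(5e4), 0.15)
    data.frame(
      event_id = seq_len(n),
      fsc_a = fsc_a,
      fsc_h = fsc_a * 0.9 * exp(rnorm(n, 0, 0.05)),
      fsc_w = rnorm(n, 70, 5),
      ssc_a = rlnorm(n, log(3e4), 0.2),
      autofluor = rlnorm(n, log(100), 0.3),
      donor = 50 + 0.8 * acceptor * exp(rnorm(n, 0, 0.1)),
      acceptor = acceptor,
      fret = amfret * acceptor,
      nucleated = nucleated)
  })
}

#' Write / read event tables as CSV
#'
#' The on-disk schema is the nine instrument columns (`event_id`, `fsc_a`,
#' `fsc_h`, `fsc_w`, `ssc_a`, `autofluor`, `donor`, `acceptor`, `fret`);
#' ground-truth columns are in-memory only.
#'
#' @param events event table
#' @param path file path
#' @export
write_events <- function(events, path) {
  cols <- c("event_id", "fsc_a", "fsc_h", "fsc_w", "ssc_a", "autofluor",
            "donor", "acceptor", "fret")
  write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Ground truth for a synthetic nucleating-interaction screen
#'
#' @param dfd_ids,seed_ids identifiers of the mEos-fused DFDs (rows of the
#'   screen) and of the seed fusions
#' @param planted_hits data.frame with columns `dfd_id`, `seed_id`: the true
#'   nucleating interactions
#' @param batch_assignment named character vector mapping each seed id to a
#'   batch label; defaults to two equal batches
#' @param c50_effect,fgate_effect effect sizes of a true hit, in units of the
#'   interquartile range of the per-DFD baseline noise (C50 shifts down,
#'   fgate shifts up)
#' @param rng_seed integer seed
#' @return object of class `"screen_truth"`
#' @export
screen_truth <- function(dfd_ids, seed_ids, planted_hits = NULL,
                         batch_assignment = NULL,
                         c50_effect = 6, fgate_effect = 6, rng_seed = 1L) {
  if (!length(dfd_ids) || !length(seed_ids))
    stop_config("dfd_ids and seed_ids must be non-empty")
  dfd_ids <- as.character(dfd_ids); seed_ids <- as.character(seed_ids)
  if (anyDuplicated(dfd_ids) || anyDuplicated(seed_ids))
    stop_config("identifiers must be unique")
  if (is.null(planted_hits))
    planted_hits <- data.frame(dfd_id = character(), seed_id = character())
  planted_hits$dfd_id <- as.character(planted_hits$dfd_id)
  planted_hits$seed_id <- as.character(planted_hits$seed_id)
  if (!all(planted_hits$dfd_id %in% dfd_ids) ||
      !all(planted_hits$seed_id %in% seed_ids))
    stop_config("planted_hits must be a subset of dfd_ids x seed_ids")
  if (anyDuplicated(planted_hits[c("dfd_id", "seed_id")]))
    stop_config("planted_hits contains duplicated pairs")
  if (is.null(batch_assignment)) {
    half <- ceiling(length(seed_ids) / 2)
    batch_assignment <- setNames(
      rep(c("batch1", "batch2"), c(half, length(seed_ids) - half)), seed_ids)
  }
  if (!all(seed_ids %in% names(batch_assignment)))
    stop_config("batch_assignment must cover every seed id")
  structure(list(dfd_ids = dfd_ids, seed_ids = seed_ids,
                 planted_hits = planted_hits,
                 batch_assignment = batch_assignment,
                 c50_effect = c50_effect, fgate_effect = fgate_effect,
                 rng_seed = as.integer(rng_seed)),
            class = "screen_truth")
}

#' Simulate a DFD x seed screen table
#'
#' Non-hit pairs draw C50 and fgate from per-DFD baseline distributions with
#' additive batch shifts on the standardized scale; planted hits move C50
#' down and fgate up by the configured number of baseline IQRs (the IQR of a
#' normal is 1.349 SD). Two negative-control seeds (`"null_a"`, `"null_b"`)
#' are appended for every DFD.
#'
#' @param truth a [screen_truth()]
#' @param replicate replicate index stored in the output (the random draws
#'   also depend on it, so replicate 2 is an independent re-run)
#' @return data.frame of screen records, one row per DFD x seed
#' @export
simulate_screen <- function(truth, replicate = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  with_seed(truth$rng_seed + 97L * (as.integer(replicate) - 1L), {
    batches <- unique(truth$batch_assignment)
    batch_shift <- setNames(rnorm(length(batches), 0, 0.5), batches)
    iqr_norm <- 2 * qnorm(0.75)  # IQR of a standard normal, ~1.349
    hit_key <- paste(truth$planted_hits$dfd_id, truth$planted_hits$seed_id)
    seeds_all <- c(truth$seed_ids, "null_a", "null_b")
    out <- vector("list", length(truth$dfd_ids))
    for (i in seq_along(truth$dfd_ids)) {
      dfd <- truth$dfd_ids[i]
      base_c50 <- rlnorm(1, log(100), 0.2)
      sd_c50 <- 0.05 * base_c50
      base_fg <- runif(1, 0.01, 0.05)
      sd_fg <- 0.008
      m <- length(seeds_all)
      batch <- unname(truth$batch_assignment[seeds_all])
      batch[is.na(batch)] <- batches[1]   # negative controls run in batch 1
      z1 <- rnorm(m); z2 <- rnorm(m)
      is_hit_true <- paste(dfd, seeds_all) %in% hit_key
      c50 <- base_c50 + sd_c50 * (z1 + batch_shift[batch]) -
        is_hit_true * truth$c50_effect * iqr_norm * sd_c50
      fgate <- base_fg + sd_fg * (z2 + batch_shift[batch]) +
        is_hit_true * truth$fgate_effect * iqr_norm * sd_fg
      out[[i]] <- data.frame(
        dfd_id = dfd, seed_id = seeds_all, batch = batch,
        replicate = as.integer(replicate),
        n_mEos_pos = 2500L + rpois(m, 2500),
        mean_acceptor = runif(m, 5, 15),
        c50 = pmax(c50, 1e-3),
        fgate = pmin(pmax(fgate, 0), 1),
        is_negative_control = seeds_all %in% c("null_a", "null_b"),
        true_hit = is_hit_true)
    }
    do.call(rbind, out)
  })
}

# CV/AR regions implied by a threshold set (see classify_morphology)
.morph_regions <- function(threshold_set) {
  if (threshold_set == "primary")
    list(diffuse = list(cv = c(-Inf, 55), ar = c(-Inf, 1.16)),
         punctate = list(cv = c(55, Inf), ar = c(-Inf, 1.16)),
         fibrillar = list(cv = c(55, Inf), ar = c(1.159, Inf)))
  else
    list(diffuse = list(cv = c(-Inf, 18), ar = c(-Inf, 1.41)),
         punctate = list(cv = c(17, Inf), ar = c(-Inf, 1.41)),
         fibrillar = list(cv = c(17, Inf), ar = c(1.4, Inf)))
}

#' Simulate an imaging object table with known morphology classes
#'
#' Each object carries a mean and SD of pixel intensity (hence a CV) and an
#' aspect ratio, drawn from per-class normal distributions truncated to
#' mean +/- 3 SD. Class parameters must place that whole range strictly
#' inside the class's CV/AR decision region; parameters straddling a
#' boundary are a configuration error.
#'
#' @param n_per_class named integer vector with entries `diffuse`,
#'   `punctate`, `fibrillar`
#' @param class_params list per class with elements `cv` (mean, sd) and `ar`
#'   (mean, sd); defaults are comfortably inside each region
#' @param threshold_set `"primary"` or `"alternate"` (see
#'   [classify_morphology()])
#' @param rng_seed integer seed
#' @return data.frame with `object_id`, `class_true`, `mean_intensity`,
#'   `sd_intensity`, `cv`, `ar`
#' @export
simulate_morphology <- function(n_per_class = c(diffuse = 100,
                                                punctate = 100,
                                                fibrillar = 100),
                                class_params = NULL,
                                threshold_set = c("primary", "alternate"),
                                rng_seed = 1L) {
  threshold_set <- match.arg(threshold_set)
  if (is.null(class_params))
    class_params <- if (threshold_set == "primary")
      list(diffuse = list(cv = c(30, 6), ar = c(1.06, 0.02)),
           punctate = list(cv = c(75, 6), ar = c(1.08, 0.02)),
           fibrillar = list(cv = c(70, 4), ar = c(1.5, 0.1)))
    else
      list(diffuse = list(cv = c(10, 2), ar = c(1.1, 0.05)),
           punctate = list(cv = c(40, 6), ar = c(1.15, 0.05)),
           fibrillar = list(cv = c(40, 6), ar = c(1.7, 0.08)))
  regions <- .morph_regions(threshold_set)
  classes <- c("diffuse", "punctate", "fibrillar")
  for (cl in classes) {
    p <- class_params[[cl]]; r <- regions[[cl]]
    for (ax in c("cv", "ar")) {
      rng <- p[[ax]][1] + c(-3, 3) * p[[ax]][2]
      if (rng[1] <= r[[ax]][1] || rng[2] >= r[[ax]][2])
        stop_config(
          "class '%s': %s parameters straddle a decision boundary", cl, ax)
    }
  }
  with_seed(rng_seed, {
    rows <- lapply(classes, function(cl) {
      k <- n_per_class[[cl]] %||% 0
      if (k == 0) return(NULL)
      p <- class_params[[cl]]
      draw <- function(mu_sd, k) {
        v <- rnorm(k, mu_sd[1], mu_sd[2])
        lim <- mu_sd[1] + c(-3, 3) * mu_sd[2]
        bad <- v < lim[1] | v > lim[2]
        while (any(bad)) {
          v[bad] <- rnorm(sum(bad), mu_sd[1], mu_sd[2])
          bad <- v < lim[1] | v > lim[2]
        }
        v
      }
      cv <- draw(p$cv, k); ar <- draw(p$ar, k)
      mean_int <- rlnorm(k, log(1000), 0.3)
      data.frame(class_true = cl, mean_intensity = mean_int,
                 sd_intensity = cv * mean_int / 100, cv = cv, ar = ar)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(class_true = character(), mean_intensity = numeric(),
                        sd_intensity = numeric(), cv = numeric(),
                        ar = numeric())
    out <- cbind(object_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a physical-interaction edge list with planted hub proteins
#'
#' Background nodes form an Erdos-Renyi graph; each planted hub is connected
#' to a large random subset of nodes, making hubs the top-ranking nodes by
#' degree and betweenness centrality. Scores of retained edges are drawn
#' above `score_min` (STRING-style 0-1000 integer confidence), plus a set of
#' decoy low-score edges that [build_graph()] must drop.
#'
#' @param n_background number of non-hub proteins
#' @param n_hubs number of planted hubs
#' @param p_background edge probability among background nodes
#' @param hub_frac fraction of nodes each hub connects to
#' @param score_min minimal score of true edges
#' @param n_decoy number of below-threshold decoy edges
#' @param rng_seed integer seed
#' @return list with `edges` (data.frame `protein_a`, `protein_b`,
#'   `physical_score`) and `hubs` (character vector)
#' @export
simulate_interaction_graph <- function(n_background = 30, n_hubs = 2,
                                       p_background = 0.08, hub_frac = 0.6,
                                       score_min = 900, n_decoy = 20,
                                       rng_seed = 1L) {
  with_seed(rng_seed, {
    bg <- sprintf("P%03d", seq_len(n_background))
    hubs <- sprintf("HUB%d", seq_len(n_hubs))
    pairs <- t(utils::combn(bg, 2))
    keep <- runif(nrow(pairs)) < p_background
    e_bg <- pairs[keep, , drop = FALSE]
    e_hub <- do.call(rbind, lapply(hubs, function(h) {
      nb <- sample(bg, max(2, round(hub_frac * n_background)))
      cbind(h, nb)
    }))
    edges <- rbind(e_bg, e_hub)
    score <- sample(score_min:1000, nrow(edges), replace = TRUE)
    decoy_pairs <- pairs[sample(nrow(pairs), min(n_decoy, nrow(pairs))), ,
                         drop = FALSE]
    edges <- rbind(edges, decoy_pairs)
    score <- c(score, sample(0:(score_min - 1), nrow(decoy_pairs),
                             replace = TRUE))
    list(edges = data.frame(protein_a = edges[, 1], protein_b = edges[, 2],
                            physical_score = as.integer(score)),
         hubs = hubs)
  })
}

#' Simulate a supersaturation-versus-lifespan table
#'
#' Per cell type and per adaptor, a transcript level (nTPM) is drawn
#' log-normally and a saturation concentration is fixed per adaptor; the
#' supersaturation proxy transcript / c_sat must therefore be computed by
#' the consumer, not read. Mean lifespan follows the power law
#' `lifespan = k * (geometric-mean proxy)^slope` with multiplicative
#' log-normal scatter (`10^N(0, scatter_sd)`).
#'
#' @param n_celltypes number of cell types (>= 3)
#' @param slope power-law exponent of lifespan on supersaturation
#' @param scatter_sd SD of the log10 multiplicative scatter
#' @param k lifespan scale in days
#' @param adaptors adaptor names (one c_sat each)
#' @param rng_seed integer seed
#' @return data.frame with `cell_type`, `adaptor`, `transcript_ntpm`,
#'   `c_sat`, `lifespan_days` (lifespan repeated across the adaptors of a
#'   cell type)
#' @export
simulate_expression_lifespan <- function(n_celltypes = 20, slope = -1,
                                         scatter_sd = 0.15, k = 1000,
                                         adaptors = c("ASC", "FADD", "BCL10",
                                                      "TRADD", "MAVS"),
                                         rng_seed = 1L) {
  if (n_celltypes < 3) stop_config("n_celltypes must be >= 3")
  with_seed(rng_seed, {
    c_sat <- setNames(rlnorm(length(adaptors), log(50), 0.5), adaptors)
    rows <- lapply(seq_len(n_celltypes), function(i) {
      tr <- rlnorm(length(adaptors), log(100), 1.2)
      gm <- geometric_mean(tr / c_sat)
      life <- k * gm^slope * 10^rnorm(1, 0, scatter_sd)
      data.frame(cell_type = sprintf("celltype_%02d", i), adaptor = adaptors,
                 transcript_ntpm = tr, c_sat = unname(c_sat),
                 lifespan_days = life)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
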