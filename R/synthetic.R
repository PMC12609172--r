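#' Configuration for the synthetic synergy study generator
#'
#' The generator emulates the structure of a drug-combination screen: drugs
#' carry binary fingerprints with cluster structure, cell lines carry a
#' Gaussian expression matrix driven by tissue-level means, and continuous
#' synergy scores come from a drug-order-symmetric latent-factor surface,
#' affine-calibrated so that thresholding at the fixed cutoffs (>30
#' synergistic, <0 antagonistic) reproduces a chosen negative:positive class
#' ratio, with a small mass left in the excluded band.
#'
#' @param m_drugs Number of drugs (>= 2).
#' @param n_cell_lines Number of cell lines.
#' @param n_tissues Number of tissues (cell lines assigned round-robin).
#' @param g_genes Number of genes in the expression panel.
#' @param latent_dim Dimension of the latent factors.
#' @param n_drug_clusters Number of drug similarity clusters.
#' @param interaction_strength Scale of the latent synergy signal (>= 0).
#' @param noise_sd Standard deviation of the Gaussian noise added to scores
#'   and (scaled) to within-tissue expression variation (>= 0).
#' @param target_neg_pos_ratio Desired negative:positive label ratio after
#'   thresholding; the default 2.3 matches the imbalance of large public
#'   drug-combination screens.
#' @param excluded_frac Probability mass calibrated into the ambiguous
#'   `[0, 30]` band so the exclusion rule is exercised.
#' @param triplet_fraction Fraction of all unordered (drug pair, cell line)
#'   triplets that receive a measurement.
#' @param replicates Measurements emitted per surviving triplet.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(m_drugs = 40L, n_cell_lines = 8L,
                             n_tissues = 4L, g_genes = 60L, latent_dim = 6L,
                             n_drug_clusters = 4L, interaction_strength = 1,
                             noise_sd = 1, target_neg_pos_ratio = 2.3,
                             excluded_frac = 0.05, triplet_fraction = 1,
                             replicates = 1L, seed = 1L) {
  stopifnot(m_drugs >= 2L, n_cell_lines >= 1L, n_tissues >= 1L,
            n_tissues <= n_cell_lines, g_genes >= 1L, latent_dim >= 1L,
            interaction_strength >= 0, noise_sd >= 0,
            target_neg_pos_ratio > 0, excluded_frac >= 0, excluded_frac < 1,
            triplet_fraction > 0, triplet_fraction <= 1, replicates >= 1L,
            abs(seed) < 2^31 - 10)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic drug panel
#'
#' Drugs are grouped into latent clusters; each cluster has a template
#' fingerprint (random bits at ~8% density) and each drug flips a small
#' fraction of all bits, so within-cluster Tanimoto similarity exceeds
#' between-cluster similarity. Drug latent factors are cluster centers plus
#' per-drug jitter, and are what the synergy surface is built from.
#'
#' @param config A [synthetic_config()].
#' @return A list with a [drug_panel()], the cluster assignment, and the
#'   `m x latent_dim` latent factor matrix.
#' @export
generate_drugs <- function(config) {
  set.seed(config$seed + 1L)
  m <- config$m_drugs
  L <- config$latent_dim
  k <- min(config$n_drug_clusters, m)
  cluster <- rep_len(seq_len(k), m)
  centers <- matrix(stats::rnorm(k * L, sd = 1), k, L)
  u <- centers[cluster, , drop = FALSE] +
    matrix(stats::rnorm(m * L, sd = 0.4), m, L)
  templates <- matrix(stats::rbinom(k * 1024L, 1L, 0.08), k, 1024L)
  fps <- templates[cluster, , drop = FALSE]
  flips <- matrix(stats::rbinom(m * 1024L, 1L, 0.05), m, 1024L)
  fps <- abs(fps - flips)
  ids <- sprintf("DRUG%03d", seq_len(m))
  rownames(u) <- ids
  list(panel = drug_panel(ids, fingerprints = fps),
       cluster = cluster, latent = u)
}

#' Generate a synthetic cell-line panel
#'
#' Each tissue gets a latent mean and a gene-expression signature; cell
#' lines are tissue means plus Gaussian cell-level variation scaled by
#' `noise_sd` (zero noise makes all lines of a tissue identical). Expression
#' is a linear readout of the cell-line latent factors, so the numerical
#' feature stream carries the information the synergy surface uses.
#'
#' @param config A [synthetic_config()].
#' @return A list with a [cell_line_panel()] (raw expression is kept in
#'   `$raw_expression`), tissue labels, and the `n x latent_dim` latent
#'   factor matrix.
#' @export
generate_cell_lines <- function(config) {
  set.seed(config$seed + 2L)
  n <- config$n_cell_lines
  L <- config$latent_dim
  g <- config$g_genes
  tissue <- sprintf("TISSUE%02d", rep_len(seq_len(config$n_tissues), n))
  t_means <- matrix(stats::rnorm(config$n_tissues * L), config$n_tissues, L)
  w <- t_means[rep_len(seq_len(config$n_tissues), n), , drop = FALSE] +
    matrix(stats::rnorm(n * L), n, L) * (0.5 * config$noise_sd)
  loading <- matrix(stats::rnorm(g * L, sd = 1), g, L)
  expr <- w %*% t(loading) +
    matrix(stats::rnorm(n * g), n, g) * config$noise_sd
  ids <- sprintf("CELL%02d", seq_len(n))
  rownames(expr) <- ids
  colnames(expr) <- sprintf("GENE%03d", seq_len(g))
  rownames(w) <- ids
  panel <- if (n >= 2L) {
    cell_line_panel(expr, tissue = tissue)
  } else {
    structure(list(cell_line_id = ids, tissue = tissue,
                   expression = expr * 0), class = "cell_line_panel")
  }
  panel$raw_expression <- expr
  list(panel = panel, tissue = tissue, latent = w)
}

#' Generate synthetic synergy measurements
#'
#' The continuous surface is `s(i, j, k) = interaction_strength *
#' (u_i' M u_j + w_k . (u_i + u_j))` with `M` symmetric, plus Gaussian noise
#' drawn once per unordered triplet, so the surface is exactly symmetric
#' under drug swap. Scores are affine-calibrated on a pilot sample of 10 000
#' triplets so that thresholding at >30 / <0 yields the configured
#' negative:positive ratio and leaves `excluded_frac` of the mass in the
#' ambiguous band. When the score distribution is degenerate (zero signal
#' and zero noise) every score maps to the calibration constant 15, the
#' midpoint of the excluded band.
#'
#' @param config A [synthetic_config()].
#' @param drugs Result of [generate_drugs()].
#' @param cell_lines Result of [generate_cell_lines()].
#' @return A list with the records data.frame (`drug1_id`, `drug2_id`,
#'   `cell_line_id`, `synergy_score`, `source`), and the ground truth
#'   (latent factors, `M`, calibration, per-triplet true scores).
#' @export
generate_synergy_records <- function(config, drugs, cell_lines) {
  set.seed(config$seed + 3L)
  u <- drugs$latent
  w <- cell_lines$latent
  m <- nrow(u)
  n <- nrow(w)
  L <- ncol(u)
  b <- matrix(stats::rnorm(L * L, sd = 0.5), L, L)
  M <- (b + t(b)) / 2 + diag(L)

  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  grid <- cbind(pairs[rep(seq_len(nrow(pairs)), times = n), , drop = FALSE],
                k = rep(seq_len(n), each = nrow(pairs)))
  raw_surface <- function(i, j, k) {
    config$interaction_strength *
      (rowSums((u[i, , drop = FALSE] %*% M) * u[j, , drop = FALSE]) +
         rowSums(w[k, , drop = FALSE] *
                   (u[i, , drop = FALSE] + u[j, , drop = FALSE])))
  }

  # calibration pilot: 10 000 random triplets with their own noise draws
  pi_ <- sample.int(m, 10000L, replace = TRUE)
  pj <- sample.int(m, 10000L, replace = TRUE)
  swap <- pi_ == pj
  pj[swap] <- (pj[swap] %% m) + 1L
  pk <- sample.int(n, 10000L, replace = TRUE)
  pilot <- raw_surface(pi_, pj, pk) + stats::rnorm(10000L, sd = config$noise_sd)

  r <- config$target_neg_pos_ratio
  p_pos <- (1 - config$excluded_frac) / (1 + r)
  p_neg <- r * p_pos
  q_lo <- stats::quantile(pilot, p_neg, names = FALSE)
  q_hi <- stats::quantile(pilot, 1 - p_pos, names = FALSE)
  if (q_hi - q_lo > 1e-12) {
    calib <- list(scale = 30 / (q_hi - q_lo), shift = q_lo, constant = FALSE)
    transform <- function(s) (s - calib$shift) * calib$scale
  } else {
    calib <- list(scale = 1, shift = 0, constant = TRUE)
    transform <- function(s) rep(15, length(s))
  }

  if (config$triplet_fraction < 1) {
    keep <- sort(sample.int(nrow(grid),
                            max(1L, round(config$triplet_fraction * nrow(grid)))))
    grid <- grid[keep, , drop = FALSE]
  }
  true_score <- raw_surface(grid[, 1L], grid[, 2L], grid[, 3L])
  rep_idx <- rep(seq_len(nrow(grid)), times = config$replicates)
  noise <- stats::rnorm(length(rep_idx), sd = config$noise_sd)
  score <- transform(true_score[rep_idx] + noise)

  # emit roughly half the records drug-swapped to exercise canonicalization
  flip <- stats::runif(length(rep_idx)) < 0.5
  i_out <- ifelse(flip, grid[rep_idx, 2L], grid[rep_idx, 1L])
  j_out <- ifelse(flip, grid[rep_idx, 1L], grid[rep_idx, 2L])
  ids_d <- drugs$panel$drug_id
  ids_c <- cell_lines$panel$cell_line_id
  records <- data.frame(drug1_id = ids_d[i_out], drug2_id = ids_d[j_out],
                        cell_line_id = ids_c[grid[rep_idx, 3L]],
                        synergy_score = score, source = "synthetic",
                        stringsAsFactors = FALSE)
  truth <- data.frame(drug1_id = ids_d[grid[, 1L]],
                      drug2_id = ids_d[grid[, 2L]],
                      cell_line_id = ids_c[grid[, 3L]],
                      true_score = transform(true_score))
  list(records = records,
       ground_truth = list(drug_latent = u, cell_latent = w, M = M,
                           calibration = calib, surface = truth))
}

#' Simulate a complete synthetic synergy study
#'
#' Runs the three generators under one configuration and returns everything
#' the downstream pipeline consumes, plus the generating ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list with `drugs`, `cell_lines`, `records`, `ground_truth`.
#' @examples
#' study <- simulate_synergy_study(synthetic_config(m_drugs = 10,
#'   n_cell_lines = 4, n_tissues = 2, seed = 7))
#' head(study$records)
#' @export
simulate_synergy_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  drugs <- generate_drugs(config)
  cells <- generate_cell_lines(config)
  syn <- generate_synergy_records(config, drugs, cells)
  list(drugs = drugs, cell_lines = cells, records = syn$records,
       ground_truth = c(syn$ground_truth,
                        list(drug_cluster = drugs$cluster,
                             tissue = cells$tissue)),
       config = config)
}

# Symmetric latent interaction features for the logistic sanity baseline:
# all symmetrized cross-products u_i[a] u_j[b] + u_i[b] u_j[a] plus the
# cell-line modulation terms w_k * (u_i + u_j). The true surface is linear
# in these, so a plain glm should separate the classes when noise is modest.
latent_baseline_features <- function(ground_truth, triplets) {
  u <- ground_truth$drug_latent
  w <- ground_truth$cell_latent
  L <- ncol(u)
  ui <- u[triplets$drug1, , drop = FALSE]
  uj <- u[triplets$drug2, , drop = FALSE]
  wk <- w[triplets$cell_line, , drop = FALSE]
  cross <- NULL
  for (a in seq_len(L)) {
    for (b in a:L) {
      cross <- cbind(cross, ui[, a] * uj[, b] + ui[, b] * uj[, a])
    }
  }
  cbind(cross, wk * (ui + uj))
}
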