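stage_names <- c("embedding_init", "embedding_trained", "aux_raw",
                 "aux_extracted", "dsa_fused", "pre_prediction")

#' Extract per-triplet representations at a named model stage
#'
#' Captures the internal representation of each triplet at one of six
#' boundaries: the pre-training embedding lookup (`embedding_init`), the
#' trained embedding lookup (`embedding_trained`), the raw concatenated
#' numerical input (`aux_raw`), the feature-extractor output
#' (`aux_extracted`), the attention-fused vector feeding FM and DNN
#' (`dsa_fused`), and the final representation entering the classifier
#' (`pre_prediction`). Extraction runs in deterministic eval mode.
#'
#' @param model A fitted `dsa_deepfm`.
#' @param dataset Dataset to represent (default: the model's own).
#' @param indices Triplet indices (default: the split's test partition).
#' @param stage One of the six stage names.
#' @return An object of class `stage_representation`: `$matrix` (triplets
#'   by dimensions), `$labels`, `$stage`.
#' @export
extract_stage <- function(model, dataset = NULL, indices = NULL,
                          stage = "pre_prediction") {
  stopifnot(inherits(model, "dsa_deepfm"))
  if (!stage %in% stage_names) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(stage_names, collapse = ", "), call. = FALSE)
  }
  dataset <- dataset %||% model$dataset
  indices <- indices %||% model$split$test
  trip <- dataset$triplets[indices, , drop = FALSE]
  v <- model$variant
  if (stage %in% c("embedding_init", "embedding_trained") &&
      !v$use_categorical) {
    stop("variant '", v$name, "' has no categorical stream", call. = FALSE)
  }
  if (stage %in% c("aux_raw", "aux_extracted") && !v$use_numerical) {
    stop("variant '", v$name, "' has no numerical stream", call. = FALSE)
  }
  if (stage == "embedding_init") {
    d1 <- match(trip$drug1, model$drug_ids)
    d2 <- match(trip$drug2, model$drug_ids)
    cl <- match(trip$cell_line, model$cell_ids) + model$dims$m
    mat <- cbind(model$emb_init[d1, , drop = FALSE],
                 model$emb_init[d2, , drop = FALSE],
                 model$emb_init[cl, , drop = FALSE])
  } else {
    feats <- triplet_features(model, trip)
    p <- predict_indices(model, feats, seq_len(nrow(trip)), capture = stage)
    mat <- attr(p, "captures")[[stage]]
  }
  structure(list(matrix = unname(mat), labels = trip$label, stage = stage),
            class = "stage_representation")
}

#' Class-separation statistics of a representation
#'
#' Rows are z-scored per dimension, L2-normalized, and compared under cosine
#' distance. Four statistics summarize class structure: the mean intra-class
#' pairwise distance (averaged over the two classes), the cosine distance
#' between the re-normalized class centroids, the margin `inter - intra`,
#' and the ratio `intra / inter`. Larger margins and smaller ratios indicate
#' tighter classes that are further apart. If the two class centroids
#' coincide the ratio is undefined and flagged degenerate.
#'
#' @param rep A `stage_representation`, or a numeric matrix (then `labels`
#'   must be given).
#' @param labels 0/1 labels when `rep` is a bare matrix.
#' @return An object of class `separation_stats` with fields `intra`,
#'   `inter`, `margin`, `ratio`, `degenerate`.
#' @export
separation_stats <- function(rep, labels = NULL) {
  if (inherits(rep, "stage_representation")) {
    mat <- rep$matrix
    labels <- rep$labels
  } else {
    mat <- as.matrix(rep)
  }
  stopifnot(!is.null(labels), nrow(mat) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("separation statistics need exactly two classes", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("need at least 2 rows per class", call. = FALSE)
  }
  x <- normalize_rows(zscore_columns(mat))
  intra_by_class <- vapply(classes, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    gram <- tcrossprod(xc)
    n <- nrow(xc)
    sum(1 - gram[upper.tri(gram)]) / (n * (n - 1) / 2)
  }, numeric(1L))
  intra <- mean(intra_by_class)
  cents <- lapply(classes, function(cl) {
    v <- colMeans(x[labels == cl, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  })
  inter <- 1 - sum(cents[[1L]] * cents[[2L]])
  degenerate <- inter <= .Machine$double.eps^0.5
  structure(list(intra = intra, inter = inter, margin = inter - intra,
                 ratio = if (degenerate) NA_real_ else intra / inter,
                 degenerate = degenerate, space = "original"),
            class = "separation_stats")
}

zscore_columns <- function(mat) {
  mu <- colMeans(mat)
  sdv <- sqrt(colMeans(mat^2) - mu^2)
  out <- sweep(mat, 2L, mu, "-")
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdv[nz], "/")
  out[, !nz] <- 0
  out
}

normalize_rows <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- 1
  mat / nrm
}

#' @export
print.separation_stats <- function(x, ...) {
  cat(sprintf(
    "separation: intra %.4f, inter %.4f, margin %.4f, intra/inter %s%s\n",
    x$intra, x$inter, x$margin,
    ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio)),
    if (x$degenerate) " [degenerate: coincident centroids]" else ""))
  invisible(x)
}

#' Two-dimensional projection of a stage representation
#'
#' Visualization plumbing for representation scatter plots: projects the
#' (z-scored) rows onto their first two principal components. The testable
#' diagnostics are the separation statistics in the original space;
#' the projection is only for plotting.
#'
#' @param rep A `stage_representation` or matrix.
#' @return A two-column matrix of coordinates.
#' @export
project_2d <- function(rep) {
  mat <- if (inherits(rep, "stage_representation")) rep$matrix else
    as.matrix(rep)
  pc <- stats::prcomp(zscore_columns(mat), center = FALSE, scale. = FALSE,
                      rank. = 2L)
  pc$x[, 1:2, drop = FALSE]
}

#' Drug-order consistency of a fitted model
#'
#' Scores every triplet under both drug orderings and reports the paired
#' probabilities with their Pearson correlation. A model that treats drug
#' pairs symmetrically (e.g. after order augmentation) should show a
#' correlation near 1. If either ordering produces constant output the
#' correlation is undefined and flagged.
#'
#' @param model A fitted `dsa_deepfm`.
#' @param dataset Dataset to score (default: the model's own).
#' @param indices Triplet indices (default: the split's test partition).
#' @return A list with `$pairs` (data.frame of `p_ab`, `p_ba`),
#'   `$pearson`, and `$constant`.
#' @export
order_consistency <- function(model, dataset = NULL, indices = NULL) {
  stopifnot(inherits(model, "dsa_deepfm"))
  dataset <- dataset %||% model$dataset
  indices <- indices %||% model$split$test
  trip <- dataset$triplets[indices, , drop = FALSE]
  # one row per unordered triplet
  trip <- trip[!duplicated(trip$key), , drop = FALSE]
  p_ab <- predict(model, trip)
  swapped <- trip
  swapped$drug1 <- trip$drug2
  swapped$drug2 <- trip$drug1
  p_ba <- predict(model, swapped)
  constant <- stats::sd(p_ab) == 0 || stats::sd(p_ba) == 0
  list(pairs = data.frame(drug1 = trip$drug1, drug2 = trip$drug2,
                          cell_line = trip$cell_line, p_ab = p_ab,
                          p_ba = p_ba),
       pearson = if (constant) NA_real_ else stats::cor(p_ab, p_ba),
       constant = constant)
}

#' Audit test performance by training-frequency quartile
#'
#' For each test triplet, computes the minimum training-set frequency among
#' its three entities (drug 1, drug 2, cell line), splits the test set into
#' four near-equal quartiles of that frequency (ties broken by stable
#' triplet order), and reports AUC-ROC and the positive-class proportion
#' per quartile — a check for bias toward frequently seen entities.
#'
#' @param model A fitted `dsa_deepfm`.
#' @param dataset Dataset (default: the model's own).
#' @param split Split (default: the model's).
#' @return A data.frame with one row per quartile plus an `"overall"` row.
#' @export
frequency_quartile_audit <- function(model, dataset = NULL, split = NULL) {
  stopifnot(inherits(model, "dsa_deepfm"))
  dataset <- dataset %||% model$dataset
  split <- split %||% model$split
  trip <- dataset$triplets
  train <- trip[split$train, , drop = FALSE]
  test <- trip[split$test, , drop = FALSE]
  if (nrow(test) < 8L) {
    stop("too few test triplets to form quartiles", call. = FALSE)
  }
  freq <- table(c(train$drug1, train$drug2, train$cell_line))
  lookup <- function(id) ifelse(id %in% names(freq), freq[id], 0L)
  minfreq <- pmin(lookup(test$drug1), lookup(test$drug2),
                  lookup(test$cell_line))
  ord <- order(minfreq, seq_along(minfreq))  # stable tie-break
  bounds <- floor(nrow(test) * (0:4) / 4)
  quart <- integer(nrow(test))
  for (q in 1:4) {
    quart[ord[seq.int(bounds[q] + 1L, bounds[q + 1L])]] <- q
  }
  p <- predict(model, test)
  rows <- lapply(1:4, function(q) {
    sel <- quart == q
    yq <- test$label[sel]
    data.frame(quartile = as.character(q), n = sum(sel),
               min_freq_range = paste(range(minfreq[sel]), collapse = "-"),
               auc_roc = if (length(unique(yq)) == 2L) {
                 auc_rank(p[sel], yq)
               } else NA_real_,
               pos_proportion = mean(yq))
  })
  overall <- data.frame(quartile = "overall", n = nrow(test),
                        min_freq_range = paste(range(minfreq),
                                               collapse = "-"),
                        auc_roc = if (length(unique(test$label)) == 2L) {
                          auc_rank(p, test$label)
                        } else NA_real_,
                        pos_proportion = mean(test$label))
  out <- rbind(do.call(rbind, rows), overall)
  rownames(out) <- NULL
  out
}

#' Rank candidate synergistic drug pairs for a cell line
#'
#' Scores every unordered pair of panel drugs on the given cell line,
#' excluding known combinations, and returns the pairs whose symmetrized
#' score (mean of both drug orderings) reaches the cutoff, sorted by score.
#' The default cutoff of 0.6 is the discovery threshold used for nominating
#' novel combinations.
#'
#' @param model A fitted `dsa_deepfm`.
#' @param cell_line A cell-line identifier of the fitted panel.
#' @param drugs Drug identifiers forming the candidate panel (default: all
#'   fitted drugs).
#' @param exclude A data.frame with columns `drug1`, `drug2` of known pairs
#'   to skip (order-insensitive), e.g. the training combinations.
#' @param cutoff Minimum symmetrized synergy probability (default 0.6).
#' @param top_k Maximum number of pairs returned.
#' @return A data.frame with columns `drug1`, `drug2`, `score_ab`,
#'   `score_ba`, `score_mean`, sorted by decreasing `score_mean`.
#' @export
discover <- function(model, cell_line, drugs = NULL, exclude = NULL,
                     cutoff = 0.6, top_k = Inf) {
  stopifnot(inherits(model, "dsa_deepfm"), length(cell_line) == 1L)
  drugs <- sort(drugs %||% model$drug_ids)
  if (length(drugs) < 2L) stop("candidate panel needs >= 2 drugs",
                               call. = FALSE)
  pairs <- t(utils::combn(drugs, 2L))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    known <- paste(pmin(exclude$drug1, exclude$drug2),
                   pmax(exclude$drug1, exclude$drug2), sep = "\r")
    keep <- !paste(pairs[, 1L], pairs[, 2L], sep = "\r") %in% known
    pairs <- pairs[keep, , drop = FALSE]
  }
  empty <- data.frame(drug1 = character(0), drug2 = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      score_mean = numeric(0))
  if (nrow(pairs) == 0L) {
    warning("no candidate pairs left after exclusions", call. = FALSE)
    return(empty)
  }
  trip <- data.frame(drug1 = pairs[, 1L], drug2 = pairs[, 2L],
                     cell_line = cell_line, stringsAsFactors = FALSE)
  swapped <- data.frame(drug1 = pairs[, 2L], drug2 = pairs[, 1L],
                        cell_line = cell_line, stringsAsFactors = FALSE)
  s_ab <- predict(model, trip)
  s_ba <- predict(model, swapped)
  out <- data.frame(drug1 = pairs[, 1L], drug2 = pairs[, 2L],
                    score_ab = s_ab, score_ba = s_ba,
                    score_mean = (s_ab + s_ba) / 2,
                    stringsAsFactors = FALSE)
  out <- out[out$score_mean >= cutoff, , drop = FALSE]
  out <- out[order(-out$score_mean, out$drug1, out$drug2), , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
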