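#' Cross-validation splits for four evaluation regimes
#'
#' Produces five-fold style splits into train/validation/test with a 3:1:1
#' fold rotation. Assignment is always performed on grouping keys so that
#' swapped-order duplicates of a drug pair can never straddle partitions:
#' `"random_cv"` groups by unordered triplet, `"leave_cell_line_out"` by
#' cell line, `"leave_tissue_out"` by tissue, and `"leave_drug_out"` by
#' drug (a test triplet then contains at least one drug absent from
#' training, and validation drugs are likewise held out of training).
#'
#' @param dataset A [build_dataset()] result.
#' @param regime One of `"random_cv"`, `"leave_cell_line_out"`,
#'   `"leave_tissue_out"`, `"leave_drug_out"`.
#' @param fold_count Number of folds (default 5: three train, one
#'   validation, one test per rotation).
#' @param seed Integer seed for the fold assignment.
#' @return A list of `synergy_split` objects, one per fold, each holding
#'   integer triplet indices `$train`, `$val`, `$test`.
#' @export
make_split <- function(dataset, regime = c("random_cv", "leave_cell_line_out",
                                           "leave_tissue_out",
                                           "leave_drug_out"),
                       fold_count = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "synergy_dataset"), fold_count >= 3L)
  regime <- match.arg(regime)
  trip <- dataset$triplets
  set.seed(seed)

  assign_groups <- function(entities) {
    if (length(entities) < fold_count) {
      stop(sprintf(
        "regime '%s' infeasible: %d grouping entities for %d folds",
        regime, length(entities), fold_count), call. = FALSE)
    }
    stats::setNames(sample(rep_len(seq_len(fold_count), length(entities))),
                    entities)
  }

  folds <- vector("list", fold_count)
  if (regime == "leave_drug_out") {
    fd <- assign_groups(sort(unique(c(trip$drug1, trip$drug2))))
    g1 <- fd[trip$drug1]
    g2 <- fd[trip$drug2]
    for (i in seq_len(fold_count)) {
      j <- i %% fold_count + 1L
      test <- which(g1 == i | g2 == i)
      val <- setdiff(which(g1 == j | g2 == j), test)
      train <- which(g1 != i & g2 != i & g1 != j & g2 != j)
      folds[[i]] <- new_split(train, val, test, regime, i, seed)
    }
  } else {
    gkey <- switch(regime,
      random_cv = trip$key,
      leave_cell_line_out = trip$cell_line,
      leave_tissue_out = {
        tis <- dataset$cell_lines$tissue
        if (is.null(tis)) {
          stop("leave_tissue_out needs tissue annotations", call. = FALSE)
        }
        tis[match(trip$cell_line, dataset$cell_lines$cell_line_id)]
      })
    fd <- assign_groups(sort(unique(gkey)))
    gf <- fd[gkey]
    for (i in seq_len(fold_count)) {
      j <- i %% fold_count + 1L
      folds[[i]] <- new_split(which(!gf %in% c(i, j)), which(gf == j),
                              which(gf == i), regime, i, seed)
    }
  }
  for (f in folds) {
    if (min(lengths(f[c("train", "val", "test")])) == 0L) {
      stop(sprintf("regime '%s' infeasible: empty partition in fold %d",
                   regime, f$fold), call. = FALSE)
    }
  }
  folds
}

new_split <- function(train, val, test, regime, fold, seed) {
  structure(list(train = as.integer(train), val = as.integer(val),
                 test = as.integer(test), regime = regime,
                 fold = as.integer(fold), seed = seed),
            class = "synergy_split")
}

#' @export
print.synergy_split <- function(x, ...) {
  cat(sprintf("synergy_split (%s, fold %d): %d train / %d val / %d test\n",
              x$regime, x$fold, length(x$train), length(x$val),
              length(x$test)))
  invisible(x)
}

#' Downsample training negatives to a target class ratio
#'
#' Reproduces the class-imbalance sensitivity protocol: the training
#' partition is downsampled (whole unordered pairs at a time, so augmented
#' orderings stay together) to a requested negative:positive ratio while the
#' validation and test partitions are untouched. Positives are always kept;
#' a ratio above the one already present is infeasible and errors.
#'
#' @param dataset The `synergy_dataset` the split indexes into.
#' @param split A `synergy_split`.
#' @param neg_pos_ratio Target negatives per positive in training.
#' @param seed Seed for the subsampling.
#' @return A `synergy_split` with a reduced `$train`.
#' @export
resample_ratio <- function(dataset, split, neg_pos_ratio, seed = 1L) {
  stopifnot(inherits(dataset, "synergy_dataset"),
            inherits(split, "synergy_split"), neg_pos_ratio > 0)
  trip <- dataset$triplets[split$train, , drop = FALSE]
  keys <- unique(trip$key)
  klab <- trip$label[match(keys, trip$key)]
  npos <- sum(klab == 1L)
  nneg <- sum(klab == 0L)
  if (npos == 0L) stop("no positive training triplets", call. = FALSE)
  target_neg <- round(neg_pos_ratio * npos)
  if (target_neg > nneg) {
    stop(sprintf(
      "infeasible ratio %.3g: only %.3g negatives per positive available",
      neg_pos_ratio, nneg / npos), call. = FALSE)
  }
  if (target_neg == nneg) return(split)
  set.seed(seed)
  keep_keys <- c(keys[klab == 1L], sample(keys[klab == 0L], target_neg))
  split$train <- split$train[trip$key %in% keep_keys]
  split
}
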