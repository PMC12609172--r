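#' Z-score normalize a cell-line-by-gene expression matrix
#'
#' Centers and scales every gene column using the population standard
#' deviation (denominator `n`). Constant columns map to all zeros, which keeps
#' the transform deterministic for degenerate genes. The transform is
#' idempotent: re-normalizing an already normalized matrix is a no-op.
#'
#' @param mat A numeric matrix, rows = cell lines, columns = genes.
#' @return A matrix of the same shape with column means 0 and unit variance
#'   (except constant columns, which become 0).
#' @export
zscore_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) {
    stop("z-score normalization needs at least 2 cell lines", call. = FALSE)
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rn <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
    cn <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
    stop(sprintf("non-finite expression value for cell line '%s', gene '%s'",
                 rn[bad[1L, 1L]], cn[bad[1L, 2L]]), call. = FALSE)
  }
  mu <- colMeans(mat)
  sdv <- sqrt(colMeans(mat^2) - mu^2)
  out <- sweep(mat, 2L, mu, "-")
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdv[nz], "/")
  out[, !nz] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label a synergy score
#'
#' Scores above 30 are synergistic (`"positive"`), scores below 0 are
#' antagonistic (`"negative"`), and scores in the ambiguous band `[0, 30]`
#' are `"excluded"` from the dataset. Both inequalities are strict.
#'
#' @param score Numeric vector of synergy scores.
#' @return A character vector in `{"positive", "negative", "excluded"}`.
#' @examples
#' label_by_threshold(c(45, -3, 30, 0))
#' @export
label_by_threshold <- function(score) {
  if (any(!is.finite(score))) {
    stop("non-finite synergy score", call. = FALSE)
  }
  ifelse(score > 30, "positive", ifelse(score < 0, "negative", "excluded"))
}

#' Resolve conflicting replicate labels by majority vote
#'
#' Replicate measurements of the same unordered (drug pair, cell line)
#' triplet may disagree; the triplet keeps the strict-majority label. Exact
#' ties are excluded, since a majority does not exist.
#'
#' @param labels Character vector of `"positive"` / `"negative"` votes.
#' @return One of `"positive"`, `"negative"`, `"excluded"`.
#' @examples
#' majority_vote(c("positive", "positive", "negative"))
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0L) stop("no votes", call. = FALSE)
  npos <- sum(labels == "positive")
  nneg <- sum(labels == "negative")
  if (npos > nneg) "positive" else if (nneg > npos) "negative" else "excluded"
}

#' Assemble a drug panel
#'
#' Builds the drug side of a dataset from identifiers plus either SMILES
#' strings (fingerprinted via [compute_fingerprint()]) or precomputed binary
#' fingerprints. Drugs whose SMILES cannot be parsed are dropped with a
#' warning naming them.
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param smiles Optional character vector of SMILES strings.
#' @param fingerprints Optional 0/1 matrix (one row per drug, 1024 columns).
#' @return An object of class `drug_panel`.
#' @export
drug_panel <- function(drug_id, smiles = NULL, fingerprints = NULL) {
  drug_id <- as.character(drug_id)
  if (anyDuplicated(drug_id)) stop("duplicated drug_id", call. = FALSE)
  if (is.null(fingerprints)) {
    if (is.null(smiles)) {
      stop("supply either smiles or fingerprints", call. = FALSE)
    }
    fps <- vector("list", length(drug_id))
    ok <- logical(length(drug_id))
    for (i in seq_along(drug_id)) {
      fp <- tryCatch(compute_fingerprint(smiles[i]), error = function(e) NULL)
      if (!is.null(fp)) {
        fps[[i]] <- fp
        ok[i] <- TRUE
      }
    }
    if (any(!ok)) {
      warning("dropped ", sum(!ok), " drug(s) with unparseable SMILES: ",
              paste(drug_id[!ok], collapse = ", "), call. = FALSE)
    }
    if (!any(ok)) stop("no valid molecules in panel", call. = FALSE)
    fingerprints <- do.call(rbind, fps[ok])
    drug_id <- drug_id[ok]
    smiles <- smiles[ok]
  } else {
    fingerprints <- as.matrix(fingerprints)
    if (nrow(fingerprints) != length(drug_id)) {
      stop("fingerprint rows must match drug_id length", call. = FALSE)
    }
    if (!all(fingerprints %in% c(0, 1))) {
      stop("fingerprints must be binary", call. = FALSE)
    }
  }
  rownames(fingerprints) <- drug_id
  structure(list(drug_id = drug_id, smiles = smiles,
                 fingerprints = fingerprints),
            class = "drug_panel")
}

#' Assemble a cell-line panel
#'
#' Wraps a raw expression matrix (rows = cell lines over a shared gene panel)
#' with optional tissue annotations; expression is z-scored per gene.
#'
#' @param expression Numeric matrix with cell-line row names.
#' @param tissue Optional character vector of tissue labels (one per row) or
#'   a data.frame with columns `cell_line_id`, `tissue`.
#' @param genes Optional character vector restricting the gene panel before
#'   normalization (e.g. a pathway-derived gene list). No filtering happens
#'   by default.
#' @return An object of class `cell_line_panel` with z-scored expression.
#' @export
cell_line_panel <- function(expression, tissue = NULL, genes = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) {
    stop("expression matrix needs cell-line row names", call. = FALSE)
  }
  if (!is.null(genes)) {
    keep <- intersect(colnames(expression), genes)
    if (length(keep) == 0L) stop("gene filter removed every gene",
                                 call. = FALSE)
    expression <- expression[, keep, drop = FALSE]
  }
  ids <- rownames(expression)
  if (is.data.frame(tissue)) {
    tissue <- tissue$tissue[match(ids, tissue$cell_line_id)]
  }
  if (!is.null(tissue) && length(tissue) != length(ids)) {
    stop("tissue labels must match the number of cell lines", call. = FALSE)
  }
  structure(list(cell_line_id = ids,
                 tissue = if (is.null(tissue)) NULL else as.character(tissue),
                 expression = zscore_normalize(expression)),
            class = "cell_line_panel")
}

#' Build a model-ready labeled triplet dataset
#'
#' Applies the full preprocessing chain to raw synergy measurements:
#' records are resolved against the drug and cell-line panels (unresolvable
#' rows dropped with a reported count), scored by [label_by_threshold()]
#' (the ambiguous `[0, 30]` band is removed before voting), deduplicated per
#' unordered (drug pair, cell line) triplet by [majority_vote()], and stored
#' with the lexicographically smaller drug identifier first. Optional order
#' augmentation adds the swapped copy of each triplet with the same label, so
#' the model sees both drug orderings.
#'
#' @param drugs A [drug_panel()].
#' @param cell_lines A [cell_line_panel()].
#' @param records A data.frame with columns `drug1_id`, `drug2_id`,
#'   `cell_line_id`, `synergy_score` (and optionally `source`).
#' @param augment_order Add swapped-order duplicates (default `FALSE`).
#' @return An object of class `synergy_dataset`: the labeled triplet table,
#'   the two panels, and positive/negative counts.
#' @export
build_dataset <- function(drugs, cell_lines, records, augment_order = FALSE) {
  stopifnot(inherits(drugs, "drug_panel"),
            inherits(cell_lines, "cell_line_panel"))
  req <- c("drug1_id", "drug2_id", "cell_line_id", "synergy_score")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rec <- data.frame(drug1 = as.character(records$drug1_id),
                    drug2 = as.character(records$drug2_id),
                    cell = as.character(records$cell_line_id),
                    score = as.numeric(records$synergy_score),
                    stringsAsFactors = FALSE)

  known <- rec$drug1 %in% drugs$drug_id & rec$drug2 %in% drugs$drug_id &
    rec$cell %in% cell_lines$cell_line_id
  if (any(!known)) {
    message("dropped ", sum(!known),
            " record(s) with unknown drugs or cell lines")
    rec <- rec[known, , drop = FALSE]
  }
  selfpair <- rec$drug1 == rec$drug2
  if (any(selfpair)) {
    message("dropped ", sum(selfpair), " self-pair record(s)")
    rec <- rec[!selfpair, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no usable synergy records", call. = FALSE)

  rec$label <- label_by_threshold(rec$score)
  rec <- rec[rec$label != "excluded", , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("empty dataset: every record fell in the excluded score band",
         call. = FALSE)
  }

  d1 <- pmin(rec$drug1, rec$drug2)
  d2 <- pmax(rec$drug1, rec$drug2)
  key <- paste(d1, d2, rec$cell, sep = "\r")
  votes <- tapply(rec$label, key, majority_vote)
  keep <- names(votes)[votes != "excluded"]
  if (length(keep) == 0L) {
    stop("empty dataset: all triplets were majority-vote ties", call. = FALSE)
  }
  parts <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
  trip <- data.frame(drug1 = parts[, 1L], drug2 = parts[, 2L],
                     cell_line = parts[, 3L],
                     label = as.integer(votes[keep] == "positive"),
                     key = keep, stringsAsFactors = FALSE)
  trip <- trip[order(trip$key), , drop = FALSE]
  rownames(trip) <- NULL

  if (augment_order) {
    swapped <- trip
    swapped$drug1 <- trip$drug2
    swapped$drug2 <- trip$drug1
    trip <- rbind(trip, swapped)
    rownames(trip) <- NULL
  }

  npos <- sum(trip$label == 1L)
  nneg <- sum(trip$label == 0L)
  message(sprintf("dataset: %d triplets (%d positive, %d negative, neg:pos = %.2f)",
                  nrow(trip), npos, nneg,
                  if (npos > 0) nneg / npos else NA_real_))
  structure(list(triplets = trip, drugs = drugs, cell_lines = cell_lines,
                 augmented = augment_order, n_pos = npos, n_neg = nneg),
            class = "synergy_dataset")
}

#' @export
print.synergy_dataset <- function(x, ...) {
  cat("Drug-combination synergy dataset\n")
  cat(sprintf("  %d labeled triplets (%d positive, %d negative)%s\n",
              nrow(x$triplets), x$n_pos, x$n_neg,
              if (x$augmented) ", order-augmented" else ""))
  cat(sprintf("  %d drugs, %d cell lines, %d genes\n",
              length(x$drugs$drug_id), length(x$cell_lines$cell_line_id),
              ncol(x$cell_lines$expression)))
  invisible(x)
}

#' Read the delimited input tables of the pipeline
#'
#' Thin readers for the CSV/TSV dialects the pipeline consumes: a drug table
#' (`drug_id`, `smiles`), a combination table (`drug1_id`, `drug2_id`,
#' `cell_line_id`, `synergy_score`\[, `source`\]), an expression matrix with
#' cell-line row names, and an optional tissue map (`cell_line_id`,
#' `tissue`). The delimiter is sniffed from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path Path to the file.
#' @return A data.frame (or numeric matrix for the expression reader).
#' @export
read_drug_table <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(all(c("drug_id", "smiles") %in% names(df)))
  df
}

#' @rdname read_drug_table
#' @export
read_combo_table <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(all(c("drug1_id", "drug2_id", "cell_line_id",
                  "synergy_score") %in% names(df)))
  df
}

#' @rdname read_drug_table
#' @export
read_expression_matrix <- function(path) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_drug_table
#' @export
read_tissue_map <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(all(c("cell_line_id", "tissue") %in% names(df)))
  df
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
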