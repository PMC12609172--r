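#' Compute a 1024-bit ECFP6 fingerprint from a SMILES string
#'
#' Encodes a molecule as an extended-connectivity (Morgan) circular
#' fingerprint of diameter 6 (radius 3). The native 4096-bit ECFP6 vector
#' produced by OpenBabel is folded to 1024 bits by OR-ing its four 1024-bit
#' pages, the standard fixed-length folding used for Tanimoto screening.
#' SMILES are canonicalized internally, so syntactically different encodings
#' of the same molecule yield identical bit vectors.
#'
#' @param smiles A single SMILES string.
#' @return An integer vector of length 1024 with entries 0/1.
#' @examples
#' fp <- compute_fingerprint("CCO")
#' sum(fp) # number of set bits
#' @export
compute_fingerprint <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("invalid molecule: empty or non-string SMILES", call. = FALSE)
  }
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) list())
  if (length(mol) == 0L) {
    stop(sprintf("invalid molecule: SMILES '%s' could not be parsed", smiles),
         call. = FALSE)
  }
  raw <- tryCatch(as.integer(ChemmineOB::fingerprint_OB(mol, "ECFP6")),
                  error = function(e) NULL)
  if (is.null(raw) || length(raw) < 1024L) {
    stop(sprintf("invalid molecule: SMILES '%s' could not be fingerprinted",
                 smiles), call. = FALSE)
  }
  pages <- matrix(raw[seq_len(4096L)], nrow = 1024L)
  as.integer(rowSums(pages) > 0)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' Computes `|A intersect B| / |A union B|` for two equal-length 0/1 vectors.
#' Two all-zero fingerprints have similarity 0 by convention.
#'
#' @param fp_a,fp_b Binary (0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b),
         call. = FALSE)
  }
  a <- fp_a != 0
  b <- fp_b != 0
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

#' Tanimoto profile of a drug against a reference panel
#'
#' The numerical representation of a drug is its vector of Tanimoto
#' similarities against every drug of a fixed reference panel (ordered as the
#' panel is). The panel is frozen per experiment so that drugs unseen during
#' training still receive profiles of the training feature dimension.
#'
#' @param fingerprint A binary fingerprint vector.
#' @param panel A matrix of reference fingerprints, one row per drug.
#' @return A numeric vector of length `nrow(panel)` with entries in `[0, 1]`.
#' @export
tanimoto_profile <- function(fingerprint, panel) {
  if (is.null(dim(panel)) || nrow(panel) < 1L) {
    stop("reference panel must be a non-empty fingerprint matrix",
         call. = FALSE)
  }
  apply(panel, 1L, tanimoto, fp_a = fingerprint)
}

# All-pairs profile matrix: rows = drugs, columns = reference panel drugs.
# Vectorized via bit-count algebra; equals element-wise tanimoto() calls.
tanimoto_matrix <- function(fps, ref_fps) {
  a <- (fps != 0) * 1
  b <- (ref_fps != 0) * 1
  inter <- a %*% t(b)
  na <- rowSums(a)
  nb <- rowSums(b)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(fps), rownames(ref_fps))
  out
}
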