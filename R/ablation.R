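#' Run a paired ablation comparison
#'
#' Trains the requested model variants under identical data, split and seed
#' (so the comparison is paired) and tabulates the eight test-set metrics
#' per variant. Because the primary model's prediction head is itself built
#' on the dual-stage attention residual, the comparison is run with that
#' residual disabled for every variant by default, isolating the effect of
#' each mechanism; set `residual_head = TRUE` to compare full architectures
#' instead.
#'
#' @param dataset A `synergy_dataset`.
#' @param names Character vector of variant names, or `"all"`.
#' @param config A [model_config()] shared by every variant.
#' @param split A `synergy_split` shared by every variant (default: fold 1
#'   of a random split under the config seed).
#' @param residual_head Whether variants other than `"w/o-res"` keep the
#'   attention-residual head (default `FALSE` for a fair comparison).
#' @param threshold Classification threshold for the tabulated metrics.
#' @param verbose Print progress per variant.
#' @return A data.frame with one row per variant and the eight metrics,
#'   with the fitted models attached as attribute `"models"`.
#' @export
run_ablation <- function(dataset, names = "all", config = model_config(),
                         split = NULL, residual_head = FALSE,
                         threshold = 0.5, verbose = FALSE) {
  if (identical(names, "all")) names <- variant_names
  bad <- setdiff(names, variant_names)
  if (length(bad)) {
    stop("unknown variant(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(variant_names, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(split)) {
    split <- make_split(dataset, "random_cv", seed = config$seed)[[1L]]
  }
  models <- list()
  rows <- NULL
  for (nm in names) {
    if (verbose) message("training variant '", nm, "'")
    cfg <- build_variant(nm, config, residual_head = residual_head)
    fit <- dsa_deepfm(dataset, split = split, config = cfg)
    rep <- evaluate(fit, threshold = threshold)
    rows <- rbind(rows, cbind(data.frame(variant = nm),
                              as.data.frame(rep)))
    models[[nm]] <- fit
  }
  rownames(rows) <- NULL
  attr(rows, "models") <- models
  rows
}
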