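#' Model and training configuration
#'
#' Collects every architecture and optimization hyperparameter of the
#' dual-stage attention DeepFM. Defaults follow the published configuration:
#' embedding dimension `E = 512` governing the attention blocks and the FM
#' input, FM latent dimension `K = 1024`, a 512 x 1024 hidden deep network
#' whose output width must equal `K` so the two branches can be fused,
#' dropout 0.5, Adam at learning rate 0.001 with exponential step decay, and
#' unweighted cross-entropy (set `w_pos = 2.3, w_neg = 1` for the
#' class-weighted mode matched to a 1:2.3 positive:negative imbalance).
#'
#' @param E Embedding dimension of each field.
#' @param K FM latent dimension and width of both fused branches.
#' @param dnn_hidden Width of the first hidden DNN layer (the second equals
#'   `K` by the fusion contract).
#' @param hidden_pred Width of the penultimate prediction layer.
#' @param feat_hidden Hidden width of the numerical feature extractor.
#' @param head_widths Widths of the three-layer head used when the
#'   attention-residual is disabled.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param w_pos,w_neg Class weights of the cross-entropy loss.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation AUC-ROC.
#' @param freeze_embeddings `TRUE`, `FALSE`, or `"auto"` (freeze whenever the
#'   split regime holds out entities, where embeddings of unseen drugs or
#'   cell lines would be untrained anyway).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An object of class `dsa_deepfm_config`.
#' @export
model_config <- function(E = 512L, K = 1024L, dnn_hidden = 512L,
                         hidden_pred = 512L, feat_hidden = 1024L,
                         head_widths = c(512L, 128L), dropout = 0.5,
                         lr = 0.001, lr_decay = 0.98, w_pos = 1, w_neg = 1,
                         batch_size = 256L, epochs = 100L, patience = 10L,
                         freeze_embeddings = "auto", seed = 1L) {
  stopifnot(E >= 1L, K >= 1L, dnn_hidden >= 1L, hidden_pred >= 1L,
            feat_hidden >= 1L, length(head_widths) == 2L,
            dropout >= 0, dropout < 1, lr > 0, lr_decay > 0, lr_decay <= 1,
            w_pos > 0, w_neg > 0, batch_size >= 1L, epochs >= 1L,
            patience >= 1L, abs(seed) < 2^31 - 10)
  cfg <- as.list(environment())
  cfg$variant <- variant_switches("full")
  structure(cfg, class = "dsa_deepfm_config")
}

# The ten named ablation variants map onto five architectural switches.
variant_names <- c("full", "cat", "aux", "w/o-attn", "w/o-res", "attn-rev",
                   "attn-field", "attn-emb", "attn-unified", "gated-sum",
                   "gated-concat")

variant_switches <- function(name) {
  base <- list(name = name, use_categorical = TRUE, use_numerical = TRUE,
               attention_mode = "dual", residual_head = TRUE,
               fusion_mode = "concat")
  switch(name,
    "full" = base,
    "cat" = utils::modifyList(base, list(use_numerical = FALSE,
                                         attention_mode = "none")),
    "aux" = utils::modifyList(base, list(use_categorical = FALSE,
                                         attention_mode = "none")),
    "w/o-attn" = utils::modifyList(base, list(attention_mode = "none")),
    "w/o-res" = utils::modifyList(base, list(residual_head = FALSE)),
    "attn-rev" = utils::modifyList(base, list(attention_mode = "rev")),
    "attn-field" = utils::modifyList(base, list(attention_mode = "field")),
    "attn-emb" = utils::modifyList(base, list(attention_mode = "emb")),
    "attn-unified" = utils::modifyList(base, list(attention_mode = "unified")),
    "gated-sum" = utils::modifyList(base, list(fusion_mode = "gated_sum")),
    "gated-concat" = utils::modifyList(base, list(fusion_mode = "gated_concat")),
    stop("unknown variant '", name, "'; valid names: ",
         paste(variant_names, collapse = ", "), call. = FALSE)
  )
}

#' Construct an ablation variant configuration
#'
#' Maps a named variant onto the architectural switches of the model:
#' dropping one input stream (`"cat"`, `"aux"`), removing or reordering the
#' attention stages (`"w/o-attn"`, `"attn-rev"`, `"attn-field"`,
#' `"attn-emb"`, `"attn-unified"`), removing the attention-residual
#' prediction head (`"w/o-res"`), or replacing branch concatenation with a
#' dimension-wise softmax gate (`"gated-sum"`, `"gated-concat"`).
#' `"full"` reproduces the primary model.
#'
#' @param name One of `r paste0('\x60"', variant_names, '"\x60', collapse = ", ")`.
#' @param config A [model_config()] to specialize.
#' @param residual_head Optional override of the attention-residual head,
#'   e.g. `FALSE` for residual-free paired comparisons across variants.
#' @return A `dsa_deepfm_config` carrying the variant switches.
#' @export
build_variant <- function(name, config = model_config(),
                          residual_head = NULL) {
  stopifnot(inherits(config, "dsa_deepfm_config"))
  config$variant <- variant_switches(name)
  if (!is.null(residual_head) && name != "w/o-res") {
    config$variant$residual_head <- isTRUE(residual_head)
  }
  config
}

#' @export
print.dsa_deepfm_config <- function(x, ...) {
  v <- x$variant
  cat(sprintf("DSA-DeepFM configuration (variant '%s')\n", v$name))
  cat(sprintf("  E = %d, K = %d, DNN %d x %d, prediction hidden %d\n",
              x$E, x$K, x$dnn_hidden, x$K, x$hidden_pred))
  cat(sprintf("  dropout %.2f, lr %.4g (decay %.3g), batch %d, epochs <= %d\n",
              x$dropout, x$lr, x$lr_decay, x$batch_size, x$epochs))
  cat(sprintf("  class weights (pos, neg) = (%.2g, %.2g)\n", x$w_pos, x$w_neg))
  invisible(x)
}
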