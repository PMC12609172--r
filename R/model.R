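#' Fit a dual-stage attention DeepFM synergy classifier
#'
#' Trains the model on the labeled triplets of a dataset: categorical drug
#' and cell-line identifiers pass through a trainable embedding table, the
#' numerical profiles (two Tanimoto profiles against the training drug panel
#' plus the z-scored expression vector) through a two-layer extractor; the
#' two streams are fused by dual-stage attention, fed to a factorization
#' machine and a hidden deep network, and classified by an
#' attention-residual prediction head. Optimization is minibatch Adam with
#' exponential learning-rate decay, (optionally class-weighted)
#' cross-entropy, and early stopping on validation AUC-ROC with the best
#' validation weights restored.
#'
#' The Tanimoto reference panel is frozen to the drugs that occur in the
#' training partition, so leave-drug-out folds keep a fixed feature
#' dimension for unseen drugs. Under leave-out regimes the embedding table
#' is (by default) kept fixed at its random initialization, since rows of
#' held-out entities receive no gradient anyway.
#'
#' @param dataset A [build_dataset()] result.
#' @param split A `synergy_split` from [make_split()]; default is fold 1 of
#'   a random 3:1:1 cross-validation split drawn with the config seed.
#' @param config A [model_config()].
#' @param variant Ablation variant name (see [build_variant()]); `"full"`
#'   is the primary model.
#' @param verbose Print per-epoch progress.
#' @return An object of class `dsa_deepfm` with, among others, `$history`
#'   (per-epoch training loss and validation AUC) and `$split`.
#' @seealso [predict.dsa_deepfm()], [evaluate()], [run_ablation()]
#' @export
dsa_deepfm <- function(dataset, split = NULL, config = model_config(),
                       variant = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "synergy_dataset"),
            inherits(config, "dsa_deepfm_config"))
  if (!is.null(variant)) config <- build_variant(variant, config)
  if (is.null(split)) {
    split <- make_split(dataset, "random_cv", seed = config$seed)[[1L]]
  }
  stopifnot(inherits(split, "synergy_split"))

  freeze <- config$freeze_embeddings
  if (identical(freeze, "auto")) freeze <- split$regime != "random_cv"

  feats <- prepare_features(dataset, split)
  set.seed(config$seed)
  init <- init_params(config, feats$m, feats$n, feats$d_num)
  model <- structure(list(
    theta = init$theta, bn = init$bn, dims = init$dims, config = config,
    variant = config$variant, drug_ids = feats$drug_ids,
    cell_ids = feats$cell_ids, ref_ids = feats$ref_ids,
    profiles = feats$profiles, expression = feats$expr,
    emb_init = init$theta$emb, frozen_embeddings = freeze,
    split = split, history = NULL, dataset = dataset), class = "dsa_deepfm")
  fit_loop(model, feats, verbose)
}

# Precompute index vectors and numerical feature matrices for every triplet.
prepare_features <- function(dataset, split) {
  trip <- dataset$triplets
  drug_ids <- dataset$drugs$drug_id
  cell_ids <- dataset$cell_lines$cell_line_id
  train_trip <- trip[split$train, , drop = FALSE]
  ref_ids <- sort(unique(c(train_trip$drug1, train_trip$drug2)))
  fps <- dataset$drugs$fingerprints
  profiles <- tanimoto_matrix(fps, fps[ref_ids, , drop = FALSE])
  expr <- dataset$cell_lines$expression
  list(d1 = match(trip$drug1, drug_ids), d2 = match(trip$drug2, drug_ids),
       cl = match(trip$cell_line, cell_ids), y = trip$label,
       profiles = profiles, expr = expr, m = length(drug_ids),
       n = length(cell_ids), d_num = 2L * ncol(profiles) + ncol(expr),
       drug_ids = drug_ids, cell_ids = cell_ids, ref_ids = ref_ids)
}

feature_batch <- function(feats, idx) {
  d1 <- feats$d1[idx]
  d2 <- feats$d2[idx]
  cl <- feats$cl[idx]
  list(d1 = d1, d2 = d2, cl = cl,
       Xn1 = feats$profiles[d1, , drop = FALSE],
       Xn2 = feats$profiles[d2, , drop = FALSE],
       Xc = feats$expr[cl, , drop = FALSE],
       y = feats$y[idx])
}

adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0), t = 0L)
}

adam_step <- function(theta, grads, opt, lr, skip = character(0),
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g) || nm %in% skip) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    theta[[nm]] <- theta[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(theta = theta, opt = opt)
}

copy_bn <- function(bn) {
  out <- list(fm = new_bn_state(length(bn$fm$running_mean)),
              dnn = new_bn_state(length(bn$dnn$running_mean)))
  out$fm$running_mean <- bn$fm$running_mean
  out$fm$running_var <- bn$fm$running_var
  out$dnn$running_mean <- bn$dnn$running_mean
  out$dnn$running_var <- bn$dnn$running_var
  out
}

fit_loop <- function(model, feats, verbose) {
  cfg <- model$config
  split <- model$split
  skip <- if (model$frozen_embeddings) "emb" else character(0)
  opt <- adam_init(model$theta)
  best <- list(auc = -Inf, theta = model$theta, bn = copy_bn(model$bn),
               epoch = 0L)
  history <- NULL
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- cfg$lr * cfg$lr_decay^(epoch - 1L)
    order_idx <- sample(split$train)
    nb <- ceiling(length(order_idx) / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- order_idx[seq.int((b - 1L) * cfg$batch_size + 1L,
                               min(b * cfg$batch_size, length(order_idx)))]
      batch <- feature_batch(feats, idx)
      tp <- ad_tape()
      pn <- wrap_params(tp, model$theta)
      fw <- model_forward(tp, pn, model$bn, cfg, model$dims, batch,
                          training = TRUE)
      ls <- loss_node(tp, fw$p, batch$y, cfg$w_pos, cfg$w_neg)
      if (!is.finite(ls$value)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d, batch %d (lr %.3g)",
          epoch, b, lr_e), call. = FALSE)
      }
      ad_backward(tp, ls)
      grads <- lapply(pn, function(nd) nd$grad)
      upd <- adam_step(model$theta, grads, opt, lr_e, skip = skip)
      model$theta <- upd$theta
      opt <- upd$opt
      ep_loss <- ep_loss + ls$value * length(idx)
    }
    ep_loss <- ep_loss / length(order_idx)
    val_p <- predict_indices(model, feats, split$val)
    val_y <- feats$y[split$val]
    val_auc <- if (length(unique(val_y)) == 2L) {
      auc_rank(val_p, val_y)
    } else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss,
                                val_auc = val_auc, lr = lr_e))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val AUC %.4f", epoch, ep_loss,
                      val_auc))
    }
    if (!is.na(val_auc) && val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, theta = model$theta,
                   bn = copy_bn(model$bn), epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (is.finite(best$auc)) {
    model$theta <- best$theta
    model$bn <- best$bn
  }
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_auc <- best$auc
  model
}

# deterministic eval-mode probabilities for triplet indices of the dataset
predict_indices <- function(model, feats, idx, chunk = 2048L,
                            capture = character(0)) {
  out <- numeric(length(idx))
  caps <- list()
  at <- 1L
  while (at <= length(idx)) {
    take <- idx[seq.int(at, min(at + chunk - 1L, length(idx)))]
    batch <- feature_batch(feats, take)
    tp <- ad_tape()
    pn <- wrap_params(tp, model$theta)
    fw <- model_forward(tp, pn, model$bn, model$config, model$dims, batch,
                        training = FALSE, capture = capture)
    out[seq.int(at, at + length(take) - 1L)] <- as.vector(fw$p$value)
    if (length(capture)) {
      caps[[length(caps) + 1L]] <- fw$captures
    }
    at <- at + length(take)
  }
  if (length(capture)) {
    merged <- lapply(capture, function(st) {
      do.call(rbind, lapply(caps, `[[`, st))
    })
    names(merged) <- capture
    attr(out, "captures") <- merged
  }
  out
}

#' Predict synergy probabilities
#'
#' Evaluates the fitted model in deterministic eval mode (no dropout; batch
#' normalization uses running statistics). `newdata` may be a data.frame of
#' triplets with columns `drug1`, `drug2`, `cell_line` (identifiers must
#' belong to the fitted panels), a `synergy_dataset` sharing the fitted
#' panels, or `NULL` for the model's own training dataset.
#'
#' @param object A fitted `dsa_deepfm`.
#' @param newdata Triplets to score (see Details).
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at
#'   `threshold`.
#' @param threshold Classification threshold for `type = "class"`.
#' @param ... Unused.
#' @return A numeric (or integer) vector, one entry per triplet.
#' @export
predict.dsa_deepfm <- function(object, newdata = NULL, type = c("prob",
                                                                "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  trip <- resolve_triplets(object, newdata)
  feats <- triplet_features(object, trip)
  p <- predict_indices(object, feats, seq_len(nrow(trip)))
  if (type == "class") as.integer(p >= threshold) else p
}

resolve_triplets <- function(object, newdata) {
  if (is.null(newdata)) return(object$dataset$triplets)
  if (inherits(newdata, "synergy_dataset")) return(newdata$triplets)
  stopifnot(is.data.frame(newdata),
            all(c("drug1", "drug2", "cell_line") %in% names(newdata)))
  newdata
}

triplet_features <- function(object, trip) {
  d1 <- match(trip$drug1, object$drug_ids)
  d2 <- match(trip$drug2, object$drug_ids)
  cl <- match(trip$cell_line, object$cell_ids)
  if (anyNA(d1) || anyNA(d2)) {
    bad <- unique(c(trip$drug1[is.na(d1)], trip$drug2[is.na(d2)]))
    stop("unknown drug identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(cl)) {
    stop("unknown cell line(s): ",
         paste(unique(trip$cell_line[is.na(cl)]), collapse = ", "),
         call. = FALSE)
  }
  list(d1 = d1, d2 = d2, cl = cl,
       y = if ("label" %in% names(trip)) trip$label else rep(NA_integer_,
                                                             nrow(trip)),
       profiles = object$profiles, expr = object$expression,
       m = length(object$drug_ids), n = length(object$cell_ids),
       d_num = object$dims$d_num, drug_ids = object$drug_ids,
       cell_ids = object$cell_ids, ref_ids = object$ref_ids)
}

#' Evaluate a fitted model on a test partition
#'
#' @param model A fitted `dsa_deepfm`.
#' @param dataset The dataset to score; defaults to the model's own.
#' @param indices Triplet indices to evaluate; defaults to the test
#'   partition of the model's split.
#' @param threshold Classification threshold.
#' @return A [metric_report()].
#' @export
evaluate <- function(model, dataset = NULL, indices = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "dsa_deepfm"))
  dataset <- dataset %||% model$dataset
  indices <- indices %||% model$split$test
  trip <- dataset$triplets[indices, , drop = FALSE]
  p <- predict(model, trip)
  metric_report(p, trip$label, threshold = threshold)
}

#' @export
print.dsa_deepfm <- function(x, ...) {
  cat(sprintf("DSA-DeepFM synergy classifier (variant '%s')\n",
              x$variant$name))
  cat(sprintf("  panels: %d drugs, %d cell lines; reference panel %d drugs\n",
              length(x$drug_ids), length(x$cell_ids), length(x$ref_ids)))
  cat(sprintf("  E = %d, K = %d, %s parameters%s\n", x$config$E, x$config$K,
              format(n_params(x), big.mark = ","),
              if (x$frozen_embeddings) " (embeddings frozen)" else ""))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epoch(s); best val AUC %.4f at epoch %d\n",
                nrow(x$history), x$best_val_auc, x$best_epoch))
  }
  cat(sprintf("  split: %s fold %d\n", x$split$regime, x$split$fold))
  invisible(x)
}

#' @export
summary.dsa_deepfm <- function(object, ...) {
  print(object)
  cat("\nTest-partition metrics:\n")
  print(evaluate(object))
  invisible(object)
}

#' @export
coef.dsa_deepfm <- function(object, ...) object$theta

n_params <- function(model) {
  sum(vapply(model$theta, length, numeric(1L)))
}

#' @export
plot.dsa_deepfm <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$val_auc, type = "l", xlab = "epoch",
       ylab = "validation AUC-ROC", main = "validation AUC", ...)
  invisible(x)
}

#' @export
residuals.dsa_deepfm <- function(object, ...) {
  trip <- object$dataset$triplets[object$split$test, , drop = FALSE]
  trip$label - predict(object, trip)
}

#' Save / load a fitted model
#'
#' The checkpoint is a parameter archive (`params.rds`: weights, batch-norm
#' running statistics, panels) plus a human-readable YAML snapshot of the
#' configuration. Loading reproduces eval-mode predictions bit-for-bit.
#'
#' @param model A fitted `dsa_deepfm`.
#' @param dir Checkpoint directory (created if missing).
#' @return `save_dsa_deepfm` returns `dir` invisibly; `load_dsa_deepfm`
#'   returns the restored model.
#' @export
save_dsa_deepfm <- function(model, dir) {
  stopifnot(inherits(model, "dsa_deepfm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  state <- unclass(model)
  state$bn <- list(fm = as.list(model$bn$fm), dnn = as.list(model$bn$dnn))
  state$config <- unclass(model$config)
  saveRDS(state, file.path(dir, "params.rds"))
  cfg <- model$config
  snap <- cfg[!vapply(cfg, is.function, logical(1L))]
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_dsa_deepfm
#' @export
load_dsa_deepfm <- function(dir) {
  state <- readRDS(file.path(dir, "params.rds"))
  bn <- list(fm = new_bn_state(length(state$bn$fm$running_mean)),
             dnn = new_bn_state(length(state$bn$dnn$running_mean)))
  bn$fm$running_mean <- state$bn$fm$running_mean
  bn$fm$running_var <- state$bn$fm$running_var
  bn$dnn$running_mean <- state$bn$dnn$running_mean
  bn$dnn$running_var <- state$bn$dnn$running_var
  state$bn <- bn
  class(state$config) <- "dsa_deepfm_config"
  structure(state, class = "dsa_deepfm")
}
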