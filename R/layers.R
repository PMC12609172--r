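# Parameter initialization and the forward computation graph.
#
# The network is built from two input streams over three fields (drug 1,
# drug 2, cell line): a trainable embedding table for the categorical
# identifiers and a two-layer extractor for the numerical profiles. The
# streams are fused by dual-stage attention (per-field gates, then
# per-embedding-dimension gates, each a softmax over the two streams with a
# residual update), flattened to a 6E vector feeding a factorization machine
# and a hidden deep network, whose batch-normalized outputs are merged and
# passed through a second, independently parameterized dual-stage attention
# acting as a residual before the final classifier.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros_row <- function(d) matrix(0, 1L, d)

new_bn_state <- function(d) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, d)
  st$running_var <- rep(1, d)
  st
}

# attention parameter block: two stream projections + shared scorer
init_attn_field <- function(theta, prefix, E) {
  theta[[paste0(prefix, "_Wa")]] <- glorot(E, E)
  theta[[paste0(prefix, "_ba")]] <- zeros_row(E)
  theta[[paste0(prefix, "_Wb")]] <- glorot(E, E)
  theta[[paste0(prefix, "_bb")]] <- zeros_row(E)
  theta[[paste0(prefix, "_Ws")]] <- glorot(2L * E, 2L)
  theta[[paste0(prefix, "_bs")]] <- zeros_row(2L)
  theta
}

init_attn_emb <- function(theta, prefix, nf) {
  theta[[paste0(prefix, "_Wa")]] <- glorot(nf, nf)
  theta[[paste0(prefix, "_ba")]] <- zeros_row(nf)
  theta[[paste0(prefix, "_Wb")]] <- glorot(nf, nf)
  theta[[paste0(prefix, "_bb")]] <- zeros_row(nf)
  theta[[paste0(prefix, "_Ws")]] <- glorot(2L * nf, 2L)
  theta[[paste0(prefix, "_bs")]] <- zeros_row(2L)
  theta
}

model_dims <- function(cfg, m, n, d_num) {
  v <- cfg$variant
  streams <- sum(v$use_categorical, v$use_numerical)
  x_dim <- streams * 3L * cfg$E
  fuse_dim <- if (v$fusion_mode == "gated_sum") cfg$K else 2L * cfg$K
  list(m = m, n = n, d_num = d_num, E = cfg$E, K = cfg$K,
       streams = streams, x_dim = x_dim, n_fields_head = x_dim %/% cfg$E,
       fuse_dim = fuse_dim)
}

init_params <- function(cfg, m, n, d_num) {
  v <- cfg$variant
  dm <- model_dims(cfg, m, n, d_num)
  E <- cfg$E
  theta <- list()
  if (v$use_categorical) {
    theta$emb <- matrix(stats::rnorm((m + n) * E, sd = 0.05), m + n, E)
  }
  if (v$use_numerical) {
    theta$feat_W1 <- glorot(d_num, cfg$feat_hidden)
    theta$feat_b1 <- zeros_row(cfg$feat_hidden)
    theta$feat_W2 <- glorot(cfg$feat_hidden, 3L * E)
    theta$feat_b2 <- zeros_row(3L * E)
  }
  if (dm$streams == 2L) {
    if (v$attention_mode %in% c("dual", "rev", "field")) {
      theta <- init_attn_field(theta, "d1f", E)
    }
    if (v$attention_mode %in% c("dual", "rev", "emb")) {
      theta <- init_attn_emb(theta, "d1e", 3L)
    }
    if (v$attention_mode == "unified") {
      theta$uni_W <- glorot(dm$x_dim, dm$x_dim)
      theta$uni_b <- zeros_row(dm$x_dim)
    }
  }
  theta$fm_W <- glorot(dm$x_dim, cfg$K)
  theta$fm_V <- matrix(stats::rnorm(dm$x_dim * cfg$K, sd = 0.05),
                       dm$x_dim, cfg$K)
  theta$dnn_W1 <- glorot(dm$x_dim, cfg$dnn_hidden)
  theta$dnn_b1 <- zeros_row(cfg$dnn_hidden)
  theta$dnn_W2 <- glorot(cfg$dnn_hidden, cfg$K)
  theta$dnn_b2 <- zeros_row(cfg$K)
  theta$bn_fm_gamma <- matrix(1, 1L, cfg$K)
  theta$bn_fm_beta <- zeros_row(cfg$K)
  theta$bn_dnn_gamma <- matrix(1, 1L, cfg$K)
  theta$bn_dnn_beta <- zeros_row(cfg$K)
  if (v$fusion_mode %in% c("gated_sum", "gated_concat")) {
    theta$gate_W <- glorot(2L, 2L)
    theta$gate_b <- zeros_row(2L)
  }
  theta$hp_W <- glorot(dm$fuse_dim, dm$x_dim)
  theta$hp_b <- zeros_row(dm$x_dim)
  if (v$residual_head) {
    theta <- init_attn_field(theta, "hdf", E)
    theta <- init_attn_emb(theta, "hde", dm$n_fields_head)
    theta$out_W1 <- glorot(2L * dm$x_dim, cfg$hidden_pred)
    theta$out_b1 <- zeros_row(cfg$hidden_pred)
    theta$out_W2 <- glorot(cfg$hidden_pred, 2L)
    theta$out_b2 <- zeros_row(2L)
  } else {
    hw <- cfg$head_widths
    theta$r_W1 <- glorot(2L * dm$x_dim, hw[1L])
    theta$r_b1 <- zeros_row(hw[1L])
    theta$r_W2 <- glorot(hw[1L], hw[2L])
    theta$r_b2 <- zeros_row(hw[2L])
    theta$r_W3 <- glorot(hw[2L], 2L)
    theta$r_b3 <- zeros_row(2L)
  }
  list(theta = theta,
       bn = list(fm = new_bn_state(cfg$K), dnn = new_bn_state(cfg$K)),
       dims = dm)
}

# closed-form parameter count mirroring init_params; used to catch shape
# drift (both routes must agree for every variant)
expected_param_count <- function(cfg, m, n, d_num) {
  v <- cfg$variant
  dm <- model_dims(cfg, m, n, d_num)
  E <- cfg$E
  K <- cfg$K
  attn_field_n <- function(E) 2L * (E * E + E) + 2L * E * 2L + 2L
  attn_emb_n <- function(nf) 2L * (nf * nf + nf) + 2L * nf * 2L + 2L
  total <- 0
  if (v$use_categorical) total <- total + (m + n) * E
  if (v$use_numerical) {
    total <- total + d_num * cfg$feat_hidden + cfg$feat_hidden +
      cfg$feat_hidden * 3 * E + 3 * E
  }
  if (dm$streams == 2L) {
    if (v$attention_mode %in% c("dual", "rev", "field")) {
      total <- total + attn_field_n(E)
    }
    if (v$attention_mode %in% c("dual", "rev", "emb")) {
      total <- total + attn_emb_n(3L)
    }
    if (v$attention_mode == "unified") {
      total <- total + dm$x_dim * dm$x_dim + dm$x_dim
    }
  }
  total <- total + 2 * dm$x_dim * K                       # FM W and V
  total <- total + dm$x_dim * cfg$dnn_hidden + cfg$dnn_hidden +
    cfg$dnn_hidden * K + K
  total <- total + 4 * K                                  # two BN gamma/beta
  if (v$fusion_mode %in% c("gated_sum", "gated_concat")) total <- total + 6
  total <- total + dm$fuse_dim * dm$x_dim + dm$x_dim
  if (v$residual_head) {
    total <- total + attn_field_n(E) + attn_emb_n(dm$n_fields_head) +
      2 * dm$x_dim * cfg$hidden_pred + cfg$hidden_pred +
      cfg$hidden_pred * 2 + 2
  } else {
    hw <- cfg$head_widths
    total <- total + 2 * dm$x_dim * hw[1L] + hw[1L] +
      hw[1L] * hw[2L] + hw[2L] + hw[2L] * 2 + 2
  }
  total
}

wrap_params <- function(tape, theta) {
  lapply(theta, function(v) ad_leaf(tape, v))
}

# field-aware attention over two streams given as lists of B x E field nodes;
# returns updated streams plus the per-field stream-one scores (values)
attn_field_stage <- function(tp, sa, sb, pn, prefix) {
  Wa <- pn[[paste0(prefix, "_Wa")]]; ba <- pn[[paste0(prefix, "_ba")]]
  Wb <- pn[[paste0(prefix, "_Wb")]]; bb <- pn[[paste0(prefix, "_bb")]]
  Ws <- pn[[paste0(prefix, "_Ws")]]; bs <- pn[[paste0(prefix, "_bs")]]
  scores <- NULL
  for (f in seq_along(sa)) {
    ha <- ad_add_bias(tp, ad_matmul(tp, sa[[f]], Wa), ba)
    hb <- ad_add_bias(tp, ad_matmul(tp, sb[[f]], Wb), bb)
    sc <- ad_add_bias(tp, ad_matmul(tp, ad_concat_cols(tp, list(ha, hb)), Ws),
                      bs)
    g1 <- ad_pair_softmax(tp, sc)
    g2 <- ad_one_minus(tp, g1)
    sa[[f]] <- ad_add(tp, sa[[f]], ad_mul_col(tp, sa[[f]], g1))
    sb[[f]] <- ad_add(tp, sb[[f]], ad_mul_col(tp, sb[[f]], g2))
    scores <- cbind(scores, as.vector(g1$value))
  }
  list(a = sa, b = sb, score = scores)
}

# embedding-aware attention: one gate per embedding dimension, shared across
# fields; streams are stacked to (B*E) x F so the per-dimension projections
# become ordinary matrix products
attn_emb_stage <- function(tp, sa, sb, pn, prefix) {
  B <- nrow(sa[[1L]]$value)
  E <- ncol(sa[[1L]]$value)
  Ta <- ad_stack_fields(tp, sa)
  Tb <- ad_stack_fields(tp, sb)
  Pa <- ad_add_bias(tp, ad_matmul(tp, Ta, pn[[paste0(prefix, "_Wa")]]),
                    pn[[paste0(prefix, "_ba")]])
  Pb <- ad_add_bias(tp, ad_matmul(tp, Tb, pn[[paste0(prefix, "_Wb")]]),
                    pn[[paste0(prefix, "_bb")]])
  sc <- ad_add_bias(tp, ad_matmul(tp, ad_concat_cols(tp, list(Pa, Pb)),
                                  pn[[paste0(prefix, "_Ws")]]),
                    pn[[paste0(prefix, "_bs")]])
  g1 <- ad_pair_softmax(tp, sc)
  g2 <- ad_one_minus(tp, g1)
  Sa <- ad_unstack_col(tp, g1, B, E)
  Sb <- ad_unstack_col(tp, g2, B, E)
  for (f in seq_along(sa)) {
    sa[[f]] <- ad_add(tp, sa[[f]], ad_mul(tp, sa[[f]], Sa))
    sb[[f]] <- ad_add(tp, sb[[f]], ad_mul(tp, sb[[f]], Sb))
  }
  list(a = sa, b = sb, score = Sa$value)
}

# split a B x (F*E) node into F field nodes of width E
split_fields <- function(tp, x, nf, E) {
  lapply(seq_len(nf), function(f) {
    ad_cols(tp, x, seq.int((f - 1L) * E + 1L, f * E))
  })
}

fm_block <- function(tp, x, pn) {
  first <- ad_matmul(tp, x, pn$fm_W)
  xv <- ad_matmul(tp, x, pn$fm_V)
  x2v2 <- ad_matmul(tp, ad_square(tp, x), ad_square(tp, pn$fm_V))
  second <- ad_scale(tp, ad_sub(tp, ad_square(tp, xv), x2v2), 0.5)
  ad_add(tp, first, second)
}

dnn_block <- function(tp, x, pn, dropout, training) {
  h <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, x, pn$dnn_W1),
                                  pn$dnn_b1))
  if (training) h <- ad_dropout(tp, h, dropout)
  h <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, h, pn$dnn_W2),
                                  pn$dnn_b2))
  if (training) h <- ad_dropout(tp, h, dropout)
  h
}

# Full forward pass for one minibatch. `batch` carries integer field indices
# and the numerical input matrices; returns the synergy probability node and
# any captured stage representations.
model_forward <- function(tp, pn, bn, cfg, dims, batch, training = FALSE,
                          capture = character(0)) {
  v <- cfg$variant
  E <- cfg$E
  caps <- list()
  streams <- list()

  if (v$use_categorical) {
    cat_fields <- list(ad_gather(tp, pn$emb, batch$d1),
                       ad_gather(tp, pn$emb, batch$d2),
                       ad_gather(tp, pn$emb, batch$cl + dims$m))
    streams$cat <- cat_fields
    if ("embedding_trained" %in% capture) {
      caps$embedding_trained <- do.call(cbind,
                                        lapply(cat_fields, `[[`, "value"))
    }
  }
  if (v$use_numerical) {
    xraw <- cbind(batch$Xn1, batch$Xn2, batch$Xc)
    if ("aux_raw" %in% capture) caps$aux_raw <- xraw
    xn <- ad_const(tp, xraw)
    h <- ad_relu(tp, ad_add_bias(tp, ad_matmul(tp, xn, pn$feat_W1),
                                 pn$feat_b1))
    out <- ad_add_bias(tp, ad_matmul(tp, h, pn$feat_W2), pn$feat_b2)
    num_fields <- split_fields(tp, out, 3L, E)
    streams$num <- num_fields
    if ("aux_extracted" %in% capture) caps$aux_extracted <- out$value
  }

  if (dims$streams == 2L) {
    sa <- streams$cat
    sb <- streams$num
    mode <- v$attention_mode
    if (mode == "dual") {
      st <- attn_field_stage(tp, sa, sb, pn, "d1f")
      st <- attn_emb_stage(tp, st$a, st$b, pn, "d1e")
      sa <- st$a; sb <- st$b
    } else if (mode == "rev") {
      st <- attn_emb_stage(tp, sa, sb, pn, "d1e")
      st <- attn_field_stage(tp, st$a, st$b, pn, "d1f")
      sa <- st$a; sb <- st$b
    } else if (mode == "field") {
      st <- attn_field_stage(tp, sa, sb, pn, "d1f")
      sa <- st$a; sb <- st$b
    } else if (mode == "emb") {
      st <- attn_emb_stage(tp, sa, sb, pn, "d1e")
      sa <- st$a; sb <- st$b
    }
    x <- ad_concat_cols(tp, c(sa, sb))
    if (mode == "unified") {
      gate <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, x, pn$uni_W),
                                         pn$uni_b))
      x <- ad_add(tp, x, ad_mul(tp, x, gate))
    }
  } else {
    x <- ad_concat_cols(tp, c(streams$cat, streams$num))
  }
  if ("dsa_fused" %in% capture) caps$dsa_fused <- x$value

  y_fm <- fm_block(tp, x, pn)
  y_dnn <- dnn_block(tp, x, pn, cfg$dropout, training)
  y_fm <- ad_batchnorm(tp, y_fm, pn$bn_fm_gamma, pn$bn_fm_beta, bn$fm,
                       training)
  y_dnn <- ad_batchnorm(tp, y_dnn, pn$bn_dnn_gamma, pn$bn_dnn_beta, bn$dnn,
                        training)

  if (v$fusion_mode == "concat") {
    fused <- ad_concat_cols(tp, list(y_fm, y_dnn))
  } else {
    # dimension-wise softmax gate over the stacked branch outputs
    B <- nrow(y_fm$value)
    Tg <- ad_stack_fields(tp, list(y_fm, y_dnn))
    sc <- ad_add_bias(tp, ad_matmul(tp, Tg, pn$gate_W), pn$gate_b)
    g1 <- ad_pair_softmax(tp, sc)
    gf <- ad_unstack_col(tp, g1, B, cfg$K)
    gd <- ad_unstack_col(tp, ad_one_minus(tp, g1), B, cfg$K)
    wf <- ad_mul(tp, y_fm, gf)
    wd <- ad_mul(tp, y_dnn, gd)
    fused <- if (v$fusion_mode == "gated_sum") {
      ad_add(tp, wf, wd)
    } else {
      ad_concat_cols(tp, list(wf, wd))
    }
  }

  x1 <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, fused, pn$hp_W),
                                   pn$hp_b))
  if (training) x1 <- ad_dropout(tp, x1, cfg$dropout)

  if (v$residual_head) {
    fa <- split_fields(tp, x, dims$n_fields_head, E)
    fb <- split_fields(tp, x1, dims$n_fields_head, E)
    st <- attn_field_stage(tp, fa, fb, pn, "hdf")
    st <- attn_emb_stage(tp, st$a, st$b, pn, "hde")
    pre <- ad_concat_cols(tp, c(st$a, st$b))
    if ("pre_prediction" %in% capture) caps$pre_prediction <- pre$value
    h <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, pre, pn$out_W1),
                                    pn$out_b1))
    z <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, h, pn$out_W2),
                                    pn$out_b2))
  } else {
    pre <- ad_concat_cols(tp, list(x, x1))
    if ("pre_prediction" %in% capture) caps$pre_prediction <- pre$value
    h <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, pre, pn$r_W1),
                                    pn$r_b1))
    h <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, h, pn$r_W2), pn$r_b2))
    z <- ad_add_bias(tp, ad_matmul(tp, h, pn$r_W3), pn$r_b3)
  }
  # softmax over the two logits; P(synergistic) = sigmoid(z2 - z1)
  p <- ad_sigmoid(tp, ad_sub(tp, ad_cols(tp, z, 2L), ad_cols(tp, z, 1L)))
  list(p = p, captures = caps)
}

# class-weighted cross-entropy as a graph node; probabilities are clamped at
# 1e-7 before the log
loss_node <- function(tp, p, y, w_pos, w_neg) {
  B <- length(y)
  ym <- matrix(as.numeric(y), ncol = 1L)
  pt <- ad_add(tp, ad_mul(tp, p, ad_const(tp, ym)),
               ad_mul(tp, ad_one_minus(tp, p), ad_const(tp, 1 - ym)))
  lg <- ad_log(tp, ad_clamp(tp, pt, 1e-7, 1 - 1e-7))
  wv <- matrix(ifelse(y == 1, w_pos, w_neg) / B, ncol = 1L)
  ad_sum(tp, ad_mul(tp, lg, ad_const(tp, -wv)))
}
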