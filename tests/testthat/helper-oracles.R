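# Independent straight-line oracles used to check the vectorized
# implementations. These deliberately use naive loops.

ns <- asNamespace("synergyfm")

# brute-force factorization machine: first-order term plus explicit double
# sum over feature pairs
fm_bruteforce <- function(x, W, V) {
  d <- length(x)
  out <- as.vector(x %*% W)
  for (i in seq_len(d - 1L)) {
    for (j in seq.int(i + 1L, d)) {
      out <- out + V[i, ] * V[j, ] * x[i] * x[j]
    }
  }
  out
}

softmax2 <- function(s) exp(s) / sum(exp(s))

# per-sample field-aware attention oracle (projection, concat, softmax over
# the two streams, residual scale)
field_attention_oracle <- function(Xa, Xb, p) {
  # Xa, Xb: F x E matrices for one sample
  outa <- Xa
  outb <- Xb
  sc <- NULL
  for (f in seq_len(nrow(Xa))) {
    ha <- as.vector(Xa[f, ] %*% p$Wa) + as.vector(p$ba)
    hb <- as.vector(Xb[f, ] %*% p$Wb) + as.vector(p$bb)
    s <- softmax2(as.vector(c(ha, hb) %*% p$Ws) + as.vector(p$bs))
    outa[f, ] <- Xa[f, ] * s[1L] + Xa[f, ]
    outb[f, ] <- Xb[f, ] * s[2L] + Xb[f, ]
    sc <- rbind(sc, unname(s))
  }
  dimnames(sc) <- NULL
  list(a = outa, b = outb, score = sc)
}

# per-sample embedding-aware attention oracle: per embedding dimension,
# project the across-field vectors of both streams, score, residual scale
embedding_attention_oracle <- function(Xa, Xb, p) {
  outa <- Xa
  outb <- Xb
  sc <- NULL
  for (j in seq_len(ncol(Xa))) {
    pa <- as.vector(Xa[, j] %*% p$Wa) + as.vector(p$ba)
    pb <- as.vector(Xb[, j] %*% p$Wb) + as.vector(p$bb)
    s <- softmax2(as.vector(c(pa, pb) %*% p$Ws) + as.vector(p$bs))
    outa[, j] <- Xa[, j] * s[1L] + Xa[, j]
    outb[, j] <- Xb[, j] * s[2L] + Xb[, j]
    sc <- rbind(sc, unname(s))
  }
  dimnames(sc) <- NULL
  list(a = outa, b = outb, score = sc)
}

# O(n^2) separation-statistics oracle with explicit pairwise loops
separation_oracle <- function(mat, labels) {
  mu <- colMeans(mat)
  sdv <- sqrt(colMeans(mat^2) - mu^2)
  x <- mat
  for (j in seq_len(ncol(mat))) {
    x[, j] <- if (sdv[j] > 0) (mat[, j] - mu[j]) / sdv[j] else 0
  }
  for (i in seq_len(nrow(x))) {
    nv <- sqrt(sum(x[i, ]^2))
    if (nv > 0) x[i, ] <- x[i, ] / nv
  }
  cosd <- function(a, b) 1 - sum(a * b)
  classes <- sort(unique(labels))
  intra <- numeric(2L)
  cents <- list()
  for (c_i in 1:2) {
    rows <- which(labels == classes[c_i])
    tot <- 0
    cnt <- 0
    for (a in seq_along(rows)) {
      for (b in seq_along(rows)) {
        if (a < b) {
          tot <- tot + cosd(x[rows[a], ], x[rows[b], ])
          cnt <- cnt + 1L
        }
      }
    }
    intra[c_i] <- tot / cnt
    cen <- colMeans(x[rows, , drop = FALSE])
    cents[[c_i]] <- cen / sqrt(sum(cen^2))
  }
  inter <- cosd(cents[[1L]], cents[[2L]])
  list(intra = mean(intra), inter = inter, margin = inter - mean(intra),
       ratio = mean(intra) / inter)
}

# random stream / attention-parameter builders and tape runners shared by
# the attention oracle tests
make_stream <- function(b, nf, e, seed) {
  set.seed(seed)
  lapply(seq_len(nf), function(f) matrix(rnorm(b * e), b, e))
}

attn_params <- function(e, seed, zero_scorer = FALSE) {
  set.seed(seed)
  p <- list(Wa = matrix(rnorm(e * e, sd = 0.4), e, e),
            ba = matrix(rnorm(e, sd = 0.2), 1L),
            Wb = matrix(rnorm(e * e, sd = 0.4), e, e),
            bb = matrix(rnorm(e, sd = 0.2), 1L),
            Ws = matrix(rnorm(2 * e * 2, sd = 0.4), 2L * e, 2L),
            bs = matrix(rnorm(2, sd = 0.2), 1L))
  if (zero_scorer) {
    p$Ws[] <- 0
    p$bs[] <- 0
  }
  p
}

run_field_stage <- function(sa_val, sb_val, p) {
  tp <- ns$ad_tape()
  pn <- list()
  for (nm in names(p)) pn[[paste0("t_", nm)]] <- ns$ad_leaf(tp, p[[nm]])
  sa <- lapply(sa_val, ns$ad_const, tape = tp)
  sb <- lapply(sb_val, ns$ad_const, tape = tp)
  ns$attn_field_stage(tp, sa, sb, pn, "t")
}

run_emb_stage <- function(sa_val, sb_val, p) {
  tp <- ns$ad_tape()
  pn <- list()
  for (nm in names(p)) pn[[paste0("t_", nm)]] <- ns$ad_leaf(tp, p[[nm]])
  sa <- lapply(sa_val, ns$ad_const, tape = tp)
  sb <- lapply(sb_val, ns$ad_const, tape = tp)
  ns$attn_emb_stage(tp, sa, sb, pn, "t")
}

# brute-force average precision: recompute the confusion matrix from
# scratch at every distinct threshold
average_precision_bruteforce <- function(prob, y) {
  ths <- sort(unique(prob), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (t in ths) {
    pred <- prob >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(y == 1)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
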