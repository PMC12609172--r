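# Unit tests of the model building blocks against straight-line oracles.

test_that("field-aware attention matches the per-sample oracle", {
  b <- 3L; e <- 4L
  sa <- make_stream(b, 3L, e, 1)
  sb <- make_stream(b, 3L, e, 2)
  p <- attn_params(e, 3)
  st <- run_field_stage(sa, sb, p)
  for (s in seq_len(b)) {
    Xa <- do.call(rbind, lapply(sa, function(m) m[s, ]))
    Xb <- do.call(rbind, lapply(sb, function(m) m[s, ]))
    or <- field_attention_oracle(Xa, Xb, p)
    for (f in 1:3) {
      expect_equal(st$a[[f]]$value[s, ], or$a[f, ], tolerance = 1e-6)
      expect_equal(st$b[[f]]$value[s, ], or$b[f, ], tolerance = 1e-6)
      expect_equal(st$score[s, f], or$score[f, 1L], tolerance = 1e-6)
    }
  }
})

test_that("embedding-aware attention matches the per-dimension oracle", {
  b <- 3L; e <- 5L
  sa <- make_stream(b, 3L, e, 4)
  sb <- make_stream(b, 3L, e, 5)
  p <- attn_params(3L, 6)  # projections act across the 3 fields
  st <- run_emb_stage(sa, sb, p)
  for (s in seq_len(b)) {
    Xa <- do.call(rbind, lapply(sa, function(m) m[s, ]))  # 3 x E
    Xb <- do.call(rbind, lapply(sb, function(m) m[s, ]))
    or <- embedding_attention_oracle(Xa, Xb, p)
    for (f in 1:3) {
      expect_equal(st$a[[f]]$value[s, ], or$a[f, ], tolerance = 1e-6)
      expect_equal(st$b[[f]]$value[s, ], or$b[f, ], tolerance = 1e-6)
    }
    expect_equal(st$score[s, ], or$score[, 1L], tolerance = 1e-6)
  }
})

test_that("attention scores of the two streams sum to one at both stages", {
  b <- 6L; e <- 4L
  sa <- make_stream(b, 3L, e, 7)
  sb <- make_stream(b, 3L, e, 8)
  stf <- run_field_stage(sa, sb, attn_params(e, 9))
  ste <- run_emb_stage(sa, sb, attn_params(3L, 10))
  # returned scores are the stream-one shares; the complement is 1 - s by
  # the two-way softmax, so verify the share reproduces the explicit softmax
  for (s in 1:b) {
    Xa <- do.call(rbind, lapply(sa, function(m) m[s, ]))
    Xb <- do.call(rbind, lapply(sb, function(m) m[s, ]))
    orf <- field_attention_oracle(Xa, Xb, attn_params(e, 9))
    expect_equal(rowSums(orf$score), rep(1, 3), tolerance = 1e-12)
    expect_equal(stf$score[s, ], orf$score[, 1L], tolerance = 1e-6)
  }
  expect_true(all(stf$score > 0 & stf$score < 1))
  expect_true(all(ste$score > 0 & ste$score < 1))
})

test_that("zero scorers give exact (0.5, 0.5) scores and 1.5x residual output", {
  b <- 4L; e <- 3L
  sa <- make_stream(b, 3L, e, 11)
  sb <- make_stream(b, 3L, e, 12)
  stf <- run_field_stage(sa, sb, attn_params(e, 13, zero_scorer = TRUE))
  ste <- run_emb_stage(sa, sb, attn_params(3L, 14, zero_scorer = TRUE))
  expect_true(all(stf$score == 0.5))
  expect_true(all(ste$score == 0.5))
  for (f in 1:3) {
    expect_equal(stf$a[[f]]$value, 1.5 * sa[[f]], tolerance = 1e-12)
    expect_equal(stf$b[[f]]$value, 1.5 * sb[[f]], tolerance = 1e-12)
    expect_equal(ste$a[[f]]$value, 1.5 * sa[[f]], tolerance = 1e-12)
  }
})

test_that("residual gating scales each row norm into (1, 2) times the input", {
  b <- 5L; e <- 4L
  sa <- make_stream(b, 3L, e, 15)
  sb <- make_stream(b, 3L, e, 16)
  st <- run_field_stage(sa, sb, attn_params(e, 17))
  for (f in 1:3) {
    rin <- sqrt(rowSums(sa[[f]]^2))
    rout <- sqrt(rowSums(st$a[[f]]$value^2))
    expect_true(all(rout > rin & rout < 2 * rin))
  }
})

test_that("the efficient FM form equals the brute-force pairwise double sum", {
  set.seed(18)
  d <- 12L; k <- 5L
  for (rep in 1:20) {
    x <- rnorm(d)
    W <- matrix(rnorm(d * k), d, k)
    V <- matrix(rnorm(d * k), d, k)
    tp <- ns$ad_tape()
    pn <- list(fm_W = ns$ad_leaf(tp, W), fm_V = ns$ad_leaf(tp, V))
    out <- ns$fm_block(tp, ns$ad_const(tp, matrix(x, 1L)), pn)
    expect_equal(as.vector(out$value), fm_bruteforce(x, W, V),
                 tolerance = 1e-6)
  }
  # zero input and single-nonzero-coordinate cases
  x0 <- numeric(d)
  tp <- ns$ad_tape()
  pn <- list(fm_W = ns$ad_leaf(tp, matrix(rnorm(d * k), d, k)),
             fm_V = ns$ad_leaf(tp, matrix(rnorm(d * k), d, k)))
  expect_equal(as.vector(ns$fm_block(tp, ns$ad_const(tp, matrix(x0, 1L)),
                                     pn)$value), rep(0, k))
  x1 <- numeric(d); x1[4] <- 2.5
  out1 <- ns$fm_block(tp, ns$ad_const(tp, matrix(x1, 1L)), pn)
  expect_equal(as.vector(out1$value), as.vector(x1 %*% pn$fm_W$value),
               tolerance = 1e-10)
})

test_that("numerical feature extraction follows the affine-relu-affine oracle", {
  set.seed(19)
  cfg <- build_variant("full", tiny_config())
  init <- ns$init_params(cfg, m = 5L, n = 2L, d_num = 14L)
  b <- 3L
  batch <- list(d1 = c(1L, 2L, 3L), d2 = c(4L, 5L, 1L), cl = c(1L, 2L, 1L),
                Xn1 = matrix(rnorm(b * 5), b), Xn2 = matrix(rnorm(b * 5), b),
                Xc = matrix(rnorm(b * 4), b), y = c(1L, 0L, 1L))
  tp <- ns$ad_tape()
  pn <- ns$wrap_params(tp, init$theta)
  fw <- ns$model_forward(tp, pn, init$bn, cfg, init$dims, batch,
                         training = FALSE, capture = "aux_extracted")
  xraw <- cbind(batch$Xn1, batch$Xn2, batch$Xc)
  h <- pmax(sweep(xraw %*% init$theta$feat_W1, 2, init$theta$feat_b1, "+"), 0)
  oracle <- sweep(h %*% init$theta$feat_W2, 2, init$theta$feat_b2, "+")
  expect_equal(fw$captures$aux_extracted, oracle, tolerance = 1e-10)
  expect_equal(dim(oracle), c(b, 3L * cfg$E))

  # zero input with zero biases maps to zero
  th0 <- init$theta
  th0$feat_b1[] <- 0; th0$feat_b2[] <- 0
  batch0 <- batch
  batch0$Xn1[] <- 0; batch0$Xn2[] <- 0; batch0$Xc[] <- 0
  tp0 <- ns$ad_tape()
  fw0 <- ns$model_forward(tp0, ns$wrap_params(tp0, th0), init$bn, cfg,
                          init$dims, batch0, capture = "aux_extracted")
  expect_equal(max(abs(fw0$captures$aux_extracted)), 0)
})

test_that("categorical embedding is an exact table lookup", {
  cfg <- build_variant("full", tiny_config())
  init <- ns$init_params(cfg, m = 6L, n = 3L, d_num = 10L)
  b <- 4L
  batch <- list(d1 = c(2L, 2L, 5L, 1L), d2 = c(3L, 4L, 6L, 2L),
                cl = c(1L, 3L, 2L, 1L),
                Xn1 = matrix(0, b, 3L), Xn2 = matrix(0, b, 3L),
                Xc = matrix(0, b, 4L), y = rep(1L, b))
  tp <- ns$ad_tape()
  fw <- ns$model_forward(tp, ns$wrap_params(tp, init$theta), init$bn, cfg,
                         init$dims, batch, capture = "embedding_trained")
  e <- cfg$E
  emb <- init$theta$emb
  expect_equal(fw$captures$embedding_trained[, 1:e],
               emb[batch$d1, , drop = FALSE])
  expect_equal(fw$captures$embedding_trained[, (e + 1):(2 * e)],
               emb[batch$d2, , drop = FALSE])
  expect_equal(fw$captures$embedding_trained[, (2 * e + 1):(3 * e)],
               emb[batch$cl + 6L, , drop = FALSE])
  # two triplets sharing drug1 share the first field row
  expect_equal(fw$captures$embedding_trained[1L, 1:e],
               fw$captures$embedding_trained[2L, 1:e])
})

test_that("forward output is a valid probability, robust to all-zero inputs", {
  cfg <- build_variant("full", tiny_config())
  init <- ns$init_params(cfg, m = 4L, n = 2L, d_num = 8L)
  init$theta$emb[] <- 0
  b <- 3L
  batch <- list(d1 = c(1L, 2L, 3L), d2 = c(2L, 3L, 4L), cl = c(1L, 2L, 1L),
                Xn1 = matrix(0, b, 2L), Xn2 = matrix(0, b, 2L),
                Xc = matrix(0, b, 4L), y = c(1L, 0L, 1L))
  tp <- ns$ad_tape()
  fw <- ns$model_forward(tp, ns$wrap_params(tp, init$theta), init$bn, cfg,
                         init$dims, batch, training = FALSE,
                         capture = "dsa_fused")
  p <- as.vector(fw$p$value)
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
  # zero bundles stay zero through the softmax-gated residual stages
  expect_equal(max(abs(fw$captures$dsa_fused)), 0)
})

test_that("parameter counts match the closed-form expectation per variant", {
  cfg0 <- tiny_config()
  for (nm in ns$variant_names) {
    cfg <- build_variant(nm, cfg0)
    init <- ns$init_params(cfg, m = 7L, n = 3L, d_num = 11L)
    got <- sum(vapply(init$theta, length, numeric(1L)))
    expect_equal(got, ns$expected_param_count(cfg, 7L, 3L, 11L),
                 info = nm)
  }
  expect_error(build_variant("nope"), "valid names")
})

test_that("full-model gradients agree with central finite differences", {
  set.seed(20)
  cfg <- build_variant("full", model_config(
    E = 4L, K = 5L, dnn_hidden = 6L, hidden_pred = 5L, feat_hidden = 7L,
    dropout = 0, seed = 9L))
  init <- ns$init_params(cfg, 6L, 3L, 13L)
  b <- 5L
  batch <- list(d1 = sample(6L, b, TRUE), d2 = sample(6L, b, TRUE),
                cl = sample(3L, b, TRUE), Xn1 = matrix(rnorm(b * 4), b),
                Xn2 = matrix(rnorm(b * 4), b), Xc = matrix(rnorm(b * 5), b),
                y = rbinom(b, 1, 0.5))
  lossval <- function(theta) {
    bn <- list(fm = ns$new_bn_state(cfg$K), dnn = ns$new_bn_state(cfg$K))
    tp <- ns$ad_tape()
    fw <- ns$model_forward(tp, ns$wrap_params(tp, theta), bn, cfg,
                           init$dims, batch, training = TRUE)
    ns$loss_node(tp, fw$p, batch$y, 2.3, 1)$value[1L]
  }
  bn <- list(fm = ns$new_bn_state(cfg$K), dnn = ns$new_bn_state(cfg$K))
  tp <- ns$ad_tape()
  pn <- ns$wrap_params(tp, init$theta)
  fw <- ns$model_forward(tp, pn, bn, cfg, init$dims, batch, training = TRUE)
  ls <- ns$loss_node(tp, fw$p, batch$y, 2.3, 1)
  ns$ad_backward(tp, ls)
  eps <- 1e-5
  for (nm in names(init$theta)) {
    idx <- sample(length(init$theta[[nm]]), min(3L,
                                                length(init$theta[[nm]])))
    for (i in idx) {
      th <- init$theta
      th[[nm]][i] <- th[[nm]][i] + eps
      up <- lossval(th)
      th[[nm]][i] <- th[[nm]][i] - 2 * eps
      dn <- lossval(th)
      expect_equal(pn[[nm]]$grad[i], (up - dn) / (2 * eps),
                   tolerance = 1e-4, info = nm)
    }
  }
})

test_that("one gradient step on one example decreases the loss", {
  cfg <- build_variant("full", tiny_config(dropout = 0))
  set.seed(21)
  init <- ns$init_params(cfg, 4L, 2L, 9L)
  batch <- list(d1 = 1L, d2 = 2L, cl = 1L, Xn1 = matrix(rnorm(3), 1L),
                Xn2 = matrix(rnorm(3), 1L), Xc = matrix(rnorm(3), 1L),
                y = 1L)
  lossfun <- function(theta, bn) {
    tp <- ns$ad_tape()
    pn <- ns$wrap_params(tp, theta)
    fw <- ns$model_forward(tp, pn, bn, cfg, init$dims, batch,
                           training = TRUE)
    list(loss = ns$loss_node(tp, fw$p, batch$y, 1, 1), pn = pn, tape = tp)
  }
  bn <- init$bn
  r1 <- lossfun(init$theta, bn)
  ns$ad_backward(r1$tape, r1$loss)
  theta2 <- init$theta
  for (nm in names(theta2)) {
    g <- r1$pn[[nm]]$grad
    if (!is.null(g)) theta2[[nm]] <- theta2[[nm]] - 0.01 * g
  }
  r2 <- lossfun(theta2, bn)
  expect_lt(r2$loss$value[1L], r1$loss$value[1L])
})

test_that("eval mode is deterministic and checkpoints restore it exactly", {
  ds <- small_dataset()
  fit <- memo("tiny_fit", {
    sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp, tiny_config())
  })
  p1 <- predict(fit)
  p2 <- predict(fit)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))

  td <- withr::local_tempdir()
  save_dsa_deepfm(fit, td)
  expect_true(file.exists(file.path(td, "config.yaml")))
  fit2 <- load_dsa_deepfm(td)
  expect_identical(predict(fit2), p1)

  # unknown entities are named in prediction errors
  expect_error(predict(fit, data.frame(drug1 = "nope", drug2 = "DRUG002",
                                       cell_line = "CELL01")), "nope")
  expect_error(predict(fit, data.frame(drug1 = "DRUG001", drug2 = "DRUG002",
                                       cell_line = "badcell")), "badcell")
})
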