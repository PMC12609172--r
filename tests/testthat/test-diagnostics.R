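test_that("training reduces the loss on a learnable synthetic dataset", {
  ds <- small_dataset()
  sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
  fit <- memo("loss_curve_fit",
              dsa_deepfm(ds, sp, tiny_config(epochs = 5L, patience = 5L)))
  h <- fit$history
  expect_gte(nrow(h), 5L)
  expect_lt(h$train_loss[5L], h$train_loss[1L])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("frozen-embedding mode leaves the table bit-identical", {
  ds <- small_dataset()
  sp <- make_split(ds, "leave_cell_line_out", fold_count = 3L,
                   seed = 6L)[[1L]]
  # leave-out regimes freeze by default ("auto")
  fit <- dsa_deepfm(ds, sp, tiny_config(epochs = 2L))
  expect_true(fit$frozen_embeddings)
  expect_identical(fit$theta$emb, fit$emb_init)
  # while an unfrozen fit moves the table
  fit2 <- memo("tiny_fit", {
    sp2 <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp2, tiny_config())
  })
  expect_false(identical(fit2$theta$emb, fit2$emb_init))
})

test_that("stage extraction exposes the six documented boundaries", {
  fit <- memo("tiny_fit", {
    ds <- small_dataset()
    sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp, tiny_config())
  })
  idx <- fit$split$test[1:40]
  e <- fit$config$E
  st <- extract_stage(fit, indices = idx, stage = "embedding_init")
  expect_equal(dim(st$matrix), c(40L, 3L * e))
  # pre-training snapshot equals a lookup of the initial table
  trip <- fit$dataset$triplets[idx, ]
  d1 <- match(trip$drug1, fit$drug_ids)
  expect_equal(st$matrix[, 1:e], unname(fit$emb_init[d1, ]))

  raw <- extract_stage(fit, indices = idx, stage = "aux_raw")
  expect_equal(dim(raw$matrix), c(40L, fit$dims$d_num))
  # verbatim concatenated numerical input
  expect_equal(raw$matrix[, 1:ncol(fit$profiles)],
               unname(fit$profiles[d1, ]))

  fused <- extract_stage(fit, indices = idx, stage = "dsa_fused")
  expect_equal(ncol(fused$matrix), 6L * e)
  pre <- extract_stage(fit, indices = idx, stage = "pre_prediction")
  expect_equal(ncol(pre$matrix), 12L * e)
  expect_equal(pre$labels, trip$label)

  expect_error(extract_stage(fit, stage = "nope"), "valid stages")
})

test_that("separation statistics equal the brute-force pairwise oracle", {
  set.seed(40)
  for (i in 1:5) {
    mat <- matrix(rnorm(20 * 5), 20, 5)
    labels <- rep(c(0, 1), each = 10)
    s <- separation_stats(mat, labels)
    o <- separation_oracle(mat, labels)
    expect_equal(s$intra, o$intra, tolerance = 1e-9)
    expect_equal(s$inter, o$inter, tolerance = 1e-9)
    expect_equal(s$margin, o$margin, tolerance = 1e-9)
    expect_equal(s$ratio, o$ratio, tolerance = 1e-9)
    # invariant under class relabeling and row permutation
    s2 <- separation_stats(mat, 1 - labels)
    expect_equal(s2$margin, s$margin, tolerance = 1e-12)
    perm <- sample(20)
    s3 <- separation_stats(mat[perm, ], labels[perm])
    expect_equal(s3$margin, s$margin, tolerance = 1e-9)
  }
})

test_that("separation statistics handle the geometric limit cases", {
  set.seed(41)
  base <- matrix(rnorm(8 * 4), 8, 4)
  # identical clouds for both classes: coincident centroids, flagged
  s <- separation_stats(rbind(base, base), rep(c(0, 1), each = 8))
  expect_true(s$degenerate)
  expect_true(is.na(s$ratio))
  expect_lt(abs(s$inter), 1e-8)
  # two tight antipodal clusters: intra ~ 0, inter ~ 2
  dir <- rnorm(6)
  up <- matrix(rep(dir, 6), 6, byrow = TRUE) + matrix(rnorm(36, sd = 1e-4), 6)
  dn <- -up + matrix(rnorm(36, sd = 1e-4), 6)
  mat <- rbind(up, dn)
  mat <- mat + matrix(rnorm(length(mat), sd = 1e-6), nrow(mat))
  s2 <- separation_stats(mat, rep(c(1, 0), each = 6))
  expect_lt(s2$intra, 0.05)
  expect_gt(s2$inter, 1.9)
  expect_gt(s2$margin, 1.85)
  # single-class input errors
  expect_error(separation_stats(base, rep(1, 8)), "two classes")
})

test_that("2-D projection returns one coordinate pair per triplet", {
  set.seed(42)
  mat <- matrix(rnorm(30 * 6), 30, 6)
  xy <- project_2d(mat)
  expect_equal(dim(xy), c(30L, 2L))
})

test_that("order consistency reports paired probabilities and flags", {
  fit <- memo("tiny_fit", {
    ds <- small_dataset()
    sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp, tiny_config())
  })
  oc <- order_consistency(fit)
  expect_true(all(c("p_ab", "p_ba") %in% names(oc$pairs)))
  expect_false(any(duplicated(
    oc$pairs[, c("drug1", "drug2", "cell_line")])))
  expect_true(is.finite(oc$pearson))
  # constant-output model: correlation undefined and flagged
  const_fit <- fit
  const_fit$theta$out_W1[] <- 0
  const_fit$theta$out_b1[] <- 0
  const_fit$theta$out_W2[] <- 0
  const_fit$theta$out_b2[] <- 0
  oc0 <- order_consistency(const_fit)
  expect_true(oc0$constant)
  expect_true(is.na(oc0$pearson))
})

test_that("frequency quartiles are balanced and aggregate consistently", {
  fit <- memo("tiny_fit", {
    ds <- small_dataset()
    sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp, tiny_config())
  })
  aud <- frequency_quartile_audit(fit)
  expect_equal(nrow(aud), 5L)
  sizes <- aud$n[1:4]
  expect_lte(max(sizes) - min(sizes), 1L)
  # weighted quartile positive proportions reproduce the overall proportion
  expect_equal(sum(sizes * aud$pos_proportion[1:4]) / sum(sizes),
               aud$pos_proportion[5L], tolerance = 1e-12)
  expect_equal(sum(sizes), aud$n[5L])
})

test_that("discovery ranks unordered pairs symmetrically above the cutoff", {
  fit <- memo("tiny_fit", {
    ds <- small_dataset()
    sp <- make_split(ds, "random_cv", seed = 5L)[[1L]]
    dsa_deepfm(ds, sp, tiny_config())
  })
  panel <- fit$drug_ids[1:4]
  cl <- fit$cell_ids[1L]
  hits <- discover(fit, cl, drugs = panel, cutoff = 0)
  expect_equal(nrow(hits), 6L)  # C(4, 2)
  expect_equal(hits$score_mean, (hits$score_ab + hits$score_ba) / 2)
  expect_true(all(diff(hits$score_mean) <= 0))
  # permuting the panel order leaves the ranking unchanged
  hits2 <- discover(fit, cl, drugs = rev(panel), cutoff = 0)
  expect_equal(hits, hits2)
  # an unreachable cutoff and full exclusion give empty results
  expect_equal(nrow(discover(fit, cl, drugs = panel, cutoff = 1.1)), 0L)
  expect_warning(
    none <- discover(fit, cl, drugs = panel,
                     exclude = hits[, c("drug1", "drug2")]),
    "no candidate")
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(discover(fit, cl, drugs = panel, cutoff = 0,
                             top_k = 2L)), 2L)
})
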