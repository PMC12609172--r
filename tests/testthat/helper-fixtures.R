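# Programmatic fixtures shared across test files. The heavier trained
# models are memoized so several test files can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small study + dataset for cheap structural tests
small_study <- function(seed = 3L, ...) {
  simulate_synergy_study(synthetic_config(
    m_drugs = 20L, n_cell_lines = 6L, n_tissues = 3L, g_genes = 30L,
    seed = seed, ...))
}

small_dataset <- function(seed = 3L, augment = TRUE) {
  memo(paste0("small_ds_", seed, "_", augment), {
    st <- small_study(seed)
    suppressMessages(build_dataset(st$drugs$panel, st$cell_lines$panel,
                                   st$records, augment_order = augment))
  })
}

tiny_config <- function(...) {
  args <- list(E = 8L, K = 10L, dnn_hidden = 8L, hidden_pred = 8L,
               feat_hidden = 12L, dropout = 0.2, epochs = 2L, patience = 2L,
               batch_size = 64L, seed = 5L)
  do.call(model_config, utils::modifyList(args, list(...)))
}

# Study conditions for the parameter-recovery experiment: a 40-drug,
# 8-cell-line screen with a strong latent interaction signal and low noise,
# order-augmented, with the reduced model (E = 32, K = 64).
recovery_config <- function() {
  synthetic_config(m_drugs = 40L, n_cell_lines = 8L, n_tissues = 4L,
                   g_genes = 60L, latent_dim = 6L, interaction_strength = 2,
                   noise_sd = 0.3, triplet_fraction = 0.7, seed = 101L)
}

reduced_model_config <- function() {
  model_config(E = 32L, K = 64L, dnn_hidden = 64L, hidden_pred = 64L,
               feat_hidden = 64L, dropout = 0.2, lr = 0.001, epochs = 30L,
               patience = 6L, batch_size = 256L, seed = 101L)
}

recovery_dataset <- function() {
  memo("recovery_ds", {
    st <- simulate_synergy_study(recovery_config())
    ds <- suppressMessages(build_dataset(st$drugs$panel,
                                         st$cell_lines$panel, st$records,
                                         augment_order = TRUE))
    list(dataset = ds, study = st)
  })
}

recovery_fit <- function() {
  memo("recovery_fit", {
    rd <- recovery_dataset()
    split <- make_split(rd$dataset, "random_cv", seed = 101L)[[1L]]
    fit <- dsa_deepfm(rd$dataset, split = split,
                      config = reduced_model_config())
    list(fit = fit, split = split, dataset = rd$dataset, study = rd$study)
  })
}

recovery_fit_cat <- function() {
  memo("recovery_fit_cat", {
    rf <- recovery_fit()
    dsa_deepfm(rf$dataset, split = rf$split,
               config = reduced_model_config(), variant = "cat")
  })
}

# label permutation applied per unordered pair so augmentation closure holds
permuted_dataset <- function(ds, seed = 202L) {
  set.seed(seed)
  keys <- unique(ds$triplets$key)
  newlab <- sample(ds$triplets$label[match(keys, ds$triplets$key)])
  ds$triplets$label <- newlab[match(ds$triplets$key, keys)]
  ds
}

recovery_fit_permuted <- function() {
  memo("recovery_fit_perm", {
    rf <- recovery_fit()
    dsa_deepfm(permuted_dataset(rf$dataset), split = rf$split,
               config = reduced_model_config())
  })
}

# dataset sized so every leave-out regime is feasible with 5 folds
regime_dataset <- function() {
  memo("regime_ds", {
    st <- simulate_synergy_study(synthetic_config(
      m_drugs = 20L, n_cell_lines = 10L, n_tissues = 5L, g_genes = 20L,
      triplet_fraction = 0.6, seed = 17L))
    suppressMessages(build_dataset(st$drugs$panel, st$cell_lines$panel,
                                   st$records, augment_order = TRUE))
  })
}

# ~50-triplet smoke dataset for variant constructability
smoke_dataset <- function() {
  memo("smoke_ds", {
    st <- simulate_synergy_study(synthetic_config(
      m_drugs = 8L, n_cell_lines = 2L, n_tissues = 1L, g_genes = 10L,
      seed = 23L))
    suppressMessages(build_dataset(st$drugs$panel, st$cell_lines$panel,
                                   st$records, augment_order = FALSE))
  })
}
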