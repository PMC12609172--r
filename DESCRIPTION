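Package: synergyfm
Title: Dual-Stage Attention Factorization-Machine Models for Drug
    Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts synergistic two-drug combinations on cancer cell
    lines with a dual-stage attention DeepFM classifier. Provides the
    preprocessing pipeline (synergy-score thresholding, majority voting,
    ECFP6 fingerprints, Tanimoto profiles, z-scored expression), the model
    itself (dense categorical embeddings, a numerical feature extractor,
    field-aware and embedding-aware attention, a factorization machine,
    a hidden deep network, and an attention-residual prediction head)
    trained by backpropagation on a built-in reverse-mode tape, four
    cross-validation regimes including leave-cell-line-out, eight
    imbalance-aware evaluation metrics, ten ablation variants, a
    latent-factor synthetic data generator, and representation
    diagnostics for class separation and drug-order consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    caret,
    ChemmineR,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
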