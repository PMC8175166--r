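Package: mdsp
Title: Multilinear Discriminative Spatial Patterns for EEG Tensor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of movement-related cortical
    potentials (MRCPs) from multichannel EEG using multilinear discriminative
    spatial patterns (MDSP), a tensor generalization of the discriminative
    spatial patterns (DSP) Fisher-criterion filter. Provides order-agnostic
    tensor algebra (mode-k unfolding and products), the classical DSP baseline,
    alternating per-mode generalized-eigenvalue optimization with convergence
    monitoring, continuous wavelet transform tensorization of EEG epochs into
    channels x time x scale arrays, a nearest projected class-mean tensor
    classifier, seeded synthetic generators (planted multilinear subspaces and
    MRCP-like trials), and repeated stratified or grouped cross-validation with
    filter-count grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
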