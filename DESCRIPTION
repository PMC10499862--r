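Package: bflex
Title: Sequence-Based Prediction of Protein B Factors with a Bidirectional
    Recurrent Regressor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts per-residue crystallographic B factors (temperature
    factors) of protein C-alpha atoms from sequence-level features using an
    encoder, bidirectional LSTM, decoder regressor trained with a per-protein
    mean-squared-error loss. Provides PDB curation filters, per-protein
    Z-score normalization of coordinates and B factors, a 28-slot per-residue
    feature encoding with toggleable feature groups for ablation studies,
    Pearson-correlation evaluation, and interpretability analyses: sequence
    window-size sweeps, Euclidean cutoff-radius masking, the per-atom marginal
    contribution to correlation, and the normalized neighbor-count statistic.
    A synthetic C-alpha chain generator with a known local-packing ("caging")
    ground-truth law makes the full pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
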