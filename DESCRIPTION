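Package: metapred
Title: Sequence-Based Prediction of Metamorphic Proteins from
    Secondary-Structure Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein is metamorphic (fold-switching) or
    monomorphic from per-residue three-state secondary-structure probability
    profiles. Computes a per-residue diversity index (the reciprocal
    Simpson/Herfindahl concentration of the helix/strand/coil probabilities),
    classifies sequences by thresholding the maximum moving average of the
    index, and trains the window length and threshold by exhaustive
    grid search maximizing the Matthews correlation coefficient, with k-fold
    cross-validation and a two-descriptor linear discriminant. Also provides
    the structural curation filters used to assemble monomorphic reference
    sets (pairwise Kabsch RMSD, windowed secondary-structure mismatch score,
    metadata and keyword screens) and a synthetic profile generator for
    end-to-end testing without external secondary-structure predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
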