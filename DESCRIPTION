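Package: gltm
Title: Global-Local Attention Bi-LSTM for Transmembrane Dimer Motif Localization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies fixed-length (40-residue) transmembrane helix fragments
    as dimerizing or non-dimerizing with a global-local bidirectional LSTM and
    a penalized self-attention layer, and localizes the candidate dimerization
    motif (GxxxG-type, polar-residue, leucine-zipper heptad) as the
    highest-attention subsequence window. Includes random-step window
    segmentation with an overlap-aware one-hot encoding, self-focus and
    position attention penalties, a repeated-segmentation voting procedure
    with tiered residue calls, and a synthetic planted-motif benchmark
    generator for training and evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
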