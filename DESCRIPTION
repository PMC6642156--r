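Package: nelcss
Title: Neuroendocrine Lung Cancer Secretome Signatures from TMT Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for quantitative secretome analysis of
    pulmonary neuroendocrine tumor subtypes from six-plex TMT (tandem mass
    tag) experiments. Covers reporter-ion extraction from MS2 spectra,
    target-decoy FDR filtering of peptide-spectrum matches with a linear
    discriminant score, per-protein reporter summation and channel-sum
    normalization, reference-relative fold-change integration across TMT
    sets, derivation of the pan-neuroendocrine secretome signature (NE-LCSS)
    and the ASCL1/NEUROD1 subtype signature (AS/ND-LCSS) via an
    empirical-Bayes moderated t-test with Benjamini-Hochberg correction, and
    the downstream validation statistics (complete-linkage clustering with
    subtype concordance, marker-driver correlation ranking, Welch tests,
    Fisher enrichment, E-box motif scanning). Ships a synthetic-data
    generator with known ground truth so every stage is testable without the
    original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
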