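Package: lipidcontrast
Title: Untargeted LC-MS Lipidomics Contrasts Between Bacterial Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for untargeted LC-QTOF lipidomics
    comparisons between bacterial strains: chromatographic feature
    alignment into a consensus feature matrix, strain-pair missingness
    filtering, minimum-based imputation, cyclic loess normalization,
    per-feature regression statistics with Storey q-value FDR
    estimation, fold-change and volcano classification, accurate-mass
    lipid annotation with cross-polarity adduct and retention-time
    confirmation, isomer labelling, and strain-level lipid-class
    composition summaries. Includes a ground-truthed synthetic data
    generator emulating a three-strain, six-replicate, dual-polarity
    design so every stage can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
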