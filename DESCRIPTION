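Package: lfqde
Title: Label-Free Proteomic Quantitation and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end label-free shotgun-proteomics analysis: selected ion
    chromatogram (SIC) peak-area quantitation with multi-pass continuous
    wavelet peak detection and fallback window integration, retention-time
    alignment and fill-in of unfragmented peptides, spectral noise-floor
    filtering and spiked-peptide normalization; protein roll-up, missingness
    filtering and log10 transformation; a dual-test (Student t and
    Mann-Whitney U) differential-expression decision rule with
    Benjamini-Hochberg Q-values and an anchor-derived fold-change cutoff;
    PCA and Pearson-correlation clustering of the differential proteins; and
    exact 2x2 overrepresentation analysis of annotation categories. Includes
    a synthetic-data generator emulating a two-condition, five-replicate
    acclimation study design, with ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
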