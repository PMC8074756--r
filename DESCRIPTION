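Package: abscopal
Title: Multi-Omics Analysis of Out-of-Field Radiation Effects in Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying out-of-field (abscopal)
    radiation responses in mouse hippocampus from multi-omics readouts.
    Implements Raman microspectroscopy preprocessing (wavenumber
    calibration, instrument-response correction, rubberband baseline
    subtraction, vector normalization, Savitzky-Golay smoothing),
    principal component analysis and classical least squares unmixing of
    tissue spectra against pure-component reference libraries; a
    negative-binomial exact test with common-dispersion estimation for
    small-count miRNA differential expression and delta-delta-Ct PCR
    array quantification; background-variance significance testing with
    Benjamini-Hochberg adjustment and ratio capping for label-free
    proteomics; subgranular-zone cell density statistics for adult
    neurogenesis; and the set-overlap arithmetic used to compare
    deregulation across exposure modality, dose and time. A synthetic
    data module generates inputs for every stage from explicit
    statistical models with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
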