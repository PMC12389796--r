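Package: nirsasym
Title: Interhemispheric Hemodynamic Asymmetry Analysis for Motor-Imagery fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying interhemispheric asymmetry of hemodynamic
    responses in functional near-infrared spectroscopy (fNIRS) recordings from
    motor-imagery brain-computer-interface sessions. Converts dual-wavelength
    intensities to oxy-/deoxyhemoglobin concentration changes via the modified
    Beer-Lambert law, band-pass filters them with a zero-phase Chebyshev
    design, and estimates task response amplitudes with a canonical-HRF
    general linear model. Provides the bounded laterality coefficient (LC) and
    task response asymmetry coefficient (TRAC), reconstructed legacy
    laterality formulas with a numerical-stability report, and the group
    statistical layer: aligned-rank-transform factorial ANOVA, pairwise
    Wilcoxon signed-rank tests with Benjamini-Yekutieli adjustment,
    daily-slope regressions, and clinical correlations. Includes a synthetic
    multi-session cohort generator with planted response amplitudes and
    physiological noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
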