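Package: damfret
Title: Nucleation Barriers and Supersaturation from DAmFRET Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of distributed amphifluoric FRET (DAmFRET) single-cell
    flow cytometry for detecting sequence-encoded nucleation barriers in
    protein self-assembly. Builds log-binned AmFRET-versus-expression
    profiles with control-derived gates, classifies profiles as continuous
    or discontinuous using spline-smoothed medians and Hartigan's dip test,
    estimates saturation concentrations and supersaturability by fitting a
    stretched-exponential (Weibull) assembly curve, calls nucleating
    interactions from seeded screens via robust outlier degrees, classifies
    assembly morphologies from imaging summaries with an exact multinomial
    association test, and computes interaction-network centralities and
    supersaturation-lifespan regressions. Includes generators for synthetic
    event tables, screens, morphology tables, interaction graphs and
    expression-lifespan tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
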