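Package: bonemech
Title: Multi-Modal Bone Quality Analysis for Murine Models of Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("bonemech", "maintainers", email = "maintainers@bonemech.org",
           role = c("aut", "cre"))
Description: A tested pipeline for murine bone-quality studies combining
    micro-computed-tomography cross-sectional morphometry (areas, principal
    second moments of area, cortical porosity, trabecular microarchitecture),
    three-point-bending flexural property extraction, Oliver-Pharr
    nanoindentation analysis with fused-silica tip calibration, Raman
    compositional metrics with rolling-circle baseline correction, and the
    statistical layer used in diabetic-bone phenotyping (exact rank tests,
    body-mass adjustment, nested linear mixed models, Tukey post-hoc tests,
    ANCOVA, backward stepwise selection by small-sample-corrected AIC).
    Forward-model synthetic-data generators for every modality provide known
    ground truth so each analysis stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
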