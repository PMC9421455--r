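Package: epicoloc
Title: Co-Localisation of Grey-Matter Volume and White-Matter Connectivity
    Abnormalities in Temporal Lobe Epilepsy
Version: 0.1.0
Authors@R:
    person("CNNP", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: A within-patient analysis pipeline for structural neuroimaging
    abnormality mapping in temporal lobe epilepsy. Starting from per-subject
    tables of regional grey-matter volumes and mean fractional anisotropy of
    atlas-defined connections, the package harmonizes scanner batches
    (parametric empirical-Bayes ComBat), expresses features as normative
    z-scores relative to healthy controls after robust covariate regression,
    flips hemispheres into an ipsilateral/contralateral frame, maps group
    effect sizes (Cohen's d), fits two-level random-intercept-and-slope
    models linking node and edge abnormalities (REML), and quantifies
    within-patient co-localisation of volumetric and connectivity
    abnormalities with a permutation-based Dice percentile score. A seeded
    synthetic-cohort generator emulating the assumed data structure makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
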