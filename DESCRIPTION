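Package: breathflow
Title: End-Tidal Breath Extraction, Quantification and Multilevel
    Statistics for PTR-ToF-MS Breathomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for online proton-transfer-reaction time-of-flight
    mass-spectrometry (PTR-ToF-MS) breath studies with repeated measures.
    Detects CO2-based exhalation triggers in 1 Hz instrument traces, extracts
    the end-tidal fraction of each breath, normalizes ion signals to the
    primary-ion count, converts counts to ppbv concentrations via first-order
    reaction kinetics, computes IUPAC-style limits of detection from
    catalyzed-air background and applies LoD replacement and retention
    filtering. Replicate agreement is assessed with Lin's concordance
    correlation coefficient. Ion identities are assigned by accurate mass and
    fragment/cluster correlation. Group and timepoint effects are modelled
    with multilevel (within-subject) PCA and PLS-DA with VIP selection and
    subject-level repeated cross-validation, followed by univariate tests
    (Lilliefors normality, Kruskal-Wallis or ANOVA with post hoc mean-rank
    comparisons). A synthetic-study generator reproduces the assumed data
    structure with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    nortest,
    jsonlite,
    optparse
Config/testthat/edition: 3
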