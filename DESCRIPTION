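Package: stuntsem
Title: Structural Equation Models for Stunting, Socioeconomic Status,
    Gut Microbiota and Child Neurodevelopment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disentangling direct and indirect (mediated) effects
    of chronic childhood undernutrition (stunting), socioeconomic status and
    fecal microbiota composition on neurodevelopmental outcomes in young
    children.  Provides derived clinical and dietary scores (height-for-age
    categories, dietary diversity, inflammation-corrected ferritin, anemia
    and biomarker classification), microbiome data-reduction constructs
    (alpha diversity, principal coordinates, Ward clustering with automated
    elbow selection, family-level taxon screening), mixed-type association
    screening for latent-construct eligibility, and a self-contained
    covariance-structure engine for structural equation models with latent
    variables: maximum-likelihood estimation against the model-implied
    covariance matrix, standard errors, standardized solutions, fit indices
    (CFI, TLI, RMSEA, SRMR) and direct/indirect/total effect decomposition
    with delta-method standard errors.  A synthetic cohort generator with
    stored ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    pracma,
    jsonlite
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
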