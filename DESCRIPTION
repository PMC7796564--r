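Package: dilisl
Title: Leakage-Aware Super Learner Models of Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting drug-induced liver injury (DILI) risk
    categories from multi-block data: gene-expression profiles of drug-exposed
    human cell lines together with molecular descriptors of the compounds.
    Provides representative-sample selection for dose/time replicate designs,
    four-class to binary label aggregation, Welch-t and information-theoretic
    (1D and 2D) feature filters, Random-Forest base models with early
    integration of expression and chemistry, and a Super Learner layer that
    combines base models via five strategies (best single, mean of all, mean
    of the five best, non-negative linear combination, Random Forest stacker).
    Performance is estimated with repeated, stratified, grouped (clustered)
    and nested cross-validation in which all feature selection happens inside
    the training folds, preventing selection and replicate leakage.  A
    synthetic multi-block data generator with compound-level replicate
    correlation supports calibration and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
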