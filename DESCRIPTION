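Package: rtshift
Title: Chemometric Modelling of Chromatographic Retention-Time Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models systematic retention-time shifts in liquid
    chromatography under a two-factor five-level full factorial design
    (mobile-phase pH and column temperature). Estimates per-compound
    design-of-experiments coefficients by multiple linear regression with
    pure-error confidence intervals, recovers the same coefficients from
    PCA loadings through a least-squares scores-to-design conversion
    factor, partitions effects by ANOVA-simultaneous component analysis
    (ASCA), calibrates per-compound retention predictors by principal
    component regression and PLS with overlap exclusion, and predicts
    design levels from retention data with RMSEC/RMSECV component
    selection. Includes a seeded synthetic-data generator with known
    ground truth (factorial retention matrices, latent uncontrolled
    factors, LC-MS peak lists with isotopes and adducts) and an
    isotope/adduct filter that reduces peak lists to monoisotopic
    species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics
Config/testthat/edition: 3
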