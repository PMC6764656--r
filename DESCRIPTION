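Package: ramanurine
Title: Chemometric Urinalysis of Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for Raman chemometric urinalysis: reading and
    aligning multi-scan urine Raman spectra, baseline correction by an
    asymmetric iteratively reweighted polynomial fit, replicate averaging and
    vector normalization, principal component analysis of the range of normal,
    discriminant analysis of principal components (DAPC) with blind
    leave-one-out validation, and distance statistics (total principal
    component distance and total spectral distance) against a synthetic-urine
    control, analyzed by two-way ANOVA and Tukey HSD. Includes a seeded
    synthetic-cohort generator so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
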