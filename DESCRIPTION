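Package: twinpath
Title: Liability-Threshold Cholesky Twin Models with Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate Cholesky ACE variance decomposition for twin-pair
    data on the liability-threshold scale, estimated by full-information
    maximum likelihood over mixed continuous and binary phenotypes with
    arbitrary missingness. Supports polygenic risk scores as pure
    additive-genetic indicator variables, definition-variable covariate
    adjustment of thresholds, threshold-homogeneity assumption tests,
    nested model-selection ladders with likelihood-ratio tests and AIC,
    profile-likelihood and non-parametric bootstrap confidence intervals,
    FIML mixed-type correlation matrices (Pearson, polyserial,
    tetrachoric), and a seeded synthetic twin-cohort generator with both
    latent ACE and meiosis-based locus-level polygenic-score simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mnormt,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
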