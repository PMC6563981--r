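Package: sudirt
Title: Explanatory Item Response Modeling of DSM-5 Substance Use Disorder
    Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rasch measurement and explanatory item response modeling (EIRM)
    for the 11 dichotomous DSM-5 substance use disorder criteria. Provides
    marginal maximum likelihood estimation of the Rasch model with a normal
    latent trait (Gauss-Hermite quadrature), latent regression on person
    covariates (gender, alcohol use, four personality scores), nested model
    comparison by likelihood-ratio tests and information criteria, uniform
    differential item functioning scans via item-by-covariate interactions,
    EAP scoring, unidimensionality and reliability descriptives, and a
    synthetic-data generator emulating the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    pracma,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
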