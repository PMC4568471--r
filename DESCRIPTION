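Package: repsen
Title: Birth-Season Stress and Reproductive Senescence in Long-Lived Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking physiologically defined "high stress" birth
    seasons to reproductive ageing in long-lived, continuously breeding
    mammals, modelled on semi-captive Asian elephant populations. Provides a
    life-history and faecal glucocorticoid simulator with known ground truth,
    classification of the high-stress season from monthly glucocorticoid
    metabolite concentrations, construction of 3-year observation-bin
    reproduction tables, a random-intercept generalised linear mixed model
    fitter (Laplace approximation) with a brute-force likelihood oracle,
    broken-stick age-trajectory model selection by AIC over a threshold grid,
    senescence-phase birth-season interaction tests, and lifetime reproductive
    success models, together with an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
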