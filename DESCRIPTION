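Package: defaultBF
Title: Default Bayes Factor Hypothesis Tests for Common Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Default Bayes factor hypothesis tests for the designs most common
    in experimental psychology and biostatistics: the Jeffreys-Zellner-Siow
    (JZS) t-test with Cauchy priors on standardized effect size, the Pearson
    correlation test under a stretched-beta prior, and ANOVA-type linear models
    (between, factorial, and repeated measures with a random participant
    factor) with per-term g-priors. Includes model enumeration under the
    principle of marginality, Bayesian model averaging with inclusion Bayes
    factors, Savage-Dickey posterior summaries, sequential evidence monitoring,
    prior-robustness curves, preregistered stopping-rule evaluation, discrete
    evidence categories, and proportion-wheel values, together with seeded
    synthetic-data generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    knitr,
    lattice,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
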