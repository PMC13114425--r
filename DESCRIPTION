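Package: uasrd
Title: The Unit Arcsine-Rayleigh Distribution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distribution functions, moments, entropy and reliability
    measures, and inference for the unit Arcsine-Rayleigh distribution
    (UASRD), a one-parameter model for proportions and other data on the
    open unit interval obtained by exponentiating a negated
    Arcsine-Rayleigh lifetime. Provides density, distribution, quantile
    and random generation functions; closed-form series and
    quadrature-based moments, mean residual life, mean inactivity time,
    order statistics, stress-strength reliability and a family of
    entropy measures; maximum likelihood and maximum product of spacings
    estimation with observed-information and delta-method intervals;
    Bayesian estimation via random-walk Metropolis-Hastings with highest
    posterior density intervals; goodness-of-fit statistics and
    information criteria; and a Monte Carlo harness for estimator
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, utils, pracma
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
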