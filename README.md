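# uasrd

Distribution theory and inference for the **unit Arcsine–Rayleigh
distribution (UASRD)**, a one-parameter model for data confined to the
open unit interval — proportions, normalised material strengths, scaled
computing times. Conventional distributions on the real line or the
positive half-line are inadequate for such data without transformation;
the UASRD is obtained by exponentiating a negated Arcsine–Rayleigh
lifetime, `Z = exp(-X)`, which yields closed forms for every principal
function while keeping a single interpretable shape parameter.

## The model

For `0 < z < 1` and shape `ζ > 0`:

    F(z; ζ) = 1 − (2/π) · arcsin √(1 − exp(−log²z / (2ζ²)))
    f(z; ζ) = (−log z) · exp(−log²z / (4ζ²)) /
              (π ζ² z √(1 − exp(−log²z / (2ζ²))))
    Q(q; ζ) = exp(−ζ √(−2 log sin²(πq/2)))

Small `ζ` concentrates mass near 1, large `ζ` near 0; the hazard can be
increasing, decreasing or bathtub-shaped. The package provides:

* `duasrd`, `puasrd`, `quasrd`, `ruasrd`, `suasrd`, `huasrd`,
  `uasrd_mode` — distribution functions with boundary-stable numerics;
* `uasrd_moment`, `uasrd_describe`, `uasrd_mgf`/`uasrd_cf`/`uasrd_cgf`,
  `uasrd_incomplete_moment` — moments by uniform-accuracy quadrature or
  by the exact binomial–erfc series with tail control;
* `uasrd_mrl`, `uasrd_mit`, `duasrd_order`/`puasrd_order`,
  `uasrd_lr_curve`/`uasrd_hr_curve`, `uasrd_stress_strength` —
  reliability measures, each with a series form cross-checked against
  its definitional integral;
* `uasrd_idelta`, `uasrd_entropy` — Shannon, Rényi, Arimoto, Tsallis,
  Havrda–Charvát and Mathai–Haubold entropies;
* `fit_uasrd` — maximum likelihood and maximum product of spacings,
  with observed-information standard errors, Wald intervals and
  delta-method inference for the survival and hazard functions
  (`predict`), plus `print`/`summary`/`coef`/`vcov`/`confint`/
  `logLik`/`simulate`/`residuals`/`plot` methods;
* `uasrd_bayes` — random-walk Metropolis–Hastings posteriors under
  gamma or Jeffreys priors, on a likelihood or product-of-spacings
  basis, with HPD intervals (`hpd_interval`) and squared-error-loss
  estimates (`sel_estimate`);
* `uasrd_gof` — information criteria and Anderson–Darling,
  Cramér–von Mises and Kolmogorov–Smirnov statistics;
* `uasrd_sim_cell` / `uasrd_sim_grid` — a seeded Monte Carlo harness
  (AE, RMSE, MRAB, interval length, coverage) over `(n, ζ, estimator)`
  grids;
* `uasrd_data`, `read_unit_sample`, `write_unit_sample`,
  `generate_fixture` — two packaged reference datasets and plain-text
  sample I/O.

## Worked example

Thirty tensile-strength measurements of polyester fibers (fractions of
the maximum sustainable stress) ship with the package:

```r
library(uasrd)
z   <- uasrd_data("tensile-strength")
fit <- fit_uasrd(z)                 # maximum likelihood
summary(fit)
```

```
Unit Arcsine-Rayleigh fit (maximum likelihood)
  n = 30
  zeta = 1.0179  (SE 0.1206)
  90% CI: [0.8196, 1.2162]
  95% CI: [0.7816, 1.2542]

Goodness of fit (zeta = 1.0179 )
  -2 logLik: -7.7408
  AIC -5.7408 | CAIC -5.5979 | BIC -4.3396 | HQIC -5.2925
  A* 0.1007 | W* 0.0141 | K-S 0.0680 (p = 0.9974)
```

The shape estimate `ζ̂ = 1.0179` puts the fitted density in its
right-skewed regime; the Kolmogorov–Smirnov p-value of 0.997 indicates
no detectable discrepancy between the empirical and fitted distribution
functions. Survival and hazard at a working stress of 0.25, with
delta-method intervals:

```r
predict(fit, z = 0.25, type = "reliability", se.fit = TRUE)
#>      z       fit         se lower_90  upper_90  lower_95  upper_95
#> 1 0.25 0.5669686 0.05657077 0.473918 0.6600192 0.4560919 0.6778453
```

so an item survives stress 0.25 with estimated probability 0.567
(SE 0.057). A Bayesian counterpart with a moment-matched gamma prior:

```r
post <- uasrd_bayes(z, basis = "likelihood", n_iter = 12000,
                    burn_in = 2000, seed = 1)
print(post)
#> Unit Arcsine-Rayleigh posterior (likelihood basis, gamma prior)
#>   10000 retained draws, acceptance rate 0.608
#>   zeta: mean 1.0306, sd 0.0851
```

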