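test_that("log-likelihood composes from the log-density", {
  expect_equal(uasrd_loglik(tensile, 1), sum(duasrd(tensile, 1, log = TRUE)),
               tolerance = 1e-12)
  expect_equal(uasrd_loglik(0.3, 0.8), duasrd(0.3, 0.8, log = TRUE))
  expect_error(uasrd_loglik(c(0.5, 1), 1), "strictly inside")
})

test_that("the analytic score matches numeric differentiation", {
  set.seed(3)
  for (i in 1:20) {
    x <- ruasrd(15, runif(1, 0.3, 3))
    zeta <- runif(1, 0.3, 3)
    h <- 1e-6 * zeta
    fd <- (uasrd_loglik(x, zeta + h) - uasrd_loglik(x, zeta - h)) / (2 * h)
    expect_equal(uasrd_score(x, zeta), fd, tolerance = 1e-6)
  }
  # stationarity at the optimum
  fit <- fit_uasrd(tensile)
  expect_lt(abs(uasrd_score(tensile, fit$zeta)), 1e-4 * length(tensile))
})

test_that("spacings telescope to one and handle small-sample cases", {
  s <- sort(tensile)
  D <- diff(c(0, puasrd(s, 1), 1))
  expect_equal(sum(D), 1, tolerance = 1e-12)
  # n = 2 hand-computable case
  x2 <- c(0.3, 0.6)
  by_hand <- (log(puasrd(0.3, 1)) + log(puasrd(0.6, 1) - puasrd(0.3, 1)) +
                log(1 - puasrd(0.6, 1))) / 3
  expect_equal(uasrd_logps(x2, 1), by_hand, tolerance = 1e-12)
  expect_warning(uasrd_logps(c(0.4, 0.4, 0.7), 1), "tied")
})

test_that("classical fits reproduce the reference analyses of both datasets", {
  f1 <- fit_uasrd(tensile)
  expect_true(f1$converged)
  expect_equal(round(f1$zeta, 4), 1.0179)
  expect_equal(round(f1$se, 4), 0.1206)
  expect_equal(round(-2 * f1$loglik, 4), -7.7408)
  m1 <- fit_uasrd(tensile, "mps")
  expect_equal(round(m1$zeta, 4), 1.0709)
  expect_equal(round(m1$se, 4), 0.1291)
  f2 <- fit_uasrd(p3times)
  expect_equal(round(f2$zeta, 4), 1.4644)
  expect_equal(round(f2$se, 4), 0.2056)
  expect_equal(round(-2 * f2$loglik, 4), -15.3328)
  m2 <- fit_uasrd(p3times, "mps")
  expect_equal(round(m2$zeta, 4), 1.5473)
  expect_equal(round(m2$se, 4), 0.2220)
  # spacings estimates exceed the likelihood ones on both datasets
  expect_gt(m1$zeta, f1$zeta)
  expect_gt(m2$zeta, f2$zeta)
})

test_that("both objectives are unimodal in zeta on the datasets", {
  zg <- exp(seq(log(0.2), log(10), length.out = 200))
  for (x in list(tensile, p3times)) {
    for (obj in list(function(z) uasrd_loglik(x, z),
                     function(z) uasrd_logps(x, z))) {
      v <- vapply(zg, obj, 0)
      d <- sign(diff(v))
      expect_equal(sum(diff(d[d != 0]) != 0), 1)  # single rise-fall switch
    }
  }
})

test_that("observed information behaves on a known quadratic", {
  expect_equal(observed_information(function(z) -(z - 2)^2, 2), 2,
               tolerance = 1e-5)
  expect_error(observed_information(function(z) (z - 2)^2, 2),
               "not a maximum")
  # differencing the analytic score agrees with differencing the objective
  fit <- fit_uasrd(tensile)
  h <- 1e-5 * fit$zeta
  I_score <- -(uasrd_score(tensile, fit$zeta + h) -
                 uasrd_score(tensile, fit$zeta - h)) / (2 * h)
  expect_equal(I_score, fit$info, tolerance = 1e-4)
})

test_that("confidence intervals nest and simulate/residual methods work", {
  fit <- fit_uasrd(tensile)
  expect_gt(fit$ci["90%", "lower"], fit$ci["95%", "lower"])
  expect_lt(fit$ci["90%", "upper"], fit$ci["95%", "upper"])
  set.seed(1)
  sims <- simulate(fit, nsim = 2)
  expect_length(sims, 2)
  expect_true(all(unlist(sims) > 0 & unlist(sims) < 1))
  r <- residuals(fit)
  expect_length(r, 30)
  expect_lt(abs(mean(r)), 0.5)
})

test_that("delta-method predictions reproduce the reference table and collapse", {
  f1 <- fit_uasrd(tensile)
  pr <- predict(f1, 0.25, type = "reliability", se.fit = TRUE)
  ph <- predict(f1, 0.25, type = "hazard", se.fit = TRUE)
  expect_equal(round(pr$fit, 4), 0.5670)
  expect_equal(round(pr$se, 4), 0.0566)
  expect_equal(round(ph$fit, 4), 2.4308)
  expect_equal(round(ph$se, 4), 0.1085)
  # invariance: the plug-in equals the distribution function at zeta-hat
  expect_identical(pr$fit, suasrd(0.25, f1$zeta))
  # zero estimator variance collapses the interval to the point
  f0 <- f1; f0$se <- 0
  pr0 <- predict(f0, 0.25, type = "reliability", se.fit = TRUE)
  expect_equal(pr0$lower_95, pr0$fit)
  expect_equal(pr0$upper_95, pr0$fit)
})

test_that("estimators are consistent on synthetic data", {
  set.seed(99)
  x <- ruasrd(5000, 2.25)
  fit <- fit_uasrd(x)
  expect_lt(abs(fit$zeta - 2.25), 3 * fit$se)
  fitm <- fit_uasrd(x, "mps")
  expect_lt(abs(fitm$zeta - 2.25), 4 * fitm$se)
})
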