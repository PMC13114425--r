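test_that("gamma prior elicitation matches the moment algebra", {
  pr <- elicit_gamma_prior(2, 1)
  expect_equal(pr$a1, 4)
  expect_equal(pr$b1, 2)
  # round trip: the spec's mean and variance are recovered
  expect_equal(pr$a1 / pr$b1, 2)
  expect_equal(pr$a1 / pr$b1^2, 1)
  expect_error(elicit_gamma_prior(-1, 1), "positive")
  pr1 <- elicit_gamma_prior(1.0179, 0.1206^2)
  expect_equal(pr1$a1 / pr1$b1, 1.0179)
})

test_that("posterior kernels compose prior and data terms exactly", {
  pr <- uasrd_prior("gamma", a1 = 3, b1 = 2)
  z <- 1.3
  expect_equal(uasrd_log_posterior(tensile, z, pr, "likelihood"),
               3 * log(z) - 2 * z + uasrd_loglik(tensile, z),
               tolerance = 1e-12)
  expect_equal(uasrd_log_posterior(tensile, z, pr, "spacings"),
               2 * log(z) - 2 * z + 31 * uasrd_logps(tensile, z),
               tolerance = 1e-12)
  jef <- uasrd_prior("jeffreys")
  expect_equal(uasrd_log_posterior(p3times, z, jef, "likelihood"),
               -log(z) + uasrd_loglik(p3times, z), tolerance = 1e-12)
  # with no data the kernel is the prior alone
  expect_equal(uasrd_log_posterior(numeric(0), z, pr, "likelihood"),
               3 * log(z) - 2 * z)
  expect_identical(uasrd_log_posterior(tensile, -1, pr, "likelihood"), -Inf)
})

test_that("posterior kernels are integrable for both bases and priors", {
  zg <- seq(0.05, 20, length.out = 800)
  for (x in list(tensile, p3times)) {
    fits <- fit_uasrd(x)
    priors <- list(elicit_gamma_prior(fits$zeta, fits$se^2),
                   uasrd_prior("jeffreys"))
    for (pr in priors) for (basis in c("likelihood", "spacings")) {
      lp <- vapply(zg, function(z) uasrd_log_posterior(x, z, pr, basis), 0)
      w <- exp(lp - max(lp))
      expect_true(all(is.finite(w)))
      # mass concentrated well inside the grid (finite normalisation)
      expect_lt(w[1], 1e-6)
      expect_lt(w[length(w)], 1e-6)
    }
  }
})

test_that("the sampler is reproducible under a fixed seed", {
  b1 <- uasrd_bayes(p3times, n_iter = 800, burn_in = 100, seed = 42)
  b2 <- uasrd_bayes(p3times, n_iter = 800, burn_in = 100, seed = 42)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$acceptance_rate, b2$acceptance_rate)
  expect_true(all(b1$draws > 0))
  expect_true(b1$acceptance_rate > 0 && b1$acceptance_rate < 1)
  expect_length(b1$draws, 700)
  expect_length(b1$reliability, 700)
  expect_length(b1$hazard, 700)
})

test_that("prior-only sampling recovers the gamma prior", {
  pr <- uasrd_prior("gamma", a1 = 9, b1 = 3)  # mean 3, sd 1
  # the spacings-basis kernel is the standard Gamma(a1, b1) shape;
  # the likelihood-basis kernel carries one extra power of zeta and so
  # targets Gamma(a1 + 1, b1) when there are no data
  b <- uasrd_bayes(numeric(0), basis = "spacings", prior = pr,
                   proposal_sd = 1, start = 3,
                   n_iter = 6000, burn_in = 1000, seed = 8)
  mcse <- sd(b$draws) / sqrt(length(b$draws) / 10)  # crude ESS deflation
  expect_lt(abs(mean(b$draws) - 3), 3 * mcse + 0.1)
  b2 <- uasrd_bayes(numeric(0), basis = "likelihood", prior = pr,
                    proposal_sd = 1, start = 3,
                    n_iter = 6000, burn_in = 1000, seed = 9)
  expect_lt(abs(mean(b2$draws) - 10 / 3), 3 * mcse + 0.1)
})

test_that("sel estimates are posterior means of the requested traces", {
  b <- uasrd_bayes(p3times, n_iter = 600, burn_in = 100, seed = 2)
  expect_equal(sel_estimate(b, "zeta"), mean(b$draws), tolerance = 1e-15)
  expect_equal(sel_estimate(b, "reliability"), mean(b$reliability),
               tolerance = 1e-15)
  expect_equal(sel_estimate(b, "hazard"), mean(b$hazard), tolerance = 1e-15)
})

test_that("hpd matches an exhaustive window search and known shapes", {
  set.seed(31)
  draws <- rnorm(1000, 5, 2)
  got <- hpd_interval(draws, 0.9)
  s <- sort(draws)
  m <- floor(0.9 * 1000)
  widths <- s[(m + 1):1000] - s[1:(1000 - m)]
  k <- which.min(widths)
  expect_identical(got, c(lower = s[k], upper = s[k + m]))
  # near-symmetric target: HPD close to the central quantile interval
  qi <- quantile(draws, c(0.05, 0.95), names = FALSE)
  expect_lt(abs(got["lower"] - qi[1]), 0.5)
  expect_lt(abs(got["upper"] - qi[2]), 0.5)
  # uniform grid: all windows tie; first (smallest lower endpoint) wins
  u <- seq(0, 1, length.out = 101)
  gu <- hpd_interval(u, 0.9)
  expect_equal(unname(gu), c(0, 0.9))
  expect_error(hpd_interval(u, 1.2), "inside")
})

test_that("chains pass a split-half stationarity smoke test", {
  b <- uasrd_bayes(tensile, n_iter = 6000, burn_in = 1000, seed = 5)
  half <- length(b$draws) %/% 2
  m1 <- mean(b$draws[1:half]); m2 <- mean(b$draws[(half + 1):(2 * half)])
  # batch-means MCSE over 20 batches
  bm <- tapply(b$draws, rep(1:20, each = length(b$draws) %/% 20)[
    seq_along(b$draws)], mean)
  mcse <- sd(bm) / sqrt(20)
  expect_lt(abs(m1 - m2), 6 * mcse)
})

test_that("informative priors tighten the credible intervals", {
  b_inf <- uasrd_bayes(tensile, n_iter = 4000, burn_in = 500, seed = 6)
  b_jef <- uasrd_bayes(tensile, prior = uasrd_prior("jeffreys"),
                       n_iter = 4000, burn_in = 500, seed = 6)
  w_inf <- diff(hpd_interval(b_inf$draws, 0.95))
  w_jef <- diff(hpd_interval(b_jef$draws, 0.95))
  expect_lt(w_inf, w_jef)
  # Wald interval from the classical fit is wider than the informative HPD
  fit <- fit_uasrd(tensile)
  expect_lt(w_inf, diff(fit$ci["95%", ]))
})
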