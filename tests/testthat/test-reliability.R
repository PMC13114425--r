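test_that("mean residual life stays in range and matches its oracle", {
  for (zeta in c(0.5, 1, 2)) for (z in c(0.1, 0.3, 0.7)) {
    mrl <- uasrd_mrl(z, zeta)
    expect_true(mrl > 0 && mrl < 1 - z)
    oracle <- integrate(function(t) suasrd(t, zeta), z, 1,
                        rel.tol = 1e-12)$value / suasrd(z, zeta)
    expect_equal(mrl, oracle, tolerance = 1e-8)
    expect_equal(uasrd_mrl(z, zeta, method = "series"), oracle,
                 tolerance = 1e-6)
  }
  # z -> 0 limit is the mean
  expect_equal(uasrd_mrl(1e-9, 0.95), uasrd_moment(0.95), tolerance = 1e-4)
})

test_that("mean inactivity time stays in range and matches its oracle", {
  for (zeta in c(0.95, 2)) for (z in c(0.2, 0.5, 0.9)) {
    mit <- uasrd_mit(z, zeta)
    expect_true(mit > 0 && mit < z)
    oracle <- integrate(function(t) puasrd(t, zeta), 0, z,
                        rel.tol = 1e-12)$value / puasrd(z, zeta)
    expect_equal(mit, oracle, tolerance = 1e-8)
    expect_equal(uasrd_mit(z, zeta, method = "series"), oracle,
                 tolerance = 1e-6)
  }
  # z -> 1 limit is 1 - mean
  expect_equal(uasrd_mit(1 - 1e-9, 0.95), 1 - uasrd_moment(0.95),
               tolerance = 1e-4)
})

test_that("mrl and mit jointly recover the mean (total expectation)", {
  for (zeta in c(0.5, 0.95, 2)) for (z in c(0.2, 0.5, 0.8)) {
    mu <- puasrd(z, zeta) * (z - uasrd_mit(z, zeta)) +
      suasrd(z, zeta) * (z + uasrd_mrl(z, zeta))
    expect_equal(mu, uasrd_moment(zeta), tolerance = 1e-8)
  }
})

test_that("order-statistic density is a density and nests the parent", {
  z <- c(0.1, 0.5, 0.9)
  expect_equal(duasrd_order(z, 1, 1, 0.95), duasrd(z, 0.95))
  mass <- integrate(duasrd_order, 0, 1, r = 2, n = 5, zeta = 1,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  expect_error(duasrd_order(0.5, 6, 5, 1), "1..n")
})

test_that("order-statistic cdf identities and double-sum equivalence", {
  z <- c(0.2, 0.4, 0.7)
  Fv <- puasrd(z, 1)
  expect_equal(puasrd_order(z, 1, 6, 1), 1 - (1 - Fv)^6, tolerance = 1e-12)
  expect_equal(puasrd_order(z, 6, 6, 1), Fv^6, tolerance = 1e-12)
  for (n in c(5, 7, 10)) for (r in c(1, (n + 1) %/% 2, n)) {
    expect_equal(puasrd_order(0.4, r, n, 1, method = "double-sum"),
                 puasrd_order(0.4, r, n, 1), tolerance = 1e-12)
  }
  # cdf is the integral of the density
  ref <- integrate(duasrd_order, 0, 0.4, r = 3, n = 7, zeta = 1,
                   rel.tol = 1e-10)$value
  expect_equal(puasrd_order(0.4, 3, 7, 1), ref, tolerance = 1e-8)
})

test_that("simulated order statistics follow the order-statistic law", {
  set.seed(5)
  reps <- 2e4
  x <- matrix(ruasrd(5 * reps, 1), reps, 5)
  second <- apply(x, 1, function(r) sort(r)[2])
  ks <- suppressWarnings(ks.test(second, function(q) puasrd_order(q, 2, 5, 1)))
  expect_gt(ks$p.value, 0.001)
})

test_that("likelihood-ratio curves are ordered in the shape parameter", {
  zg <- seq(0.001, 0.999, length.out = 1000)
  expect_equal(uasrd_lr_curve(zg, 1.3, 1.3), rep(1, 1000))
  # with zeta1 < zeta2 the ratio is monotone in the lifetime scale
  # x = -log z (decreasing in x), i.e. non-decreasing in z: the smaller
  # shape puts its mass toward 1
  r1 <- uasrd_lr_curve(zg, 0.5, 1.5)
  expect_true(all(diff(r1) >= -1e-12))
  expect_equal(r1[1], 0, tolerance = 1e-10)
  expect_equal(r1, duasrd(zg, 0.5) / duasrd(zg, 1.5), tolerance = 1e-10)
})

test_that("hazard-ratio curves match their definition (diagnostic only)", {
  zg <- seq(0.05, 0.95, length.out = 200)
  expect_equal(uasrd_hr_curve(zg, 2, 2), rep(1, 200))
  expect_equal(uasrd_hr_curve(zg, 0.5, 1.5),
               huasrd(zg, 0.5) / huasrd(zg, 1.5), tolerance = 1e-10)
})

test_that("stress-strength reliability obeys symmetry and limits", {
  expect_identical(uasrd_stress_strength(1.3, 1.3), 0.5)
  expect_equal(uasrd_stress_strength(1.5, 1) + uasrd_stress_strength(1, 1.5),
               1, tolerance = 1e-10)
  # integral path equals the definitional double quadrature
  def <- integrate(function(z) duasrd(z, 1.5) * puasrd(z, 1.0), 0, 1,
                   rel.tol = 1e-11)$value
  expect_equal(uasrd_stress_strength(1.5, 1.0), def, tolerance = 1e-8)
  # series cross-check
  for (p in list(c(1.5, 1), c(0.5, 2), c(3, 1))) {
    expect_equal(uasrd_stress_strength(p[1], p[2], method = "series"),
                 uasrd_stress_strength(p[1], p[2]), tolerance = 1e-7)
  }
  # a larger shape concentrates mass toward 0, so reliability is
  # monotone decreasing in alpha = (zeta1/zeta2)^2, from 1 to 0
  alphas <- c(0.01, 0.1, 1, 10, 100)
  rss <- vapply(alphas, function(a) uasrd_stress_strength(sqrt(a), 1), 0)
  expect_true(all(diff(rss) < 0))
  expect_gt(rss[1], 0.9)
  expect_lt(rss[5], 0.1)
  expect_true(all(rss > 0 & rss < 1))
})
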