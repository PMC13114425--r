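test_that("density integrates to one across the shape range", {
  for (zeta in c(0.03, 0.25, 0.95, 2.25, 14, 31)) {
    mass <- integrate(function(u) {
      # integrate in the -log z scale to tame the lower-tail spike
      duasrd(pmax(exp(-u), 1e-300), zeta) * exp(-u)
    }, 0, Inf, rel.tol = 1e-12)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
})

test_that("cdf and quantile are inverse to each other", {
  q <- seq(0.1, 0.9, by = 0.1)
  for (zeta in c(0.25, 1, 5)) {
    z <- quasrd(q, zeta)
    expect_true(all(diff(z) > 0))
    expect_equal(puasrd(z, zeta), q, tolerance = 1e-10)
    zz <- c(0.05, 0.3, 0.8)
    expect_equal(quasrd(puasrd(zz, zeta), zeta), zz, tolerance = 1e-10)
  }
})

test_that("density is the derivative of the cdf", {
  h <- 1e-6
  for (zeta in c(0.5, 1, 3)) for (z in c(0.1, 0.4, 0.85)) {
    fd <- (puasrd(z + h, zeta) - puasrd(z - h, zeta)) / (2 * h)
    expect_equal(fd, duasrd(z, zeta), tolerance = 1e-6)
  }
})

test_that("density attains its analytic limit at the upper boundary", {
  expect_equal(duasrd(1 - 1e-12, 1), sqrt(2) / pi, tolerance = 1e-6)
  expect_equal(duasrd(1 - 1e-12, 0.3), sqrt(2) / (pi * 0.3), tolerance = 1e-6)
  # boundary.ok path returns the exact limit
  expect_equal(duasrd(1, 2, boundary.ok = TRUE), sqrt(2) / (pi * 2))
})

test_that("support boundaries are rejected unless explicitly allowed", {
  expect_error(duasrd(0, 1), "strictly inside")
  expect_error(puasrd(1, 1), "strictly inside")
  expect_error(quasrd(c(0.2, 1.2), 1), "strictly inside")
  expect_identical(puasrd(c(0, 0.5, 1), 1, boundary.ok = TRUE)[c(1, 3)],
                   c(0, 1))
})

test_that("hazard equals density over survival and basic shapes hold", {
  set.seed(42)
  z <- runif(100, 0.01, 0.99)
  zetas <- runif(100, 0.1, 5)
  for (i in seq_along(z)) {
    expect_equal(huasrd(z[i], zetas[i]),
                 duasrd(z[i], zetas[i]) / suasrd(z[i], zetas[i]),
                 tolerance = 1e-12)
  }
  zg <- seq(0.01, 0.99, length.out = 200)
  for (zeta in c(0.3, 1, 4)) {
    expect_true(all(diff(puasrd(zg, zeta)) > 0))
    expect_true(all(duasrd(zg, zeta) >= 0))
    expect_true(all(huasrd(zg, zeta) > 0))
    # each tail formula is exact in its own tail; complementarity holds
    # to within a few ulps of the saturated tail
    expect_equal(suasrd(zg, zeta) + puasrd(zg, zeta), rep(1, 200),
                 tolerance = 1e-13)
  }
})

test_that("distinct shapes give distinct distributions (identifiability)", {
  zg <- seq(0.05, 0.95, length.out = 50)
  pairs <- list(c(0.5, 0.6), c(1, 1.01), c(2, 5))
  for (p in pairs) {
    gap <- max(abs(puasrd(zg, p[1]) - puasrd(zg, p[2])))
    expect_gt(gap, 1e-4)
  }
})

test_that("published quartiles are reproduced by the quantile function", {
  # moderate rows at the printed 4 decimals
  expect_equal(round(quasrd(c(0.25, 0.5, 0.75), 0.95), 4),
               c(0.1553, 0.3268, 0.5859))
  expect_equal(round(quasrd(c(0.25, 0.5, 0.75), 0.42), 4),
               c(0.4390, 0.6099, 0.7895))
  # extreme row at the printed 2 significant digits
  expect_equal(quasrd(0.25, 31), 4.1e-27, tolerance = 0.05)
})

test_that("inverse-transform sampler is deterministic and consistent", {
  set.seed(7); a <- ruasrd(100, 0.95)
  set.seed(7); b <- ruasrd(100, 0.95)
  expect_identical(a, b)
  expect_true(all(a > 0 & a < 1))
  set.seed(11)
  x <- ruasrd(1e5, 0.95)
  ks <- suppressWarnings(ks.test(x, function(q) puasrd(q, 0.95)))
  expect_gt(ks$p.value, 0.01)
  mu <- uasrd_moment(0.95)
  s <- sqrt(uasrd_moment(0.95, 2, central = TRUE))
  expect_lt(abs(mean(x) - mu), 3 * s / sqrt(1e5))
})

test_that("the mode solves the stationarity condition and maximises the density", {
  for (zeta in c(0.3, 0.95, 2)) {
    m <- uasrd_mode(zeta)
    expect_true(m$interior)
    expect_lt(abs(m$objective), 1e-8)
    # local maximum
    eps <- 1e-4 * m$mode
    expect_gte(duasrd(m$mode, zeta), duasrd(m$mode - eps, zeta))
    expect_gte(duasrd(m$mode, zeta), duasrd(m$mode + eps, zeta))
    # global argmax on a fine grid (grid resolution tolerance)
    zs <- exp(seq(log(1e-12), log(1 - 1e-9), length.out = 2e5))
    gm <- zs[which.max(duasrd(zs, zeta))]
    expect_equal(log(gm), log(m$mode), tolerance = 1e-3)
  }
})
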