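# Internal numeric kernels shared across the package.

# Error function and complements in terms of pnorm (machine-accurate).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Scaled complementary error function exp(x^2) * erfc(x).
# pracma::erfcx underflows to NaN for x > ~26 (it goes through erfc);
# beyond that the Laplace asymptotic series is accurate to ~1e-16.
erfcx <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 25
  if (any(lo)) out[lo] <- pracma::erfcx(x[lo])
  if (any(!lo)) {
    xx <- x[!lo]
    s <- 1 / (2 * xx^2)
    out[!lo] <- (1 - s * (1 - 3 * s * (1 - 5 * s * (1 - 7 * s * (1 - 9 * s))))) /
      (xx * sqrt(pi))
  }
  out
}

# Kummer confluent hypergeometric function 1F1(a; b; x) by its power
# series.  The series converges for all x; adequate in double precision
# for the moderate nonnegative arguments arising here (x = (d-1)^2
# zeta^2 / (2k+d)).  Scalar in (a, b), vectorised in x.
kummer_1f1 <- function(a, b, x, tol = 1e-15, max_terms = 10000L) {
  s <- rep(1, length(x))
  term <- rep(1, length(x))
  for (n in 0:(max_terms - 1L)) {
    term <- term * (a + n) / (b + n) * x / (n + 1)
    s <- s + term
    if (all(abs(term) <= tol * abs(s))) break
  }
  s
}

stopifnot_scalar_shape <- function(zeta) {
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) || zeta <= 0)
    stop("'zeta' must be a single positive finite number", call. = FALSE)
  invisible(zeta)
}

check_unit_interior <- function(x, name = "z") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  bad <- which(x <= 0 | x >= 1)
  if (length(bad))
    stop(sprintf("'%s' must lie strictly inside (0, 1); offending positions: %s",
                 name, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}
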