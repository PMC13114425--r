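# Moments and descriptive measures.
#
# Expectations are computed by default through the standardised
# integral representation
#   E[g(Z)] = int_0^inf g(exp(-zeta * u)) phi(u) du,
#   phi(u)  = u exp(-u^2/4) / (pi sqrt(1 - exp(-u^2/2))),
# obtained by substituting u = -log(z)/zeta.  phi is a fixed, smooth,
# Gaussian-tailed kernel independent of zeta, so adaptive quadrature is
# uniformly accurate across the whole parameter range (the density
# itself develops an enormous integrable spike near 0 for large zeta,
# which defeats naive quadrature in z).

.uasrd_phi <- function(u) {
  w <- u^2 / 2
  ifelse(w > 0, u * exp(-u^2 / 4) / (pi * sqrt(-expm1(-w))), sqrt(2) / pi)
}

.uasrd_expect <- function(g, zeta, rel_tol = 1e-11) {
  # clamp away from exact 0 so integrands defined on the open interval
  # can be evaluated in the far (negligible-mass) tail
  stats::integrate(function(u) g(pmax(exp(-zeta * u), 1e-300)) * .uasrd_phi(u),
                   0, Inf, rel.tol = rel_tol, abs.tol = rel_tol)$value
}

# Series term of the m-th raw moment: central binomial weight times
#   2/(pi(2k+1)) - 2 m zeta erfcx(m zeta / sqrt(2k+1)) / (sqrt(pi) (2k+1)^{3/2}),
# with the scaled complement erfcx absorbing exp(m^2 zeta^2/(2k+1)),
# which would overflow on its own for large m * zeta.
.raw_moment_term <- function(m, zeta) {
  function(k) {
    central_binomial_weight(k) *
      (2 / (pi * (2 * k + 1)) -
         2 * m * zeta / (sqrt(pi) * (2 * k + 1)^1.5) *
           erfcx(m * zeta / sqrt(2 * k + 1)))
  }
}

#' Moments of the unit Arcsine-Rayleigh distribution
#'
#' Raw moments \eqn{E[Z^m]} (any real order \eqn{m > -1}) and central
#' moments \eqn{E[(Z-\mu)^m]} (integer \eqn{m \ge 1}).  Two evaluation
#' paths are provided: adaptive quadrature of the standardised integral
#' representation (the default, uniformly accurate in \eqn{\zeta}), and
#' the exact binomial--erfc series
#' \deqn{E[Z^m] = \sum_{k\ge 0} \frac{\binom{2k}{k}}{4^k}\left[
#'   \frac{2}{\pi(2k+1)} - \frac{2m\zeta}{\sqrt{\pi}(2k+1)^{3/2}}
#'   e^{m^2\zeta^2/(2k+1)}\,\mathrm{erfc}\!\Big(\frac{m\zeta}
#'   {\sqrt{2k+1}}\Big)\right],}
#' whose terms decay like \eqn{k^{-3/2}}; see [series_control()] for how
#' the tail is handled.  The series path requires \eqn{m \ge 0} (for
#' \eqn{-1 < m < 0} the quadrature path is authoritative).
#'
#' @param zeta positive shape parameter.
#' @param order moment order.
#' @param central compute the central moment (integer order).
#' @param method `"quadrature"` or `"series"`.
#' @param control a [series_control()] for the series path.
#' @return The moment value.
#' @examples
#' uasrd_moment(0.95)                      # mean
#' uasrd_moment(0.95, 2, central = TRUE)   # variance
#' @export
uasrd_moment <- function(zeta, order = 1, central = FALSE,
                         method = c("quadrature", "series"),
                         control = series_control()) {
  stopifnot_scalar_shape(zeta)
  method <- match.arg(method)
  if (central) {
    if (order < 1 || order != round(order))
      stop("central moments require integer 'order' >= 1")
    if (order == 1) return(0)
    mu <- uasrd_moment(zeta, 1, method = method, control = control)
    if (method == "quadrature")
      return(.uasrd_expect(function(z) (z - mu)^order, zeta))
    # binomial expansion over raw moments
    j <- 0:order
    raw <- vapply(j, function(jj)
      if (jj == 0) 1 else uasrd_moment(zeta, jj, method = "series",
                                       control = control), 0)
    return(sum(choose(order, j) * (-mu)^(order - j) * raw))
  }
  if (order <= -1) stop("'order' must exceed -1 (integrability)")
  if (order == 0) return(1)
  if (method == "quadrature")
    return(.uasrd_expect(function(z) z^order, zeta))
  if (order < 0)
    stop("the series representation requires 'order' >= 0; use method = \"quadrature\"")
  sum_binomial_series(.raw_moment_term(order, zeta), control)$value
}

#' Descriptive measures of the unit Arcsine-Rayleigh distribution
#'
#' Quartiles (from the closed-form quantile function), mean, variance,
#' skewness \eqn{\gamma_1 = \mu_3/\mu_2^{3/2}}, excess kurtosis
#' \eqn{\gamma_2 = \mu_4/\mu_2^2 - 3}, coefficient of variation
#' \eqn{\sigma/\mu} and coefficient of dispersion \eqn{\sigma^2/\mu},
#' for one or more shape values.
#'
#' With `method = "series"` the moments come from the partial sums of
#' the binomial--erfc series under `control`; with the default
#' `tail = "none"` removed (i.e. `series_control()` defaults) the two
#' methods agree to near machine accuracy.  A literal truncated partial
#' sum (`series_control(k_max = ..., tail = "none")`) is retained
#' because published tabulations of these measures are tied to a fixed
#' truncation point; see the package vignette.
#'
#' @param zeta vector of positive shape parameters.
#' @param method `"quadrature"` or `"series"` (moment path).
#' @param control a [series_control()] for the series path.
#' @return A `data.frame` with one row per `zeta` and columns `zeta`,
#'   `q1`, `q2`, `q3`, `mean`, `variance`, `skewness`, `kurtosis_excess`,
#'   `cv`, `cd`.
#' @examples
#' uasrd_describe(c(0.42, 0.95))
#' @export
uasrd_describe <- function(zeta, method = c("quadrature", "series"),
                           control = series_control()) {
  method <- match.arg(method)
  one <- function(zz) {
    raw <- vapply(1:4, function(m) uasrd_moment(zz, m, method = method,
                                                control = control), 0)
    mu <- raw[1L]
    v <- raw[2L] - mu^2
    if (method == "quadrature") {
      # direct central quadrature avoids cancellation among raw moments
      m3 <- .uasrd_expect(function(z) (z - mu)^3, zz)
      m4 <- .uasrd_expect(function(z) (z - mu)^4, zz)
    } else {
      m3 <- raw[3L] - 3 * mu * raw[2L] + 2 * mu^3
      m4 <- raw[4L] - 4 * mu * raw[3L] + 6 * mu^2 * raw[2L] - 3 * mu^4
    }
    c(q = quasrd(c(0.25, 0.5, 0.75), zz), mean = mu, variance = v,
      skewness = m3 / v^1.5, kurtosis_excess = m4 / v^2 - 3,
      cv = sqrt(v) / mu, cd = v / mu)
  }
  out <- t(vapply(zeta, one, numeric(9L)))
  data.frame(zeta = zeta, q1 = out[, 1L], q2 = out[, 2L], q3 = out[, 3L],
             mean = out[, 4L], variance = out[, 5L], skewness = out[, 6L],
             kurtosis_excess = out[, 7L], cv = out[, 8L], cd = out[, 9L])
}

#' Generating functions of the unit Arcsine-Rayleigh distribution
#'
#' Finite truncations of the moment generating function
#' \eqn{M(t) = \sum_m t^m \mu'_m / m!}, the characteristic function
#' \eqn{\varphi(t)} and the cumulant generating function
#' \eqn{K(t) = \log M(t)}.  Because \eqn{Z \in (0,1)}, truncating the
#' outer sum after order \eqn{M} leaves an error of at most
#' \eqn{\sum_{m > M} |t|^m/m!}, which is returned alongside the value.
#'
#' @param zeta positive shape parameter.
#' @param t evaluation point (scalar).
#' @param order truncation order of the outer series.
#' @param method moment path passed to [uasrd_moment()].
#' @param control series control for the moment path.
#' @return A list with `value` (complex for `uasrd_cf`) and
#'   `truncation_bound`.
#' @examples
#' uasrd_mgf(0.95, t = 1)$value
#' @export
uasrd_mgf <- function(zeta, t, order = 30L,
                      method = c("quadrature", "series"),
                      control = series_control()) {
  stopifnot_scalar_shape(zeta)
  method <- match.arg(method)
  m <- 0:order
  mom <- c(1, vapply(seq_len(order), function(mm)
    uasrd_moment(zeta, mm, method = method, control = control), 0))
  value <- sum(t^m / factorial(m) * mom)
  bound <- exp(abs(t)) - sum(abs(t)^m / factorial(m))
  list(value = value, truncation_bound = max(bound, 0))
}

#' @rdname uasrd_mgf
#' @export
uasrd_cf <- function(zeta, t, order = 30L,
                     method = c("quadrature", "series"),
                     control = series_control()) {
  stopifnot_scalar_shape(zeta)
  method <- match.arg(method)
  m <- 0:order
  mom <- c(1, vapply(seq_len(order), function(mm)
    uasrd_moment(zeta, mm, method = method, control = control), 0))
  value <- sum(complex(real = 0, imaginary = t)^m / factorial(m) * mom)
  bound <- exp(abs(t)) - sum(abs(t)^m / factorial(m))
  list(value = value, truncation_bound = max(bound, 0))
}

#' @rdname uasrd_mgf
#' @export
uasrd_cgf <- function(zeta, t, order = 30L,
                      method = c("quadrature", "series"),
                      control = series_control()) {
  mg <- uasrd_mgf(zeta, t, order = order, method = method, control = control)
  if (mg$value <= 0) stop("truncated MGF is non-positive; increase 'order'")
  list(value = base::log(mg$value),
       truncation_bound = mg$truncation_bound / mg$value)
}

#' Incomplete moments
#'
#' The lower incomplete moment \eqn{\psi_m(z) = E[Z^m 1\{Z \le z\}]} for
#' real \eqn{m > -1}.  The default path integrates
#' \eqn{\int_0^z t^m f(t)\,dt} in the \eqn{-\log} scale; the series path
#' evaluates the exact expansion whose \eqn{k}-th term is
#' \eqn{w_k\,[2 z^m e^{-(2k+1)\log^2 z/(4\zeta^2)}/(\pi(2k+1)) -
#'   2m\zeta\,e^{m^2\zeta^2/(2k+1)}\mathrm{erfc}(\cdot)/
#'   (\sqrt{\pi}(2k+1)^{3/2})]}
#' (erfc arguments as in the raw-moment series, shifted by the
#' truncation point; evaluated via the scaled complement so no
#' overflow/underflow occurs).  \eqn{\psi_0(z)} is the distribution
#' function and \eqn{\psi_m(z) \to E[Z^m]} as \eqn{z \to 1^-}.
#'
#' @param zeta positive shape.
#' @param order real moment order \eqn{> -1} (series path: \eqn{\ge 0}).
#' @param z upper limit in (0, 1).
#' @param method `"quadrature"` or `"series"`.
#' @param control series control.
#' @return The incomplete moment value.
#' @examples
#' uasrd_incomplete_moment(1, order = 0, z = 0.3)  # = puasrd(0.3, 1)
#' @export
uasrd_incomplete_moment <- function(zeta, order, z,
                                    method = c("quadrature", "series"),
                                    control = series_control()) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(z, "z")
  if (order <= -1) stop("'order' must exceed -1")
  method <- match.arg(method)
  if (method == "quadrature") {
    A <- -base::log(z) / zeta
    return(stats::integrate(function(u) exp(-order * zeta * u) * .uasrd_phi(u),
                            A, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value)
  }
  if (order < 0)
    stop("the series representation requires 'order' >= 0")
  m <- order
  A <- -base::log(z)
  term <- function(k) {
    beta <- (2 * k + 1) / (4 * zeta^2)
    core <- exp(-beta * A^2 - m * A)      # z^m e^{-(2k+1) log^2 z/(4 zeta^2)}
    x <- sqrt(beta) * A + m / (2 * sqrt(beta))
    central_binomial_weight(k) * core *
      (2 / (pi * (2 * k + 1)) -
         2 * m * zeta / (sqrt(pi) * (2 * k + 1)^1.5) * erfcx(x))
  }
  sum_binomial_series(term, control)$value
}
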