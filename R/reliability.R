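# Reliability-theoretic measures: mean residual life, mean inactivity
# time, order statistics, stochastic-ordering diagnostics and
# stress-strength reliability.

#' Mean residual life and mean inactivity time
#'
#' For \eqn{Z} on the unit interval, the mean residual life is
#' \eqn{\hat m_r(z) = E[Z - z \mid Z > z] = \int_z^1 R(t)\,dt / R(z)}
#' and the mean inactivity time is
#' \eqn{\hat m_i(z) = E[z - Z \mid Z \le z] = \int_0^z F(t)\,dt / F(z)}.
#' The default path integrates the survival/distribution function
#' directly; `method = "series"` evaluates the exact binomial--erf
#' expansions of the truncated Gaussian-type integrals underlying both
#' quantities.  Near the boundaries, where the conditioning probability
#' vanishes, the analytic limits are returned: \eqn{\hat m_r \to \mu}
#' as \eqn{z \to 0^+} and \eqn{\hat m_i \to 1 - \mu} as
#' \eqn{z \to 1^-}.
#'
#' @param zeta positive shape parameter.
#' @param z evaluation point(s) in (0, 1).
#' @param method `"quadrature"` or `"series"`.
#' @param control a [series_control()] for the series path.
#' @return Numeric vector; `uasrd_mrl` values lie in \eqn{(0, 1-z)},
#'   `uasrd_mit` values in \eqn{(0, z)}.
#' @examples
#' uasrd_mrl(0.3, zeta = 1)
#' uasrd_mit(0.5, zeta = 0.95)
#' @export
uasrd_mrl <- function(z, zeta, method = c("quadrature", "series"),
                      control = series_control()) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(z, "z")
  method <- match.arg(method)
  one <- function(zz) {
    Rz <- suasrd(zz, zeta)
    if (Rz < 1e-12) return((1 - zz) / 2)  # degenerate upper tail
    if (puasrd(zz, zeta) < 1e-12)         # z in the far lower tail
      return(uasrd_moment(zeta) - zz)
    if (method == "quadrature") {
      num <- stats::integrate(function(t) suasrd(t, zeta), zz, 1,
                              rel.tol = 1e-11, abs.tol = 1e-13)$value
      return(num / Rz)
    }
    A <- -base::log(zz)
    term <- function(k) {
      b <- sqrt(2 * k + 1)
      g1 <- 2 / (pi * (2 * k + 1)) *
        (1 - zz * exp(-(2 * k + 1) * A^2 / (4 * zeta^2)))
      g2 <- 2 * zeta / (sqrt(pi) * (2 * k + 1)^1.5) * exp(zeta^2 / (2 * k + 1)) *
        (erf(zeta / b) - erf(((2 * k + 1) * A + 2 * zeta^2) / (2 * zeta * b)))
      central_binomial_weight(k) * (g1 + g2)
    }
    sum_binomial_series(term, control)$value / Rz - zz
  }
  vapply(z, one, 0)
}

#' @rdname uasrd_mrl
#' @export
uasrd_mit <- function(z, zeta, method = c("quadrature", "series"),
                      control = series_control()) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(z, "z")
  method <- match.arg(method)
  one <- function(zz) {
    Fz <- puasrd(zz, zeta)
    if (Fz < 1e-12) return(zz / 2)        # degenerate lower tail
    if (method == "quadrature") {
      num <- stats::integrate(function(t) puasrd(t, zeta), 0, zz,
                              rel.tol = 1e-11, abs.tol = 1e-13)$value
      return(num / Fz)
    }
    # z - psi_1-type truncated integral over the upper -log range
    A <- -base::log(zz)
    term <- function(k) {
      beta <- (2 * k + 1) / (4 * zeta^2)
      core <- exp(-beta * A^2 - A)
      x <- sqrt(beta) * A + 1 / (2 * sqrt(beta))
      central_binomial_weight(k) * core *
        (2 / (pi * (2 * k + 1)) -
           2 * zeta / (sqrt(pi) * (2 * k + 1)^1.5) * erfcx(x))
    }
    zz - sum_binomial_series(term, control)$value / Fz
  }
  vapply(z, one, 0)
}

#' Order statistics of a unit Arcsine-Rayleigh sample
#'
#' Density and distribution function of the \eqn{r}-th order statistic
#' of an i.i.d. sample of size \eqn{n}.  The distribution function is
#' computed by default from the numerically stable binomial-tail form
#' \eqn{\sum_{k=r}^n \binom{n}{k} F^k (1-F)^{n-k}} (equivalently
#' `pbinom`); the algebraically identical alternating double sum
#' \eqn{\sum_{k=r}^n \sum_{m=0}^{n-k} \binom{n}{k}\binom{n-k}{m}
#' (-1)^m F^{m+k}} is retained as `method = "double-sum"` for
#' cross-checking (it cancels catastrophically for large \eqn{n}).
#'
#' @param z evaluation point(s) in (0, 1).
#' @param r rank, \eqn{1 \le r \le n}.
#' @param n sample size.
#' @param zeta positive shape parameter.
#' @param method see Details.
#' @return Density or probability values.
#' @examples
#' integrate(duasrd_order, 0, 1, r = 2, n = 5, zeta = 1)  # unit mass
#' @export
duasrd_order <- function(z, r, n, zeta) {
  if (r < 1 || r > n || r != round(r)) stop("'r' must be an integer in 1..n")
  check_unit_interior(z, "z")
  Fv <- puasrd(z, zeta)
  exp(lgamma(n + 1) - lgamma(r) - lgamma(n - r + 1) +
        (r - 1) * base::log(Fv) + (n - r) * log1p(-Fv)) * duasrd(z, zeta)
}

#' @rdname duasrd_order
#' @export
puasrd_order <- function(z, r, n, zeta, method = c("binomial", "double-sum")) {
  if (r < 1 || r > n || r != round(r)) stop("'r' must be an integer in 1..n")
  method <- match.arg(method)
  check_unit_interior(z, "z")
  Fv <- puasrd(z, zeta)
  if (method == "binomial")
    return(stats::pbinom(r - 1, n, Fv, lower.tail = FALSE))
  vapply(Fv, function(p) {
    s <- 0
    for (k in r:n) for (m in 0:(n - k))
      s <- s + choose(n, k) * choose(n - k, m) * (-1)^m * p^(m + k)
    s
  }, 0)
}

#' Stochastic-ordering diagnostic curves
#'
#' Pointwise ratios comparing two shape parameters: the likelihood ratio
#' \eqn{r_1(z) = f(z;\zeta_1)/f(z;\zeta_2)} and the hazard ratio
#' \eqn{r_2(z) = h(z;\zeta_1)/h(z;\zeta_2)}.  For \eqn{\zeta_1 <
#' \zeta_2} the likelihood ratio is non-increasing in \eqn{z} (the
#' family is likelihood-ratio ordered in \eqn{\zeta}); the hazard ratio
#' is not globally monotone, which these curves make visible.
#'
#' @param z grid of evaluation points in (0, 1).
#' @param zeta1,zeta2 positive shape parameters.
#' @return Numeric vector of ratios along `z`.
#' @examples
#' r1 <- uasrd_lr_curve(seq(0.05, 0.95, 0.05), 0.5, 1.5)
#' all(diff(r1) <= 0)
#' @export
uasrd_lr_curve <- function(z, zeta1, zeta2) {
  exp(duasrd(z, zeta1, log = TRUE) - duasrd(z, zeta2, log = TRUE))
}

#' @rdname uasrd_lr_curve
#' @export
uasrd_hr_curve <- function(z, zeta1, zeta2) {
  # log-space evaluation: both hazards underflow in the deep lower tail
  exp(duasrd(z, zeta1, log = TRUE) - base::log(suasrd(z, zeta1)) -
        duasrd(z, zeta2, log = TRUE) + base::log(suasrd(z, zeta2)))
}

#' Stress-strength reliability
#'
#' The probability \eqn{R_{ss} = P(Z_1 > Z_2)} that an independent
#' strength \eqn{Z_1 \sim \mathrm{UASRD}(\zeta_1)} exceeds a stress
#' \eqn{Z_2 \sim \mathrm{UASRD}(\zeta_2)}.  The quantity depends on the
#' parameters only through \eqn{\alpha = (\zeta_1/\zeta_2)^2} and admits
#' the single-integral form
#' \deqn{R_{ss} = \frac{4}{\pi^2}\int_0^{\pi/2}
#'   \arcsin(\sin^\alpha\theta)\,d\theta,}
#' the default evaluation path (smooth integrand on a finite interval).
#' The equivalent arcsine-expansion series
#' \eqn{R_{ss} = 2\pi^{-3/2}\sum_k w_k
#' \Gamma(\tfrac{\alpha(2k+1)+1}{2}) / \{(2k+1)
#' \Gamma(\tfrac{\alpha(2k+1)+2}{2})\}} is available as a cross-check
#' (its terms decay like \eqn{k^{-3/2}}).  \eqn{\alpha = 1} gives
#' exactly 1/2 by symmetry, and \eqn{R_{ss}(\zeta_1,\zeta_2) +
#' R_{ss}(\zeta_2,\zeta_1) = 1}.
#'
#' @param zeta1,zeta2 shape parameters of strength and stress.
#' @param method `"integral"` or `"series"`.
#' @param control a [series_control()] for the series path.
#' @return The reliability in (0, 1).
#' @examples
#' uasrd_stress_strength(1.5, 1.0)
#' @export
uasrd_stress_strength <- function(zeta1, zeta2,
                                  method = c("integral", "series"),
                                  control = series_control()) {
  stopifnot_scalar_shape(zeta1); stopifnot_scalar_shape(zeta2)
  method <- match.arg(method)
  alpha <- (zeta1 / zeta2)^2
  if (alpha == 1) return(0.5)
  if (method == "integral") {
    return(4 / pi^2 * stats::integrate(function(th) asin(sin(th)^alpha),
                                       0, pi / 2, rel.tol = 1e-12,
                                       abs.tol = 1e-14)$value)
  }
  term <- function(k) {
    a1 <- (alpha * (2 * k + 1) + 1) / 2
    central_binomial_weight(k) / (2 * k + 1) * exp(lgamma(a1) - lgamma(a1 + 0.5))
  }
  2 / pi^1.5 * sum_binomial_series(term, control)$value
}
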