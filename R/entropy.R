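# Entropy measures.  All generalized entropies of order delta are
# functionals of the common integral
#   I_delta(zeta) = int_0^1 f(z; zeta)^delta dz,
# evaluated by default as int_0^inf f_X(t)^delta e^{(delta-1) t} dt in
# the -log scale (f_X the Arcsine-Rayleigh density, bounded at 0), or
# through the exact generalized-binomial / Kummer-1F1 series.

#' The entropy kernel integral
#'
#' \eqn{I_\delta(\zeta) = \int_0^1 f(z;\zeta)^\delta\,dz} for
#' \eqn{\delta > 0}.  The series path expands
#' \eqn{(1 - e^{-y^2/2\zeta^2})^{-\delta/2}} with generalised binomial
#' weights and reduces each term to Kummer confluent hypergeometric
#' functions:
#' \deqn{I_\delta = \frac{1}{\pi^\delta \zeta^{2\delta}} \sum_{k\ge0}
#'   \binom{\delta/2+k-1}{k}\,\tfrac{1}{2}\beta_k^{-\delta/2-1}
#'   \Big[(\delta-1)\,\Gamma(\tfrac{\delta}{2}+1)\,
#'   {}_1F_1(\tfrac{\delta}{2}+1;\tfrac32;x_k) + \sqrt{\beta_k}\,
#'   \Gamma(\tfrac{\delta+1}{2})\,
#'   {}_1F_1(\tfrac{\delta+1}{2};\tfrac12;x_k)\Big],}
#' with \eqn{\beta_k = (2k+\delta)/(4\zeta^2)} and
#' \eqn{x_k = (\delta-1)^2\zeta^2/(2k+\delta)}.
#'
#' @param zeta positive shape parameter.
#' @param delta positive entropy order (\eqn{\ne 1} for the generalized
#'   entropies; \eqn{I_1 = 1}).
#' @param method `"integral"` or `"series"`.
#' @param control a [series_control()] for the series path.
#' @return The (positive) value of the integral.
#' @examples
#' uasrd_idelta(1, delta = 2)
#' @export
uasrd_idelta <- function(zeta, delta, method = c("integral", "series"),
                         control = series_control()) {
  stopifnot_scalar_shape(zeta)
  if (delta <= 0) stop("'delta' must be positive")
  method <- match.arg(method)
  if (method == "integral") {
    # f_Z(e^{-t}) = f_X(t) e^{t}; integrate f_X(t)^delta e^{(delta-1)t}
    lfx <- function(t) {
      u <- t^2 / (2 * zeta^2)
      ifelse(u > 0,
             base::log(t) - t^2 / (4 * zeta^2) - base::log(pi * zeta^2) -
               0.5 * base::log(-expm1(-u)),
             base::log(sqrt(2) / (pi * zeta)))
    }
    return(stats::integrate(function(t) exp(delta * lfx(t) + (delta - 1) * t),
                            0, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value)
  }
  A <- delta - 1
  term <- function(k) {
    beta <- (2 * k + delta) / (4 * zeta^2)
    x <- A^2 / (4 * beta)
    inner <- 0.5 * beta^(-delta / 2 - 1) *
      (A * gamma(delta / 2 + 1) * kummer_1f1(delta / 2 + 1, 1.5, x) +
         sqrt(beta) * gamma((delta + 1) / 2) *
           kummer_1f1((delta + 1) / 2, 0.5, x))
    gen_binomial_weight(k, delta / 2) * inner /
      (pi^delta * zeta^(2 * delta))
  }
  sum_binomial_series(term, control)$value
}

#' Entropy measures of the unit Arcsine-Rayleigh distribution
#'
#' Shannon entropy and the five generalized entropies driven by the
#' kernel \eqn{I_\delta}: Renyi \eqn{\log I_\delta/(1-\delta)}, Arimoto
#' \eqn{\delta(I_\delta^{1/\delta}-1)/(1-\delta)}, Tsallis
#' \eqn{(1-I_\delta)/(\delta-1)}, Havrda-Charvat
#' \eqn{(I_\delta-1)/(2^{1-\delta}-1)} and Mathai-Haubold
#' \eqn{(I_{2-\delta}-1)/(\delta-1)} (the latter requires
#' \eqn{0 < \delta < 2} so that the kernel order \eqn{2-\delta} is
#' positive).  All five converge to the Shannon entropy as
#' \eqn{\delta \to 1}.
#'
#' Shannon entropy is computed either by quadrature of
#' \eqn{-E[\log f(Z)]} or from its exact series
#' \deqn{\mathrm{Sh}(\zeta) = \log(\pi\zeta)
#'   - \frac{\zeta}{\sqrt{2\pi}}\sum_k \frac{w_k}{(k+1/2)^{3/2}}
#'   - \frac{1}{2\pi}\sum_k w_k\,
#'     \frac{\log 2-\gamma-\log(k+1/2)}{k+1/2},}
#' \eqn{\gamma} Euler's constant.  The derivation of this closed form
#' rests on an exact cancellation of the quadratic log-moment against
#' the log-complement term, both reducing to moments of a
#' Beta(1/2, 1/2) variable with \eqn{E[\log Y] = E[\log(1-Y)] =
#' -2\log 2}.
#'
#' @param zeta positive shape parameter.
#' @param type entropy family.
#' @param delta order for the generalized entropies (ignored for
#'   `"shannon"`).
#' @param method `"integral"` or `"series"` (the path used for the
#'   kernel or, for Shannon, the expectation).
#' @param control a [series_control()].
#' @return The entropy value (differential; may be negative).
#' @examples
#' uasrd_entropy(1, "shannon")
#' uasrd_entropy(1, "renyi", delta = 2)
#' @export
uasrd_entropy <- function(zeta,
                          type = c("shannon", "renyi", "arimoto", "tsallis",
                                   "havrda-charvat", "mathai-haubold"),
                          delta = NULL,
                          method = c("integral", "series"),
                          control = series_control()) {
  stopifnot_scalar_shape(zeta)
  type <- match.arg(type)
  method <- match.arg(method)
  if (type == "shannon") {
    if (method == "integral")
      return(-.uasrd_expect(function(z) duasrd(z, zeta, log = TRUE), zeta))
    g <- -digamma(1)
    term <- function(k) {
      central_binomial_weight(k) *
        (-zeta / sqrt(2 * pi) / (k + 0.5)^1.5 -
           (base::log(2) - g - base::log(k + 0.5)) / (2 * pi * (k + 0.5)))
    }
    return(base::log(pi * zeta) + sum_binomial_series(term, control)$value)
  }
  if (is.null(delta)) stop("'delta' is required for generalized entropies")
  if (delta <= 0 || delta == 1)
    stop("'delta' must be positive and different from 1")
  if (type == "mathai-haubold" && delta >= 2)
    stop("Mathai-Haubold entropy requires 0 < delta < 2")
  kern_order <- if (type == "mathai-haubold") 2 - delta else delta
  I <- uasrd_idelta(zeta, kern_order, method = method, control = control)
  switch(type,
         "renyi" = base::log(I) / (1 - delta),
         "arimoto" = delta / (1 - delta) * (I^(1 / delta) - 1),
         "tsallis" = (1 - I) / (delta - 1),
         "havrda-charvat" = (I - 1) / (2^(1 - delta) - 1),
         "mathai-haubold" = (I - 1) / (delta - 1))
}
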