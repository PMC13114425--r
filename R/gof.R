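# Goodness of fit: information criteria and empirical-distribution-
# function statistics for a fitted unit Arcsine-Rayleigh model.

#' Information criteria from a maximised log-likelihood
#'
#' Standard penalised-likelihood criteria with \eqn{p} parameters and
#' \eqn{n} observations:
#' AIC \eqn{= -2\ell + 2p}, CAIC \eqn{= -2\ell + 2pn/(n-p-1)},
#' BIC \eqn{= -2\ell + p\log n} and HQIC \eqn{= -2\ell +
#' 2p\log\log n}.
#'
#' @param minus_2_loglik \eqn{-2\ell} at the optimum.
#' @param n sample size.
#' @param p number of estimated parameters.
#' @return Named numeric vector `aic`, `caic`, `bic`, `hqic`.
#' @export
information_criteria <- function(minus_2_loglik, n, p) {
  if (n <= p + 1) stop("CAIC undefined: need n > p + 1")
  c(aic = minus_2_loglik + 2 * p,
    caic = minus_2_loglik + 2 * p * n / (n - p - 1),
    bic = minus_2_loglik + p * base::log(n),
    hqic = minus_2_loglik + 2 * p * base::log(base::log(n)))
}

# EDF statistics of the PIT values u = F(z; zeta): the plain (n-
# unmodified) Anderson-Darling and Cramer-von Mises statistics and the
# two-sided Kolmogorov-Smirnov statistic, with the exact finite-n
# two-sided KS p-value.  (Both plain statistics and the exact p-value
# reproduce the reference analyses for this model; the small-sample
# modified variants do not.)
edf_statistics <- function(x, zeta) {
  u <- sort(puasrd(sort(x), zeta))
  n <- length(u)
  if (any(u <= 0 | u >= 1)) {
    warning("probability-integral transforms clamped away from 0/1")
    u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  w2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  a2 <- -n - mean((2 * i - 1) * (base::log(u) + base::log(1 - rev(u))))
  pv <- suppressWarnings(
    stats::ks.test(x, function(q) puasrd(q, zeta))$p.value)
  c(ad = a2, cvm = w2, ks = ks, ks_pvalue = pv)
}

#' Goodness of fit of a unit Arcsine-Rayleigh model
#'
#' Computes \eqn{-2\ell}, the AIC/CAIC/BIC/HQIC information criteria,
#' and the Anderson-Darling (\eqn{A^2}), Cramer-von Mises (\eqn{W^2})
#' and Kolmogorov-Smirnov statistics (with exact two-sided p-value) of
#' the probability-integral transforms under the fitted shape.
#'
#' @param object a [fit_uasrd()] object, or a numeric sample (in which
#'   case `zeta` must be given).
#' @param zeta shape parameter when `object` is a raw sample.
#' @return An object of class `"uasrd_gof"`: a list with
#'   `minus_2_loglik`, `aic`, `caic`, `bic`, `hqic`, `ad`, `cvm`, `ks`,
#'   `ks_pvalue`, `n` and `p`.
#' @examples
#' fit <- fit_uasrd(uasrd_data("tensile-strength"))
#' uasrd_gof(fit)
#' @export
uasrd_gof <- function(object, zeta = NULL) {
  if (inherits(object, "uasrd_fit")) {
    x <- object$data
    zeta <- object$zeta
  } else {
    x <- object
    if (is.null(zeta)) stop("'zeta' is required for a raw sample")
    check_unit_interior(x, "x")
  }
  n <- length(x)
  m2l <- -2 * uasrd_loglik(x, zeta)
  ic <- information_criteria(m2l, n, p = 1L)
  ed <- edf_statistics(x, zeta)
  structure(c(list(minus_2_loglik = m2l), as.list(ic), as.list(ed),
              list(n = n, p = 1L, zeta = zeta)),
            class = "uasrd_gof")
}

#' @export
print.uasrd_gof <- function(x, digits = 4, ...) {
  cat("Goodness of fit (zeta =", format(x$zeta, digits = digits + 1), ")\n")
  cat(sprintf("  -2 logLik: %.*f\n", digits, x$minus_2_loglik))
  cat(sprintf("  AIC %.*f | CAIC %.*f | BIC %.*f | HQIC %.*f\n",
              digits, x$aic, digits, x$caic, digits, x$bic, digits, x$hqic))
  cat(sprintf("  A* %.*f | W* %.*f | K-S %.*f (p = %.*f)\n",
              digits, x$ad, digits, x$cvm, digits, x$ks, digits,
              x$ks_pvalue))
  invisible(x)
}
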