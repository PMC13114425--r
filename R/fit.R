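# Classical (likelihood- and spacings-based) estimation of the shape
# parameter, with observed-information standard errors, Wald intervals,
# and delta-method inference for the survival and hazard functions.

#' Log-likelihood and score for a unit Arcsine-Rayleigh sample
#'
#' The log-likelihood of a sample \eqn{z_1,\dots,z_n} in (0, 1) is
#' \deqn{\ell(\zeta) = -n\log\pi - 2n\log\zeta - \sum\log z_i +
#'   \sum\log(-\log z_i) - \frac{1}{4\zeta^2}\sum\log^2 z_i -
#'   \frac12\sum\log\big(1 - e^{-\log^2 z_i/(2\zeta^2)}\big),}
#' and the score (its derivative in \eqn{\zeta}) is
#' \deqn{-\frac{2n}{\zeta} + \frac{1}{2\zeta^3}\sum\log^2 z_i +
#'   \frac{1}{2\zeta^3}\sum \log^2 z_i\,
#'   \frac{e^{-\log^2 z_i/(2\zeta^2)}}{1 - e^{-\log^2 z_i/(2\zeta^2)}}.}
#'
#' @param x sample of values strictly inside (0, 1).
#' @param zeta positive shape parameter.
#' @return Scalar log-likelihood / score value.
#' @seealso [fit_uasrd()]
#' @export
uasrd_loglik <- function(x, zeta) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(x, "x")
  sum(duasrd(x, zeta, log = TRUE))
}

#' @rdname uasrd_loglik
#' @export
uasrd_score <- function(x, zeta) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(x, "x")
  l2 <- base::log(x)^2
  xi <- l2 / (2 * zeta^2)
  n <- length(x)
  -2 * n / zeta + sum(l2) / (2 * zeta^3) +
    sum(l2 * exp(-xi) / (-expm1(-xi))) / (2 * zeta^3)
}

#' Log product of spacings
#'
#' The maximum-product-of-spacings objective
#' \eqn{\ell_{MPS}(\zeta) = \frac{1}{n+1}\sum_{i=1}^{n+1}\log D_i(\zeta)}
#' where the spacings \eqn{D_i = F(z_{i:n}) - F(z_{(i-1):n})} (with
#' \eqn{F(z_{0:n}) \equiv 0}, \eqn{F(z_{(n+1):n}) \equiv 1}) telescope to
#' one.  The sample is sorted internally.  Tied observations produce a
#' zero spacing; following the usual remedy its log term is replaced by
#' the log-density at the tied point, with a warning.
#'
#' @param x sample in (0, 1) (any order).
#' @param zeta positive shape parameter.
#' @return The mean log-spacing (the \eqn{1/(n+1)}-normalised sum).
#' @export
uasrd_logps <- function(x, zeta) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(x, "x")
  s <- sort(x)
  D <- diff(c(0, puasrd(s, zeta), 1))
  # far from the optimum extreme spacings can underflow; floor them so
  # the objective stays finite for the optimiser
  D[D < 1e-300] <- 1e-300
  tied <- which(diff(s) == 0)
  if (length(tied)) {
    warning("tied observations: zero spacings replaced by log-density terms")
    D[tied + 1L] <- NA_real_
    ld <- base::log(D)
    ld[tied + 1L] <- duasrd(s[tied], zeta, log = TRUE)
    return(sum(ld) / (length(x) + 1))
  }
  sum(base::log(D)) / (length(x) + 1)
}

# Observed information at the optimum: central second difference of the
# objective with relative step 1e-5.  For the spacings method the
# curvature of the *unnormalised* log-spacings sum (n+1) * l_MPS is
# used as the information analogue, matching the asymptotic variance of
# the MPS estimator (the 1/(n+1) prefactor of the objective is a
# normalisation, not part of the information).
observed_information <- function(objective, zeta_hat, rel_step = 1e-5) {
  h <- rel_step * zeta_hat
  I <- -(objective(zeta_hat + h) - 2 * objective(zeta_hat) +
           objective(zeta_hat - h)) / h^2
  if (!is.finite(I) || I <= 0)
    stop("non-positive curvature at the optimum: not a maximum")
  I
}

#' Fit the unit Arcsine-Rayleigh distribution
#'
#' Estimates the shape parameter \eqn{\zeta} from a sample on (0, 1) by
#' maximum likelihood (`"mle"`) or maximum product of spacings
#' (`"mps"`), using bounded quasi-Newton (`L-BFGS-B`) on
#' \eqn{\zeta \in [10^{-6}, 10^3]} with a multistart around the
#' Rayleigh-backbone moment start \eqn{\zeta_0 =
#' \sqrt{\overline{\log^2 z}/2}}.  Standard errors come from the
#' observed information (for MPS, the curvature of the unnormalised
#' log-spacings sum), and two-sided Wald intervals are formed at the
#' requested confidence levels.
#'
#' @param x numeric sample with all values strictly inside (0, 1).
#' @param method `"mle"` or `"mps"`.
#' @param conf_levels confidence levels for the Wald intervals.
#' @return An object of class `"uasrd_fit"`: a list with components
#'   `zeta` (estimate), `se`, `ci` (matrix of intervals), `method`,
#'   `loglik` (maximised log-likelihood of the sample, whatever the
#'   objective), `objective_value`, `converged`, `n`, and the data.
#'   Methods: `print`, `summary` (adds fit diagnostics via
#'   [uasrd_gof()]), `coef`, `vcov`, `confint`, `logLik`, `predict`
#'   (distribution functions at new points with delta-method
#'   intervals), `simulate`, `residuals` (quantile residuals) and
#'   `plot`.
#' @examples
#' z <- uasrd_data("tensile-strength")
#' fit <- fit_uasrd(z)
#' coef(fit); confint(fit)
#' predict(fit, z = 0.25, type = "reliability", se.fit = TRUE)
#' @export
fit_uasrd <- function(x, method = c("mle", "mps"),
                      conf_levels = c(0.90, 0.95)) {
  method <- match.arg(method)
  check_unit_interior(x, "x")
  n <- length(x)
  if (n < 2) stop("at least two observations are required")
  obj <- switch(method,
                mle = function(z) uasrd_loglik(x, z),
                mps = function(z) uasrd_logps(x, z))
  grad <- if (method == "mle") function(z) uasrd_score(x, z) else NULL
  z0 <- sqrt(mean(base::log(x)^2) / 2)
  starts <- c(0.5, 1, 2) * z0
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, fn = function(z) -obj(z),
                      gr = if (is.null(grad)) NULL else function(z) -grad(z),
                      method = "L-BFGS-B", lower = 1e-6, upper = 1e3,
                      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  zeta_hat <- best$par
  info_obj <- if (method == "mps") function(z) (n + 1) * obj(z) else obj
  info <- observed_information(info_obj, zeta_hat)
  se <- 1 / sqrt(info)
  ci <- t(vapply(conf_levels, function(lv) {
    zq <- stats::qnorm(1 - (1 - lv) / 2)
    c(lower = zeta_hat - zq * se, upper = zeta_hat + zq * se)
  }, numeric(2L)))
  rownames(ci) <- sprintf("%g%%", 100 * conf_levels)
  structure(list(zeta = zeta_hat, se = se, ci = ci,
                 conf_levels = conf_levels, method = method,
                 loglik = uasrd_loglik(x, zeta_hat),
                 objective_value = obj(zeta_hat),
                 converged = best$convergence == 0L,
                 info = info, n = n, data = x,
                 call = match.call()),
            class = "uasrd_fit")
}

#' @export
print.uasrd_fit <- function(x, digits = 4, ...) {
  cat("Unit Arcsine-Rayleigh fit (",
      if (x$method == "mle") "maximum likelihood" else
        "maximum product of spacings", ")\n", sep = "")
  cat("  n =", x$n, "\n")
  cat(sprintf("  zeta = %.*f  (SE %.*f)\n", digits, x$zeta, digits, x$se))
  for (i in seq_len(nrow(x$ci)))
    cat(sprintf("  %s CI: [%.*f, %.*f]\n", rownames(x$ci)[i],
                digits, x$ci[i, 1L], digits, x$ci[i, 2L]))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.uasrd_fit <- function(object, ...) c(zeta = object$zeta)

#' @export
vcov.uasrd_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("zeta", "zeta"))
}

#' @export
logLik.uasrd_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n, class = "logLik")
}

#' @export
confint.uasrd_fit <- function(object, parm = "zeta", level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$zeta - zq * object$se, object$zeta + zq * object$se), 1, 2,
         dimnames = list("zeta", sprintf("%g %%", 100 * c((1 - level) / 2,
                                                          1 - (1 - level) / 2))))
}

# central relative-step derivative of g at zeta
.num_deriv <- function(g, zeta, rel_step = 1e-6) {
  h <- rel_step * zeta
  (g(zeta + h) - g(zeta - h)) / (2 * h)
}

#' Predict method for unit Arcsine-Rayleigh fits
#'
#' Plug-in values of the density, distribution, survival (reliability)
#' or hazard function at new points, by the invariance property of the
#' ML and MPS estimators.  With `se.fit = TRUE` the delta method
#' propagates the estimator's variance through the requested function
#' (derivative by central differencing, relative step `1e-6`), and Wald
#' intervals are attached at the fit's confidence levels.
#'
#' @param object a [fit_uasrd()] result.
#' @param z evaluation points in (0, 1).
#' @param type which function to evaluate.
#' @param se.fit attach delta-method standard errors and intervals.
#' @param ... unused.
#' @return Numeric vector, or with `se.fit = TRUE` a `data.frame` with
#'   columns `z`, `fit`, `se` and interval bounds per confidence level.
#' @export
predict.uasrd_fit <- function(object, z,
                              type = c("reliability", "hazard", "density",
                                       "cdf"),
                              se.fit = FALSE, ...) {
  type <- match.arg(type)
  check_unit_interior(z, "z")
  fn <- switch(type,
               reliability = function(zz, zeta) suasrd(zz, zeta),
               hazard = function(zz, zeta) huasrd(zz, zeta),
               density = function(zz, zeta) duasrd(zz, zeta),
               cdf = function(zz, zeta) puasrd(zz, zeta))
  fit <- fn(z, object$zeta)
  if (!se.fit) return(fit)
  se <- vapply(z, function(zz)
    abs(.num_deriv(function(zeta) fn(zz, zeta), object$zeta)) * object$se, 0)
  out <- data.frame(z = z, fit = fit, se = se)
  for (i in seq_along(object$conf_levels)) {
    lv <- object$conf_levels[i]
    zq <- stats::qnorm(1 - (1 - lv) / 2)
    out[[sprintf("lower_%g", 100 * lv)]] <- fit - zq * se
    out[[sprintf("upper_%g", 100 * lv)]] <- fit + zq * se
  }
  out
}

#' @export
simulate.uasrd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, ruasrd(object$n, object$zeta), simplify = FALSE)
}

#' @export
residuals.uasrd_fit <- function(object, ...) {
  # quantile residuals: standard-normal under a correct model
  stats::qnorm(puasrd(object$data, object$zeta))
}

#' @export
summary.uasrd_fit <- function(object, ...) {
  structure(list(fit = object, gof = uasrd_gof(object)),
            class = "summary.uasrd_fit")
}

#' @export
print.summary.uasrd_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$gof, digits = digits)
  invisible(x)
}

#' @export
plot.uasrd_fit <- function(x, which = c("density", "cdf"), ...) {
  which <- match.arg(which)
  zg <- seq(0.001, 0.999, length.out = 400L)
  if (which == "density") {
    graphics::hist(x$data, freq = FALSE, breaks = "FD",
                   main = "Fitted unit Arcsine-Rayleigh density",
                   xlab = "z", ...)
    graphics::lines(zg, duasrd(zg, x$zeta), lwd = 2)
  } else {
    graphics::plot(stats::ecdf(x$data),
                   main = "Empirical vs fitted distribution function",
                   xlab = "z", ...)
    graphics::lines(zg, puasrd(zg, x$zeta), lwd = 2)
  }
  invisible(x)
}
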