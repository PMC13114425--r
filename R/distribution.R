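#' The unit Arcsine-Rayleigh distribution
#'
#' Density, distribution function, survival (reliability) function,
#' hazard rate, quantile function and random generation for the unit
#' Arcsine-Rayleigh distribution (UASRD) with shape parameter
#' \eqn{\zeta > 0}.  The UASRD arises as \eqn{Z = e^{-X}} where \eqn{X}
#' follows the Arcsine-Rayleigh lifetime model, and has support on the
#' open unit interval with
#' \deqn{F(z;\zeta) = 1 - \frac{2}{\pi}\arcsin\sqrt{1 -
#'   e^{-\log^2 z/(2\zeta^2)}}, \qquad 0 < z < 1.}
#' The density is evaluated through `expm1` so that the 0/0 form at the
#' upper end of the support is resolved exactly; its limit as
#' \eqn{z \to 1^-} is \eqn{\sqrt{2}/(\pi\zeta)}.
#'
#' The endpoints 0 and 1 are outside the support.  By default they raise
#' an error (silent boundary values usually indicate invalid data);
#' `boundary.ok = TRUE` instead returns the limiting values.
#'
#' @param x,z,q vector of quantiles in (0, 1).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param zeta positive shape parameter.
#' @param log,log.p logical; return log values.
#' @param lower.tail logical; if `FALSE`, probabilities are
#'   \eqn{P(Z > z)}.
#' @param boundary.ok allow evaluation at 0 and 1, returning limits.
#' @return `duasrd` the density, `puasrd` the distribution function,
#'   `suasrd` the survival function, `huasrd` the hazard rate (which
#'   diverges as \eqn{z \to 1^-}), `quasrd` the quantile function and
#'   `ruasrd` a vector of variates.
#' @examples
#' quasrd(c(0.25, 0.5, 0.75), zeta = 0.95)
#' integrate(duasrd, 0, 1, zeta = 2)       # unit mass
#' set.seed(1); mean(ruasrd(1e4, zeta = 0.95))
#' @name uasrd-distribution
NULL

# log' z^2 / (2 zeta^2), the argument of the inner exponential
.uasrd_xi <- function(z, zeta) log(z)^2 / (2 * zeta^2)

#' @rdname uasrd-distribution
#' @export
duasrd <- function(x, zeta, log = FALSE, boundary.ok = FALSE) {
  stopifnot_scalar_shape(zeta)
  if (boundary.ok) {
    out <- numeric(length(x))
    inner <- x > 0 & x < 1
    out[x <= 0] <- if (log) -Inf else 0
    out[x >= 1] <- if (log) base::log(sqrt(2) / (pi * zeta)) else sqrt(2) / (pi * zeta)
    if (any(inner)) out[inner] <- duasrd(x[inner], zeta, log = log)
    return(out)
  }
  check_unit_interior(x, "x")
  t <- -base::log(x)
  # 1 - exp(-t^2/(2 zeta^2)) via expm1: exact through the z -> 1 limit,
  # where t/sqrt(-expm1(-t^2/(2 zeta^2))) -> zeta * sqrt(2)
  u <- t^2 / (2 * zeta^2)
  ld <- ifelse(u > 0,
               base::log(t) - t^2 / (4 * zeta^2) - base::log(pi * zeta^2) -
                 base::log(x) - 0.5 * base::log(-expm1(-u)),
               base::log(sqrt(2) / (pi * zeta)) - base::log(x))
  if (log) ld else exp(ld)
}

#' @rdname uasrd-distribution
#' @export
puasrd <- function(q, zeta, lower.tail = TRUE, log.p = FALSE,
                   boundary.ok = FALSE) {
  stopifnot_scalar_shape(zeta)
  if (boundary.ok) {
    out <- numeric(length(q))
    inner <- q > 0 & q < 1
    out[q <= 0] <- 0
    out[q >= 1] <- 1
    if (any(inner)) out[inner] <- puasrd(q[inner], zeta)
    if (!lower.tail) out <- 1 - out
    return(if (log.p) base::log(out) else out)
  }
  check_unit_interior(q, "q")
  # complementary arcsin forms: each tail is computed without
  # cancellation (asin(x) + asin(sqrt(1-x^2)) = pi/2)
  u <- .uasrd_xi(q, zeta)
  if (lower.tail) {
    p <- 2 / pi * asin(exp(-u / 2))
  } else {
    # where exp(-u) is below working precision the sqrt saturates at 1;
    # the exact complement of the lower-tail form keeps the tail
    p <- ifelse(exp(-u) < 1e-8,
                1 - 2 / pi * asin(exp(-u / 2)),
                2 / pi * asin(sqrt(-expm1(-u))))
  }
  if (log.p) base::log(p) else p
}

#' @rdname uasrd-distribution
#' @export
suasrd <- function(q, zeta, boundary.ok = FALSE) {
  puasrd(q, zeta, lower.tail = FALSE, boundary.ok = boundary.ok)
}

#' @rdname uasrd-distribution
#' @export
huasrd <- function(z, zeta) {
  stopifnot_scalar_shape(zeta)
  check_unit_interior(z, "z")
  duasrd(z, zeta) / suasrd(z, zeta)
}

#' @rdname uasrd-distribution
#' @export
quasrd <- function(p, zeta, lower.tail = TRUE, log.p = FALSE) {
  stopifnot_scalar_shape(zeta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  check_unit_interior(p, "p")
  exp(-zeta * sqrt(-4 * base::log(sin(pi * p / 2))))
}

#' @rdname uasrd-distribution
#' @export
ruasrd <- function(n, zeta) {
  stopifnot_scalar_shape(zeta)
  if (length(n) != 1L || n < 1) stop("'n' must be a positive count")
  quasrd(stats::runif(n), zeta)
}

#' Mode of the unit Arcsine-Rayleigh density
#'
#' Solves the stationarity condition of the log-density,
#' \deqn{1 - \log z - \frac{\log^2 z}{2\zeta^2\,(1 - e^{-\log^2
#'   z/(2\zeta^2)})} = 0,}
#' by bracketing on a geometric grid in \eqn{t = -\log z} followed by
#' `uniroot` refinement.  An interior stationary point exists for every
#' \eqn{\zeta}: the left-hand side tends to \eqn{0^+} as \eqn{z \to 1^-}
#' and to \eqn{-\infty} as \eqn{z \to 0^+}.  For large \eqn{\zeta} the
#' mode underflows double precision in \eqn{z}; the root is therefore
#' also reported on the \eqn{-\log z} scale.
#'
#' @param zeta positive shape parameter.
#' @param tol root tolerance (on the \eqn{t} scale).
#' @return A list with `mode` (the location in (0,1), possibly 0 by
#'   underflow), `neg_log_mode` (\eqn{-\log} of the mode), `interior`
#'   (logical: a bracketed interior root was found) and `objective` (the
#'   stationarity residual at the root).
#' @examples
#' m <- uasrd_mode(0.95)
#' m$mode  # maximiser of duasrd(., 0.95)
#' @export
uasrd_mode <- function(zeta, tol = 1e-12) {
  stopifnot_scalar_shape(zeta)
  g <- function(t) {
    u <- t^2 / (2 * zeta^2)
    ratio <- ifelse(u > 1e-8, u / (-expm1(-u)), 1 + u / 2 + u^2 / 12)
    1 + t - ratio
  }
  grid <- exp(seq(base::log(1e-10), base::log(1e3 * max(zeta, 1)), length.out = 512L))
  v <- g(grid)
  ix <- which(v[-1L] * v[-length(v)] <= 0)
  if (!length(ix)) {
    return(list(mode = NA_real_, neg_log_mode = NA_real_, interior = FALSE,
                objective = NA_real_))
  }
  r <- stats::uniroot(g, lower = grid[ix[1L]], upper = grid[ix[1L] + 1L],
                      tol = tol)
  list(mode = exp(-r$root), neg_log_mode = r$root, interior = TRUE,
       objective = r$f.root)
}
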