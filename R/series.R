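#' Truncation control for the infinite binomial series
#'
#' Many quantities of the unit Arcsine-Rayleigh distribution have exact
#' series representations whose terms carry the central binomial weight
#' \eqn{\binom{2k}{k}/4^k \sim 1/\sqrt{\pi k}} and decay only like
#' \eqn{k^{-3/2}}.  A plain partial sum of \eqn{K} terms therefore still
#' misses a tail of order \eqn{1/\sqrt{K}}, which is far too large at any
#' practical \eqn{K}.  The series evaluator compensates with an
#' Euler--Maclaurin tail estimate (the summand, extended to real index
#' through log-gamma, is integrated over the remaining range), which
#' brings partial sums of a few thousand terms to near machine accuracy.
#'
#' @param rel_tol relative tolerance on the summed value.
#' @param abs_tol absolute tolerance.
#' @param k_max largest index summed explicitly before the tail estimate
#'   takes over (or, with `tail = "none"`, the hard truncation point).
#' @param tail `"integral"` for the Euler--Maclaurin tail correction,
#'   `"none"` for a literal partial sum.
#' @return An object of class `"uasrd_series_control"`.
#' @seealso [sum_binomial_series()]
#' @export
series_control <- function(rel_tol = 1e-10, abs_tol = 1e-14, k_max = 20000L,
                           tail = c("integral", "none")) {
  stopifnot(rel_tol > 0, abs_tol > 0, k_max >= 1)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 k_max = as.integer(k_max), tail = match.arg(tail)),
            class = "uasrd_series_control")
}

#' Central binomial weight
#'
#' The weight \eqn{w_k = \binom{2k}{k}/4^k} appearing in every series
#' expansion of the distribution (it is the coefficient of \eqn{w^k} in
#' \eqn{(1-w)^{-1/2}}).  Computed in log space; for very large `k` the
#' log-gamma differences lose precision and an asymptotic expansion in
#' \eqn{1/k} is used instead.  Accepts real `k` (used by the tail
#' integrator).
#'
#' @param k nonnegative index (vectorised; real values allowed).
#' @param log return the logarithm of the weight.
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' central_binomial_weight(0:3)  # 1, 1/2, 3/8, 5/16
#' @export
central_binomial_weight <- function(k, log = FALSE) {
  if (any(k < 0)) stop("'k' must be nonnegative")
  lw <- numeric(length(k))
  big <- k > 1e7
  if (any(!big)) {
    kk <- k[!big]
    lw[!big] <- lgamma(2 * kk + 1) - 2 * lgamma(kk + 1) - kk * base::log(4)
  }
  if (any(big)) {
    kk <- k[big]
    corr <- 1 - 1 / (8 * kk) + 1 / (128 * kk^2) + 5 / (1024 * kk^3)
    lw[big] <- -0.5 * base::log(pi * kk) + base::log(corr)
  }
  if (log) lw else exp(lw)
}

# Generalised binomial weight C(a + k - 1, k) = Gamma(k + a) /
# (Gamma(a) Gamma(k + 1)), the coefficient in (1 - w)^{-a}.  Real k
# allowed; asymptotic branch for very large k avoids lgamma cancellation.
gen_binomial_weight <- function(k, a, log = FALSE) {
  lw <- numeric(length(k))
  big <- k > 1e7
  if (any(!big)) {
    kk <- k[!big]
    lw[!big] <- lgamma(kk + a) - lgamma(a) - lgamma(kk + 1)
  }
  if (any(big)) {
    kk <- k[big]
    # Gamma(k+a)/Gamma(k+1) ~ k^(a-1) (1 + (a-1)a/(2k))
    lw[big] <- (a - 1) * base::log(kk) + log1p((a - 1) * a / (2 * kk)) - lgamma(a)
  }
  if (log) lw else exp(lw)
}

#' Sum a slowly converging binomial-type series
#'
#' Evaluates \eqn{\sum_{k\ge 0} t(k)} for a summand `term` that must be
#' vectorised and defined for real \eqn{k \ge 0} (all series in this
#' package are built from log-gamma expressions, so extending the index
#' to the real line is immediate).  The partial sum to `k_max` is
#' augmented, unless `tail = "none"`, by the Euler--Maclaurin tail
#' \eqn{\int_{K+1}^\infty t(x)\,dx + t(K+1)/2}, computed under the
#' substitution \eqn{x = v^{-2}} which flattens the ubiquitous
#' \eqn{k^{-3/2}} decay.
#'
#' @param term vectorised function of the (real) index.
#' @param control a [series_control()] object.
#' @return A list with `value`, `terms_used`, `converged` and
#'   `tail_estimate`.  `converged` is `FALSE` when the terms show no
#'   decay by `k_max` (divergent or too slowly converging series).
#' @examples
#' # generating-function identity: sum w_k x^k = 1/sqrt(1-x)
#' s <- sum_binomial_series(function(k) central_binomial_weight(k) * 0.5^k)
#' all.equal(s$value, sqrt(2))
#' @export
sum_binomial_series <- function(term, control = series_control()) {
  K <- control$k_max
  k <- 0:K
  tk <- term(k)
  if (any(!is.finite(tk)))
    stop("non-finite series term at k = ", k[which(!is.finite(tk))[1L]])
  s <- sum(tk)
  # decay diagnostic: compare head and tail blocks of |terms|
  nb <- max(10L, K %/% 100L)
  head_mag <- mean(abs(tk[seq_len(nb)]))
  tail_mag <- mean(abs(tk[(K + 1L - nb):(K + 1L)]))
  decaying <- tail_mag < head_mag || head_mag == 0
  tail_est <- 0
  converged <- decaying
  if (control$tail == "integral" && decaying && tail_mag > 0) {
    a <- K + 1
    ti <- tryCatch(
      stats::integrate(function(v) term(v^-2) * 2 / v^3, 0, 1 / sqrt(a),
                       rel.tol = 1e-9, abs.tol = control$abs_tol)$value,
      error = function(e) NA_real_)
    if (is.na(ti)) {
      converged <- FALSE
    } else {
      tail_est <- ti + term(a) / 2
      s <- s + tail_est
    }
  } else if (control$tail == "none") {
    # literal partial sum: converged only if last terms are below tolerance
    converged <- decaying &&
      tail_mag <= max(control$abs_tol, control$rel_tol * abs(s))
  }
  list(value = s, terms_used = K + 1L, converged = converged,
       tail_estimate = tail_est)
}

# Adaptive quadrature wrapper used as the reference evaluation path for
# every series-valued quantity.  domain "unit" integrates over (0,1),
# "positive" over (0, Inf).
quadrature_oracle <- function(integrand, domain = c("unit", "positive"),
                              rel_tol = 1e-10) {
  domain <- match.arg(domain)
  upper <- if (domain == "unit") 1 else Inf
  r <- stats::integrate(integrand, 0, upper, rel.tol = rel_tol,
                        abs.tol = rel_tol, stop.on.error = FALSE)
  if (!r$message %in% c("OK", "the integral is probably divergent") &&
      r$abs.error > max(1e-8, 1e-6 * abs(r$value)))
    stop("quadrature failed to converge: ", r$message)
  r$value
}
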