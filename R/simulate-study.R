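# Monte Carlo evaluation harness: generate-fit-summarise over grids of
# sample size, true shape and estimator flavour, reporting average
# estimate (AE), root mean squared error (RMSE), mean relative absolute
# bias (MRAB), average interval length (AL) and coverage probability
# (CP) for the shape, the survival function and the hazard at a fixed
# point.

.sim_estimators <- c("ML", "MPS", "S-ML-I", "S-ML-N", "S-MPS-I", "S-MPS-N")

# One replicate: returns estimate / lower / upper per target and level.
.sim_replicate <- function(x, estimator, z_eval, levels, mcmc, prior_true) {
  bayes <- grepl("^S-", estimator)
  if (!bayes) {
    fit <- fit_uasrd(x, method = if (estimator == "ML") "mle" else "mps",
                     conf_levels = levels)
    pr_r <- predict(fit, z_eval, type = "reliability", se.fit = TRUE)
    pr_h <- predict(fit, z_eval, type = "hazard", se.fit = TRUE)
    est <- c(zeta = fit$zeta, reliability = pr_r$fit, hazard = pr_h$fit)
    ints <- lapply(seq_along(levels), function(i) {
      lo <- sprintf("lower_%g", 100 * levels[i])
      hi <- sprintf("upper_%g", 100 * levels[i])
      rbind(zeta = fit$ci[i, ],
            reliability = c(pr_r[[lo]], pr_r[[hi]]),
            hazard = c(pr_h[[lo]], pr_h[[hi]]))
    })
  } else {
    basis <- if (grepl("ML", estimator)) "likelihood" else "spacings"
    informative <- grepl("-I$", estimator)
    prior <- if (informative) prior_true else uasrd_prior("jeffreys")
    post <- uasrd_bayes(x, basis = basis, prior = prior,
                        n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                        z = z_eval, conf_levels = levels)
    est <- post$estimates
    ints <- lapply(seq_along(levels), function(i) {
      rbind(zeta = post$hpd$zeta[i, ],
            reliability = post$hpd$reliability[i, ],
            hazard = post$hpd$hazard[i, ])
    })
  }
  list(est = est, ints = ints)
}

#' Run one Monte Carlo cell
#'
#' Simulates `replications` samples of size `n` from the distribution
#' with true shape `zeta` (inverse-transform sampling), applies the
#' requested estimator, and summarises the estimates of \eqn{\zeta},
#' \eqn{R(z)} and \eqn{h(z)} by AE, RMSE, MRAB, and the AL/CP of the
#' intervals at each level.  Per-replicate seeds are derived
#' deterministically from `seed` so any cell can be reproduced in
#' isolation.  Replicates whose fit fails are excluded and counted in
#' `failures` (never silently dropped).
#'
#' @param n sample size.
#' @param zeta true shape.
#' @param estimator one of `"ML"`, `"MPS"`, `"S-ML-I"`, `"S-ML-N"`,
#'   `"S-MPS-I"`, `"S-MPS-N"` (S- prefixes are Metropolis-Hastings
#'   posteriors, -I informative moment-matched prior on the truth with
#'   variance `0.25 * zeta^2`, -N Jeffreys).
#' @param replications Monte Carlo replicates.
#' @param z_eval evaluation point for survival/hazard.
#' @param levels interval levels.
#' @param seed master seed for the cell.
#' @param mcmc list with `n_iter` and `burn_in` for Bayesian cells.
#' @return A `data.frame` with one row per target (zeta, reliability,
#'   hazard) and columns `estimator`, `n`, `zeta_true`, `target`,
#'   `truth`, `ae`, `rmse`, `mrab`, `al_*`, `cp_*`, `failures`.
#' @examples
#' uasrd_sim_cell(20, 0.75, "ML", replications = 10, seed = 1)
#' @export
uasrd_sim_cell <- function(n, zeta, estimator = "ML", replications = 200L,
                           z_eval = 0.25, levels = c(0.90, 0.95),
                           seed = 1L,
                           mcmc = list(n_iter = 2500L, burn_in = 500L)) {
  estimator <- match.arg(estimator, .sim_estimators)
  stopifnot_scalar_shape(zeta)
  truth <- c(zeta = zeta, reliability = suasrd(z_eval, zeta),
             hazard = huasrd(z_eval, zeta))
  prior_true <- elicit_gamma_prior(zeta, 0.25 * zeta^2)
  ests <- matrix(NA_real_, replications, 3L,
                 dimnames = list(NULL, names(truth)))
  cover <- len <- array(NA_real_, c(replications, 3L, length(levels)))
  failures <- 0L
  for (r in seq_len(replications)) {
    set.seed(seed + 1000003L * (r - 1L) %% 2147480000L)
    x <- ruasrd(n, zeta)
    res <- tryCatch(
      .sim_replicate(x, estimator, z_eval, levels, mcmc, prior_true),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    ests[r, ] <- res$est
    for (i in seq_along(levels)) {
      lo <- res$ints[[i]][, 1L]; hi <- res$ints[[i]][, 2L]
      len[r, , i] <- hi - lo
      cover[r, , i] <- as.numeric(truth >= lo & truth <= hi)
    }
  }
  ok <- !is.na(ests[, 1L])
  out <- lapply(1:3, function(j) {
    e <- ests[ok, j]
    row <- data.frame(estimator = estimator, n = n, zeta_true = zeta,
                      target = names(truth)[j], truth = truth[j],
                      ae = mean(e),
                      rmse = sqrt(mean((e - truth[j])^2)),
                      mrab = mean(abs(e - truth[j]) / truth[j]),
                      failures = failures, row.names = NULL)
    for (i in seq_along(levels)) {
      row[[sprintf("al_%g", 100 * levels[i])]] <- mean(len[ok, j, i])
      row[[sprintf("cp_%g", 100 * levels[i])]] <- mean(cover[ok, j, i])
    }
    row
  })
  do.call(rbind, out)
}

#' Run a Monte Carlo grid
#'
#' Cross-product of sample sizes, true shapes and estimators, each cell
#' handled by [uasrd_sim_cell()].  The full published-scale design uses
#' sample sizes \{20, 40, 80, 160, 320, 640\}, shapes \{0.25, 0.75,
#' 2.25, 6.75, 14\} and 1000 replications with 12000/2000
#' Metropolis-Hastings iterations; the defaults here are a desk-scale
#' reduction (see the vignette).
#'
#' @param sample_sizes vector of sample sizes.
#' @param zetas vector of true shape values.
#' @param estimators subset of the six estimator labels.
#' @param replications replicates per cell.
#' @param z_eval evaluation point.
#' @param levels interval levels.
#' @param seed master seed; cell seeds are derived from it.
#' @param mcmc Bayesian chain configuration.
#' @param verbose print progress.
#' @return Long-format `data.frame` of cell summaries (3 rows per
#'   cell, one per target).
#' @export
uasrd_sim_grid <- function(sample_sizes = c(20L, 80L, 320L),
                           zetas = c(0.75, 2.25),
                           estimators = c("ML", "MPS"),
                           replications = 200L, z_eval = 0.25,
                           levels = c(0.90, 0.95), seed = 1L,
                           mcmc = list(n_iter = 2500L, burn_in = 500L),
                           verbose = FALSE) {
  grid <- expand.grid(n = sample_sizes, zeta = zetas, estimator = estimators,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (verbose)
      message(sprintf("cell %d/%d: n=%d zeta=%g %s", i, nrow(grid),
                      grid$n[i], grid$zeta[i], grid$estimator[i]))
    out[[i]] <- uasrd_sim_cell(grid$n[i], grid$zeta[i], grid$estimator[i],
                               replications = replications, z_eval = z_eval,
                               levels = levels, seed = seed + 7919L * i,
                               mcmc = mcmc)
  }
  do.call(rbind, out)
}
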