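# Truncated-normal-on-[0,1] helpers (inverse-CDF sampling; parameters are
# those of the parent normal before truncation).

dtruncnorm01 <- function(x, mean, sd, log = FALSE) {
  z <- pnorm(1, mean, sd) - pnorm(0, mean, sd)
  out <- ifelse(x < 0 | x > 1, if (log) -Inf else 0,
                if (log) dnorm(x, mean, sd, log = TRUE) - log(z)
                else dnorm(x, mean, sd) / z)
  out
}

rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' Build the per-scenario belonging-measure priors
#'
#' One truncated-normal prior per scenario: centred on the normalized
#' averaged expert rating (averaged rating / 10), with a common
#' pre-truncation standard deviation (default 0.15), truncated to the BM
#' support \[0, 1\].
#'
#' @param experts An [expert_ratings()] object.
#' @param sigma Pre-truncation standard deviation of each prior (> 0).
#' @return A `scenario_priors` object: data.frame with columns
#'   `scenario_id`, `mu`, `sigma`.
#' @examples
#' m <- matrix(c(10, 0, 10, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("e1", "e2")))
#' build_scenario_priors(expert_ratings(m))
#' @export
build_scenario_priors <- function(experts, sigma = 0.15) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  structure(
    data.frame(scenario_id = experts$scenario_ids,
               mu = as.numeric(experts$normalized),
               sigma = sigma,
               stringsAsFactors = FALSE),
    class = c("scenario_priors", "data.frame")
  )
}

#' Prior density of one scenario's belonging measure
#'
#' Density of the truncated-normal prior for a single scenario, zero
#' outside \[0, 1\] and integrating to one over it.
#'
#' @param x Evaluation points.
#' @param prior One row of a `scenario_priors` data.frame (or any list with
#'   `mu` and `sigma`).
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @export
scenario_prior_density <- function(x, prior, log = FALSE) {
  dtruncnorm01(x, prior$mu, prior$sigma, log = log)
}

#' MCMC configuration
#'
#' Sampler and model settings for the per-rater posterior fits.
#'
#' @param n_chains Number of chains.
#' @param n_iterations Iterations per chain (including warmup).
#' @param n_warmup Warmup (discarded) iterations per chain.
#' @param seed Base RNG seed; rater `k` in [fit_all()] uses `seed + k`.
#' @param tau Steepness of the logistic link approximating the hard
#'   decision rule BM > BT; the Bernoulli success probability is
#'   `plogis((bm - bt) / tau)`.  Smaller tau = closer to the hard rule.
#' @param bt_prior Prior on the belonging threshold:
#'   `list(type = "uniform")` (default) or
#'   `list(type = "truncnorm", mu =, sigma =)` on \[0, 1\].
#' @param rhat_threshold Split-chain R-hat above which a fit is flagged as
#'   non-converged.
#' @param ess_threshold Minimum effective sample size per parameter.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4L, n_iterations = 2000L,
                        n_warmup = 1000L, seed = 1L, tau = 0.05,
                        bt_prior = list(type = "uniform"),
                        rhat_threshold = 1.01, ess_threshold = 400) {
  if (n_warmup >= n_iterations) {
    stop("n_warmup must be smaller than n_iterations", call. = FALSE)
  }
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!bt_prior$type %in% c("uniform", "truncnorm")) {
    stop("bt_prior$type must be 'uniform' or 'truncnorm'", call. = FALSE)
  }
  structure(
    list(n_chains = as.integer(n_chains),
         n_iterations = as.integer(n_iterations),
         n_warmup = as.integer(n_warmup),
         seed = as.integer(seed), tau = tau, bt_prior = bt_prior,
         rhat_threshold = rhat_threshold, ess_threshold = ess_threshold),
    class = "mcmc_config"
  )
}

bt_log_prior <- function(bt, bt_prior) {
  if (bt_prior$type == "uniform") {
    ifelse(bt < 0 | bt > 1, -Inf, 0)
  } else {
    dtruncnorm01(bt, bt_prior$mu, bt_prior$sigma, log = TRUE)
  }
}

#' Unnormalized log posterior of one rater's parameters
#'
#' Sum of the truncated-normal log priors on the belonging measures, the
#' log prior on the belonging threshold, and the Bernoulli log likelihood
#' of the observed binary decisions with success probability
#' `plogis((bm_i - bt) / tau)` -- a smooth approximation of the hard rule
#' "decide 1 iff BM exceeds BT" that converges to it as `tau -> 0`.
#' Returns `-Inf` whenever any parameter leaves \[0, 1\].
#'
#' @param bt Scalar belonging threshold.
#' @param bms Numeric vector of belonging measures, one per scenario.
#' @param y Binary decision vector (0/1), aligned with `bms`.
#' @param priors A `scenario_priors` data.frame aligned with `y`.
#' @param config An [mcmc_config()].
#' @return Scalar unnormalized log posterior density.
#' @export
log_posterior <- function(bt, bms, y, priors, config = mcmc_config()) {
  n <- length(y)
  if (length(bms) != n || nrow(priors) != n) {
    stop("bms, y and priors must have matching lengths", call. = FALSE)
  }
  if (bt < 0 || bt > 1 || any(bms < 0 | bms > 1)) return(-Inf)
  lp <- sum(dtruncnorm01(bms, priors$mu, priors$sigma, log = TRUE)) +
    bt_log_prior(bt, config$bt_prior)
  q <- (bms - bt) / config$tau
  # stable Bernoulli log-lik: log plogis(q) for y=1, log plogis(-q) for y=0
  ll <- sum(stats::plogis(ifelse(y == 1, q, -q), log.p = TRUE))
  lp + ll
}

#' Grid-integration oracle for the per-rater posterior
#'
#' Computes the posterior means of the belonging threshold and the
#' belonging measures by dense numerical integration of the same
#' unnormalized posterior evaluated by [log_posterior()].  Conditional on
#' the threshold the posterior factorizes over scenarios, so the
#' high-dimensional integral reduces exactly to one-dimensional quadratures
#' per scenario nested in a one-dimensional quadrature over the threshold;
#' midpoint rules with step `grid_step` are used throughout.  Intended as a
#' brute-force verification oracle for small instances.
#'
#' @param y Binary decision vector.
#' @param priors A `scenario_priors` data.frame aligned with `y`.
#' @param config An [mcmc_config()] (only `tau` and `bt_prior` are used).
#' @param grid_step Quadrature step on \[0, 1\].
#' @param max_scenarios Capacity guard; instances with more scenarios
#'   raise an error.
#' @return List with `bt_mean` and `bm_means`.
#' @export
grid_posterior_oracle <- function(y, priors, config = mcmc_config(),
                                  grid_step = 0.001, max_scenarios = 15L) {
  n <- length(y)
  if (nrow(priors) != n) stop("y and priors must align", call. = FALSE)
  if (n > max_scenarios) {
    stop(sprintf("grid oracle capacity exceeded: %d scenarios (max %d)",
                 n, max_scenarios), call. = FALSE)
  }
  g <- seq(grid_step / 2, 1 - grid_step / 2, by = grid_step) # midpoints
  m <- length(g)

  log_bt_prior <- bt_log_prior(g, config$bt_prior)
  if (n == 0L) {
    w <- exp(log_bt_prior - max(log_bt_prior))
    return(list(bt_mean = sum(g * w) / sum(w), bm_means = numeric(0)))
  }

  # per-scenario integrals of prior(b) * lik(y | b, bt) over b, per bt value
  log_z <- matrix(0, m, n)   # log \int f_i(b; bt) db
  bm_cond <- matrix(0, m, n) # conditional posterior mean of bm_i given bt
  for (i in seq_len(n)) {
    lp_b <- dtruncnorm01(g, priors$mu[i], priors$sigma[i], log = TRUE)
    q <- outer(g, g, function(b, bt) (b - bt) / config$tau) # b rows, bt cols
    if (y[i] == 0) q <- -q
    log_f <- lp_b + stats::plogis(q, log.p = TRUE)          # m_b x m_bt
    mx <- apply(log_f, 2L, max)
    f <- exp(sweep(log_f, 2L, mx))
    z <- colSums(f)
    log_z[, i] <- mx + log(z * grid_step)
    bm_cond[, i] <- colSums(g * f) / z
  }

  log_w <- log_bt_prior + rowSums(log_z)
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  list(bt_mean = sum(g * w),
       bm_means = as.numeric(colSums(w * bm_cond)))
}
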