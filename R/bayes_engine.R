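#' MCMC sampler configuration
#'
#' Defaults follow common practice for this model: 3 chains, a burn-in
#' of 50,000 iterations, 200,000 sampling iterations with thinning rate
#' 2 (every 2nd draw retained). Proposal scales are adapted only during
#' the burn-in (over at most `adapt_window` iterations) and frozen
#' afterwards, so the retained draws come from a fixed-kernel chain.
#'
#' @param chains number of chains (>= 2, so convergence can be judged).
#' @param burn_in iterations discarded from the start of each chain.
#' @param iterations post-burn-in iterations per chain.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param seed integer; chain `j` uses `seed + j - 1`.
#' @param adapt_window number of initial iterations during which
#'   proposal scales adapt (capped at `burn_in`).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 3, burn_in = 50000, iterations = 200000,
                           thin = 2, seed = 1, adapt_window = burn_in) {
  stopifnot(chains >= 2, thin >= 1, burn_in >= 0, iterations >= thin)
  structure(list(chains = as.integer(chains),
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_window = as.integer(min(adapt_window, burn_in))),
            class = "sampler_config")
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# binomial log-likelihood up to the constant binomial coefficient,
# parameterized by the logit eta: r*eta - n*log(1 + exp(eta))
binom_ll <- function(eta, r, n) r * eta - n * log1pexp(eta)

#' Log posterior density of the hierarchical binomial-logit model
#'
#' The model: for study i, `r_c ~ Bin(n_c, plogis(mu_i))` and
#' `r_t ~ Bin(n_t, plogis(mu_i + delta_i))`; study-level log odds
#' ratios `delta_i ~ N(theta, tau^2)`; vague `N(0, mu_prior_sd^2)`
#' priors on each baseline logit `mu_i` and on the overall log OR
#' `theta`; and the heterogeneity prior `prior` on tau (or tau^2). The
#' binomial terms include their binomial coefficients, so the
#' likelihood part equals a sum of `dbinom(log = TRUE)` terms. At
#' `tau = 0` the density is `-Inf` unless every `delta_i` equals
#' `theta` (a degenerate point mass; the sampler never visits it since
#' tau is updated on a positive scale).
#'
#' @param state list with elements `mu` (length k), `delta` (length k),
#'   `theta`, `tau`.
#' @param data a [meta_dataset].
#' @param prior a [prior_spec] for the heterogeneity.
#' @param mu_prior_sd,theta_prior_sd standard deviations of the vague
#'   normal priors (default 100).
#' @return the log posterior density (up to the evidence constant).
#' @export
log_posterior <- function(state, data, prior,
                          mu_prior_sd = 100, theta_prior_sd = 100) {
  k <- nrow(data)
  stopifnot(length(state$mu) == k, length(state$delta) == k,
            length(state$theta) == 1L, length(state$tau) == 1L)
  # tau <= 0 excluded by convention: the boundary carries a degenerate
  # point mass and the sampler works on a strictly positive tau scale
  if (state$tau <= 0) return(-Inf)
  pc <- stats::plogis(state$mu)
  pt <- stats::plogis(state$mu + state$delta)
  ll <- sum(stats::dbinom(data$r_c, data$n_c, pc, log = TRUE)) +
    sum(stats::dbinom(data$r_t, data$n_t, pt, log = TRUE))
  lp <- sum(stats::dnorm(state$delta, state$theta, state$tau, log = TRUE)) +
    sum(stats::dnorm(state$mu, 0, mu_prior_sd, log = TRUE)) +
    stats::dnorm(state$theta, 0, theta_prior_sd, log = TRUE) +
    prior_log_density_tau(prior, state$tau)
  ll + lp
}

# Initial state: empirical logits with a 0.5 stabilizer, jittered
# multiplicatively by +/-50% (plus small additive noise so that zero
# initial values also disperse across chains).
init_state <- function(data, jitter = TRUE) {
  pc <- (data$r_c + 0.5) / (data$n_c + 1)
  pt <- (data$r_t + 0.5) / (data$n_t + 1)
  mu <- stats::qlogis(pc)
  delta <- stats::qlogis(pt) - stats::qlogis(pc)
  delta[data$r_t + data$r_c == 0] <- 0
  theta <- mean(delta)
  tau <- 0.1
  k <- length(mu)
  if (jitter) {
    mu <- mu * stats::runif(k, 0.5, 1.5) + stats::rnorm(k, 0, 0.05)
    delta <- delta * stats::runif(k, 0.5, 1.5) + stats::rnorm(k, 0, 0.05)
    theta <- theta * stats::runif(1, 0.5, 1.5) + stats::rnorm(1, 0, 0.05)
    tau <- tau * stats::runif(1, 0.5, 1.5)
  }
  list(mu = mu, delta = delta, theta = theta, tau = tau)
}

# Conjugate Gibbs draw of theta | delta, tau under the N(0, sd^2) prior
gibbs_theta <- function(delta, tau, theta_prior_sd = 100) {
  k <- length(delta)
  prec <- k / tau^2 + 1 / theta_prior_sd^2
  stats::rnorm(1, (sum(delta) / tau^2) / prec, 1 / sqrt(prec))
}

# One full chain of the Metropolis-within-Gibbs sampler. The k
# baseline logits mu_i (and likewise the k study effects delta_i) have
# mutually independent full conditionals given the remaining blocks,
# so they are proposed and accepted component-wise in one vectorized
# sweep. theta is a conjugate Gibbs draw; tau is either a conjugate
# inverse-gamma Gibbs draw (inverse_gamma prior) or a random-walk
# Metropolis step on log(tau) with the Jacobian correction.
run_chain <- function(rt, nt, rc, nc, prior, cfg, seed,
                      use_likelihood = TRUE, tau_update = "auto",
                      mu_prior_sd = 100, theta_prior_sd = 100) {
  set.seed(seed)
  k <- length(rt)
  data0 <- list(r_t = rt, n_t = nt, r_c = rc, n_c = nc)
  st <- init_state(data0, jitter = TRUE)
  mu <- st$mu; delta <- st$delta; theta <- st$theta; tau <- st$tau

  gibbs_tau <- (tau_update == "auto" && prior$family == "inverse_gamma") ||
    tau_update == "gibbs"
  if (gibbs_tau && prior$family != "inverse_gamma")
    stop("Gibbs update for tau requires the inverse_gamma prior")

  lik <- if (use_likelihood) 1 else 0
  n_total <- cfg$burn_in + cfg$iterations
  n_keep <- cfg$iterations %/% cfg$thin
  draws <- matrix(NA_real_, n_keep, 2L + 2L * k)
  colnames(draws) <- c("theta", "tau",
                       paste0("mu_", seq_len(k)),
                       paste0("delta_", seq_len(k)))
  # adaptive proposal scales (log parameterization, Robbins-Monro
  # toward 44% acceptance, burn-in only)
  ls_mu <- rep(base::log(0.5), k)
  ls_delta <- rep(base::log(0.5), k)
  ls_tau <- base::log(0.5)
  ls_shift <- base::log(0.25)
  target <- 0.44
  acc_mu <- acc_delta <- acc_tau <- acc_shift <- 0
  n_acc <- 0L

  inv_2mu_var <- 1 / (2 * mu_prior_sd^2)
  kept <- 0L
  for (t in seq_len(n_total)) {
    s_mu <- exp(ls_mu); s_delta <- exp(ls_delta); s_tau <- exp(ls_tau)

    # --- mu sweep -------------------------------------------------
    prop <- mu + stats::rnorm(k) * s_mu
    logr <- lik * (binom_ll(prop, rc, nc) - binom_ll(mu, rc, nc) +
                   binom_ll(prop + delta, rt, nt) -
                   binom_ll(mu + delta, rt, nt)) +
      (mu^2 - prop^2) * inv_2mu_var
    acc1 <- base::log(stats::runif(k)) < logr
    mu[acc1] <- prop[acc1]

    # --- delta sweep ----------------------------------------------
    prop <- delta + stats::rnorm(k) * s_delta
    logr <- lik * (binom_ll(mu + prop, rt, nt) -
                   binom_ll(mu + delta, rt, nt)) +
      ((delta - theta)^2 - (prop - theta)^2) / (2 * tau^2)
    acc2 <- base::log(stats::runif(k)) < logr
    delta[acc2] <- prop[acc2]

    # --- theta (conjugate Gibbs) ----------------------------------
    theta <- gibbs_theta(delta, tau, theta_prior_sd)

    # --- joint translation of (theta, delta) ----------------------
    # When tau is small the deltas are glued to theta and the
    # componentwise moves above advance the common location only in
    # O(tau) steps; shifting the whole block at once restores mixing.
    # The hierarchical term delta - theta is shift-invariant, so only
    # the treatment-arm likelihood and the theta prior enter.
    eps <- stats::rnorm(1) * exp(ls_shift)
    logr <- lik * sum(binom_ll(mu + delta + eps, rt, nt) -
                      binom_ll(mu + delta, rt, nt)) +
      (theta^2 - (theta + eps)^2) / (2 * theta_prior_sd^2)
    acc4 <- is.finite(logr) && base::log(stats::runif(1)) < logr
    if (acc4) {
      theta <- theta + eps
      delta <- delta + eps
    }

    # --- tau ------------------------------------------------------
    if (gibbs_tau) {
      a <- prior$params[["alpha"]]; b <- prior$params[["beta"]]
      tau <- sqrt(1 / stats::rgamma(1, shape = a + k / 2,
                                    rate = b + 0.5 * sum((delta - theta)^2)))
      acc3 <- TRUE
    } else {
      phi <- base::log(tau)
      phi_new <- phi + stats::rnorm(1) * s_tau
      tau_new <- exp(phi_new)
      logr <- sum(stats::dnorm(delta, theta, tau_new, log = TRUE)) -
        sum(stats::dnorm(delta, theta, tau, log = TRUE)) +
        prior_log_density_tau(prior, tau_new) -
        prior_log_density_tau(prior, tau) +
        phi_new - phi  # Jacobian of the log transform
      acc3 <- is.finite(logr) && base::log(stats::runif(1)) < logr
      if (acc3) tau <- tau_new
    }

    # --- adaptation (burn-in only) --------------------------------
    if (t <= cfg$adapt_window) {
      step <- min(0.25, 1 / sqrt(t))
      ls_mu <- ls_mu + step * (as.numeric(acc1) - target)
      ls_delta <- ls_delta + step * (as.numeric(acc2) - target)
      if (!gibbs_tau) ls_tau <- ls_tau + step * (as.numeric(acc3) - target)
      ls_shift <- ls_shift + step * (as.numeric(acc4) - target)
    }

    if (t > cfg$burn_in) {
      acc_mu <- acc_mu + mean(acc1)
      acc_delta <- acc_delta + mean(acc2)
      acc_tau <- acc_tau + as.numeric(acc3)
      acc_shift <- acc_shift + as.numeric(acc4)
      n_acc <- n_acc + 1L
      if ((t - cfg$burn_in) %% cfg$thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        draws[kept, ] <- c(theta, tau, mu, delta)
      }
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       acceptance = c(mu = acc_mu / n_acc, delta = acc_delta / n_acc,
                      tau = acc_tau / n_acc, shift = acc_shift / n_acc),
       scales = list(mu = exp(ls_mu), delta = exp(ls_delta),
                     tau = exp(ls_tau)))
}

#' Fit the Bayesian random-effects model by MCMC
#'
#' Draws from the posterior of the hierarchical binomial-logit model
#' (see [log_posterior]) with an adaptive Metropolis-within-Gibbs
#' sampler: vectorized component-wise random-walk Metropolis sweeps
#' over the baseline logits `mu_i` and the study effects `delta_i`, a
#' conjugate normal Gibbs draw for `theta` followed by a joint
#' random-walk translation of `(theta, delta)` (which keeps the chain
#' mobile when tau is near zero and the block is tightly coupled), and
#' either a conjugate
#' inverse-gamma Gibbs draw for `tau^2` (inverse-gamma prior) or a
#' random-walk Metropolis step on `log(tau)` with Jacobian correction
#' (all other priors). Proposal scales adapt toward 44% acceptance
#' during the burn-in only. No continuity correction or exclusion is
#' applied: the exact binomial likelihood handles zero cells, and
#' double-zero studies contribute baseline information.
#'
#' @param data a [meta_dataset] (used as-is; see [apply_sparse_policy]
#'   with `mode = "bayesian"`).
#' @param prior a [prior_spec] for the heterogeneity.
#' @param config a [sampler_config].
#' @param use_likelihood set `FALSE` to sample from the joint prior
#'   (used by [prior_predictive_check]).
#' @param tau_update `"auto"` (Gibbs for inverse-gamma, otherwise
#'   Metropolis on log tau), `"gibbs"`, or `"mh"`.
#' @param mu_prior_sd,theta_prior_sd vague-prior standard deviations.
#' @return an object of class `posterior_result`: per-chain `draws`
#'   (matrices with columns `theta`, `tau`, `mu_1..k`, `delta_1..k`),
#'   `or_summary` and `tau_summary` (posterior median and 95% credible
#'   interval), per-chain acceptance rates, and a `diagnostics`
#'   convergence report (see [build_report]).
#' @examples
#' d <- meta_dataset(paste0("s", 1:4), r_t = c(12, 8, 15, 9),
#'                   n_t = c(100, 90, 120, 80),
#'                   r_c = c(6, 5, 8, 4), n_c = c(100, 90, 120, 80))
#' cfg <- sampler_config(chains = 2, burn_in = 500, iterations = 2000,
#'                       thin = 1, seed = 7)
#' fit <- run_mcmc(d, prior_spec("half_normal", sigma2 = 1), cfg)
#' fit$or_summary
#' @export
run_mcmc <- function(data, prior, config = sampler_config(),
                     use_likelihood = TRUE, tau_update = "auto",
                     mu_prior_sd = 100, theta_prior_sd = 100) {
  validate_meta_dataset(data)
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "sampler_config"))
  k <- nrow(data)
  st0 <- init_state(list(r_t = data$r_t, n_t = data$n_t,
                         r_c = data$r_c, n_c = data$n_c), jitter = FALSE)
  lp0 <- log_posterior(st0, data, prior,
                       mu_prior_sd = mu_prior_sd,
                       theta_prior_sd = theta_prior_sd)
  if (!is.finite(lp0))
    stop("non-finite log posterior at the initial state; check the data")
  chains <- lapply(seq_len(config$chains), function(j) {
    run_chain(data$r_t, data$n_t, data$r_c, data$n_c, prior, config,
              seed = config$seed + j - 1L,
              use_likelihood = use_likelihood, tau_update = tau_update,
              mu_prior_sd = mu_prior_sd, theta_prior_sd = theta_prior_sd)
  })
  draws <- lapply(chains, `[[`, "draws")
  theta_pool <- unlist(lapply(draws, function(m) m[, "theta"]))
  tau_pool <- unlist(lapply(draws, function(m) m[, "tau"]))
  summ <- summarize_posterior(theta_pool, tau_pool)
  res <- structure(list(draws = draws,
                        or_summary = summ$or_summary,
                        tau_summary = summ$tau_summary,
                        acceptance = lapply(chains, `[[`, "acceptance"),
                        prior = prior,
                        config = config,
                        k = k,
                        study_id = data$study_id),
                   class = "posterior_result")
  res$diagnostics <- build_report(res)
  res
}

#' Posterior summaries of the overall OR and heterogeneity SD
#'
#' The OR summary applies `exp` to the 2.5%, 50%, and 97.5% quantiles
#' of the pooled `theta` draws (quantiles commute with monotone maps,
#' so this equals summarizing `exp(theta)` directly); the tau summary
#' uses the tau draws as-is.
#'
#' @param theta_draws pooled draws of the overall log OR.
#' @param tau_draws pooled draws of the heterogeneity SD.
#' @return list of `or_summary` and `tau_summary`, each a named vector
#'   `(lower, median, upper)`.
#' @export
summarize_posterior <- function(theta_draws, tau_draws) {
  if (length(theta_draws) < 100L || length(tau_draws) < 100L)
    stop("insufficient posterior sample: need at least 100 pooled draws")
  qs <- c(0.025, 0.5, 0.975)
  orq <- exp(stats::quantile(theta_draws, qs, names = FALSE))
  tq <- stats::quantile(tau_draws, qs, names = FALSE)
  list(or_summary = c(lower = orq[1], median = orq[2], upper = orq[3]),
       tau_summary = c(lower = tq[1], median = tq[2], upper = tq[3]))
}

#' Prior-predictive check of the sampler
#'
#' Runs the full sampler with the binomial likelihood disabled on a
#' one-study placeholder dataset, so the chain targets the joint prior
#' of `(mu, delta, theta, tau)`. The marginal tau draws must then
#' reproduce the heterogeneity prior; compare against
#' [tau_quantiles].
#'
#' @param prior a [prior_spec].
#' @param config a [sampler_config].
#' @return pooled tau draws.
#' @export
prior_predictive_check <- function(prior, config = sampler_config()) {
  placeholder <- meta_dataset("placeholder", r_t = 0, n_t = 1,
                              r_c = 0, n_c = 1)
  fit <- run_mcmc(placeholder, prior, config, use_likelihood = FALSE)
  unlist(lapply(fit$draws, function(m) m[, "tau"]))
}

#' Export posterior draws as a rectangular table
#'
#' @param result a `posterior_result`.
#' @return a data.frame with columns `chain`, `iteration`, `theta`,
#'   `tau`, `mu_1..k`, `delta_1..k`, suitable for external diagnostic
#'   tools.
#' @export
draws_table <- function(result) {
  stopifnot(inherits(result, "posterior_result"))
  out <- do.call(rbind, lapply(seq_along(result$draws), function(j) {
    m <- result$draws[[j]]
    data.frame(chain = j, iteration = seq_len(nrow(m)), m,
               check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_result <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian random-effects meta-analysis, k = %d, prior %s\n",
              x$k, format(x$prior)))
  n <- sum(vapply(x$draws, nrow, integer(1)))
  cat(sprintf("  %d chains, %d retained draws\n", length(x$draws), n))
  fmt <- function(s) sprintf("%s [%s, %s]",
                             format(s[["median"]], digits = digits),
                             format(s[["lower"]], digits = digits),
                             format(s[["upper"]], digits = digits))
  if (!is.null(x$diagnostics) && x$diagnostics$verdict == "failed") {
    cat("  convergence FAILED; posterior summaries suppressed (NA)\n")
    cat("  remedies:", paste(x$diagnostics$remedies, collapse = "; "), "\n")
  } else {
    cat("  OR  (median [95% CrI]):", fmt(x$or_summary), "\n")
    cat("  tau (median [95% CrI]):", fmt(x$tau_summary), "\n")
    if (!is.null(x$diagnostics))
      cat("  convergence verdict:", x$diagnostics$verdict, "\n")
  }
  invisible(x)
}
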