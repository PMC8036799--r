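# Term-by-term reference implementation of the log posterior, written
# independently of the package's vectorized version.
naive_log_posterior <- function(state, data, prior, sd0 = 100) {
  lp <- 0
  for (i in seq_len(nrow(data))) {
    pc <- 1 / (1 + exp(-state$mu[i]))
    pt <- 1 / (1 + exp(-(state$mu[i] + state$delta[i])))
    lp <- lp + dbinom(data$r_c[i], data$n_c[i], pc, log = TRUE)
    lp <- lp + dbinom(data$r_t[i], data$n_t[i], pt, log = TRUE)
    lp <- lp + dnorm(state$delta[i], state$theta, state$tau, log = TRUE)
    lp <- lp + dnorm(state$mu[i], 0, sd0, log = TRUE)
  }
  lp <- lp + dnorm(state$theta, 0, sd0, log = TRUE)
  tau <- state$tau
  lp + switch(prior$family,
    uniform = dunif(tau, 0, prior$params[["c"]], log = TRUE),
    half_normal = log(2 * dnorm(tau, 0, sqrt(prior$params[["sigma2"]]))),
    log_normal = dlnorm(tau^2, prior$params[["mu"]],
                        prior$params[["sigma"]], log = TRUE) + log(2 * tau),
    inverse_gamma = {
      a <- prior$params[["alpha"]]; b <- prior$params[["beta"]]
      a * log(b) - lgamma(a) - (a + 1) * log(tau^2) - b / tau^2 + log(2 * tau)
    })
}

test_that("log posterior reduces to Bernoulli terms on a degenerate study", {
  d <- meta_dataset("one", r_t = 0, n_t = 1, r_c = 0, n_c = 1)
  state <- list(mu = 0, delta = 0, theta = 0, tau = 1)
  prior <- prior_spec("half_normal", sigma2 = 1)
  lp <- log_posterior(state, d, prior)
  hyper <- dnorm(0, 0, 1, log = TRUE) +          # delta | theta, tau
    dnorm(0, 0, 100, log = TRUE) * 2 +           # mu and theta priors
    log(2) + dnorm(1, 0, 1, log = TRUE)          # half-normal at tau = 1
  expect_equal(lp - hyper, 2 * log(0.5))
})

test_that("log posterior matches a naive reference on random states", {
  set.seed(55)
  d <- toy_dataset()
  priors <- list(prior_spec("uniform", c = 10),
                 prior_spec("half_normal", sigma2 = 2),
                 prior_spec("inverse_gamma", alpha = 0.1, beta = 0.1),
                 turner_prior("non_pharma", "subjective"))
  for (i in 1:20) {
    st <- list(mu = rnorm(6, -2, 1), delta = rnorm(6, 0.5, 0.5),
               theta = rnorm(1), tau = runif(1, 0.05, 2))
    pr <- priors[[1 + i %% 4]]
    expect_equal(log_posterior(st, d, pr), naive_log_posterior(st, d, pr))
  }
  # additivity over independent studies
  d2 <- meta_dataset(c("a", "b"), r_t = c(3, 7), n_t = c(20, 30),
                     r_c = c(2, 4), n_c = c(20, 30))
  st <- list(mu = c(-1, -0.5), delta = c(0.4, 0.6), theta = 0.5, tau = 0.3)
  pr <- priors[[2]]
  per_study <- sapply(1:2, function(i) {
    di <- meta_dataset(d2$study_id[i], r_t = d2$r_t[i], n_t = d2$n_t[i],
                       r_c = d2$r_c[i], n_c = d2$n_c[i])
    sti <- list(mu = st$mu[i], delta = st$delta[i], theta = st$theta,
                tau = st$tau)
    log_posterior(sti, di, pr)
  })
  shared <- dnorm(st$theta, 0, 100, log = TRUE) +
    log(2 * dnorm(st$tau, 0, sqrt(2)))
  expect_equal(log_posterior(st, d2, pr), sum(per_study) - shared)
  # tau = 0 boundary is excluded by convention
  expect_equal(log_posterior(list(mu = c(-1, -1), delta = c(0, 0),
                                  theta = 0, tau = 0), d2, pr), -Inf)
})

test_that("posterior summaries are quantile-equivariant under exp", {
  expect_equal(summarize_posterior(rep(0, 200), rep(0.2, 200))$or_summary,
               c(lower = 1, median = 1, upper = 1))
  set.seed(8)
  th <- rnorm(5e5)
  s <- summarize_posterior(th, abs(th))
  # equal up to the interpolation arithmetic of type-7 quantiles
  expect_equal(unname(s$or_summary),
               unname(quantile(exp(th), c(0.025, 0.5, 0.975))),
               tolerance = 1e-6)
  expect_equal(unname(s$or_summary[c(1, 3)]), exp(c(-1.96, 1.96)),
               tolerance = 0.02)
  expect_error(summarize_posterior(rnorm(50), rnorm(50)), "insufficient")
})

test_that("identical seed and config reproduce draws bit for bit", {
  d <- toy_dataset()
  cfg <- fast_config(chains = 2, burn_in = 200, iterations = 600, seed = 42)
  pr <- prior_spec("half_normal", sigma2 = 1)
  f1 <- run_mcmc(d, pr, cfg)
  f2 <- run_mcmc(d, pr, cfg)
  expect_identical(f1$draws, f2$draws)
  # retained draw count = chains x iterations / thin
  expect_equal(sum(sapply(f1$draws, nrow)), 2 * 600 %/% 2)
  # a different seed gives different draws
  cfg2 <- fast_config(chains = 2, burn_in = 200, iterations = 600, seed = 43)
  expect_false(identical(run_mcmc(d, pr, cfg2)$draws, f1$draws))
})

test_that("theta Gibbs step has the correct conditional moments", {
  set.seed(14)
  delta <- rnorm(7, 0.8, 0.3)
  tau <- 0.4
  draws <- replicate(2e5, binmeta:::gibbs_theta(delta, tau, 100))
  prec <- 7 / tau^2 + 1 / 100^2
  expect_lt(abs(mean(draws) - sum(delta) / tau^2 / prec),
            5 / sqrt(prec) / sqrt(2e5))
  expect_equal(var(draws), 1 / prec, tolerance = 0.02)
})

test_that("prior-predictive sampling reproduces the heterogeneity prior", {
  cfg <- fast_config(chains = 2, burn_in = 1000, iterations = 8000,
                     thin = 1, seed = 31)
  tau <- prior_predictive_check(prior_spec("uniform", c = 2), cfg)
  expect_equal(median(tau), 1, tolerance = 0.06)
  expect_true(all(tau <= 2 & tau >= 0))
})

test_that("arm swap maps the posterior of theta to its mirror image", {
  d <- toy_dataset()
  cfg <- test_config(seed = 17)
  pr <- prior_spec("half_normal", sigma2 = 1)
  fit_a <- run_mcmc(d, pr, cfg)
  fit_b <- run_mcmc(swap_arms(d), pr, cfg)
  expect_equal(log(fit_b$or_summary[["median"]]),
               -log(fit_a$or_summary[["median"]]), tolerance = 0.05)
  expect_equal(fit_b$tau_summary[["median"]], fit_a$tau_summary[["median"]],
               tolerance = 0.05)
})

test_that("double-zero studies contribute baseline information", {
  d <- toy_dataset()
  dz <- meta_dataset(c(d$study_id, "dz"),
                     r_t = c(d$r_t, 0), n_t = c(d$n_t, 60),
                     r_c = c(d$r_c, 0), n_c = c(d$n_c, 60))
  cfg <- fast_config(seed = 23)
  pr <- prior_spec("half_normal", sigma2 = 1)
  fit_a <- run_mcmc(d, pr, cfg)
  fit_b <- run_mcmc(dz, pr, cfg)
  expect_equal(fit_b$k, 7)  # retained, not excluded
  expect_true(all(is.finite(fit_b$or_summary)))
  expect_false(identical(fit_a$or_summary, fit_b$or_summary))
  # the frequentist path must drop the same study
  expect_equal(apply_sparse_policy(dz)$excluded_ids, "dz")
})

test_that("with a near-degenerate heterogeneity prior the fit is common-effect", {
  s <- sim_scenario(k = 10, theta_true = log(2), tau_true = 0,
                    baseline_mean = -1, baseline_sd = 0.3,
                    n_range = c(2000, 2000), seed = 3)
  sim <- simulate_meta(s)
  fit <- run_mcmc(sim$data, prior_spec("half_normal", sigma2 = 1e-8),
                  test_config(seed = 5))
  fe <- pool_effects(apply_sparse_policy(sim$data), 0)
  expect_equal(log(fit$or_summary[["median"]]), fe$theta_hat,
               tolerance = 0.02)
})

test_that("credible intervals tighten as total information doubles", {
  s1 <- sim_scenario(k = 8, theta_true = 0.5, tau_true = 0,
                     baseline_mean = -1, baseline_sd = 0.2,
                     n_range = c(400, 400), seed = 61)
  sim1 <- simulate_meta(s1)
  d2 <- sim1$data
  d2$n_t <- d2$n_t * 2; d2$r_t <- d2$r_t * 2
  d2$n_c <- d2$n_c * 2; d2$r_c <- d2$r_c * 2
  cfg <- test_config(seed = 19)
  pr <- prior_spec("half_normal", sigma2 = 0.1)
  w1 <- diff(log(run_mcmc(sim1$data, pr, cfg)$or_summary[c("lower", "upper")]))
  w2 <- diff(log(run_mcmc(d2, pr, cfg)$or_summary[c("lower", "upper")]))
  expect_lt(w2, w1)
})

test_that("draws export as a rectangular table", {
  d <- toy_dataset()
  cfg <- fast_config(chains = 2, burn_in = 100, iterations = 400, seed = 2)
  fit <- run_mcmc(d, prior_spec("uniform", c = 10), cfg)
  tab <- draws_table(fit)
  expect_equal(nrow(tab), 2 * 400 %/% 2)
  expect_true(all(c("chain", "iteration", "theta", "tau", "mu_1",
                    "delta_6") %in% names(tab)))
})
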