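test_that("the Turner catalogue returns the published hyper-parameters", {
  expected <- list(
    pharma_vs_placebo = list(all_cause_mortality = c(-4.06, 1.45),
                             semi_objective = c(-3.02, 1.85),
                             subjective = c(-2.13, 1.58)),
    pharma_vs_pharma = list(all_cause_mortality = c(-4.27, 1.48),
                            semi_objective = c(-3.23, 1.88),
                            subjective = c(-2.34, 1.62)),
    non_pharma = list(all_cause_mortality = c(-3.93, 1.51),
                      semi_objective = c(-2.89, 1.91),
                      subjective = c(-2.01, 1.64)))
  for (comp in names(expected)) {
    for (out in names(expected[[comp]])) {
      sp <- turner_prior(comp, out)
      expect_equal(sp$family, "log_normal")
      expect_equal(sp$target, "tau2")
      expect_equal(unname(sp$params), expected[[comp]][[out]])
    }
  }
  expect_error(turner_prior("homeopathy", "subjective"), "valid keys")
  expect_error(turner_prior("non_pharma", "objective"), "valid keys")
})

test_that("the default grid is the standard 12-prior set", {
  g <- default_prior_grid("non_pharma")
  expect_length(g, 12L)
  fams <- vapply(g, `[[`, character(1), "family")
  expect_equal(unname(table(fams)[c("inverse_gamma", "uniform",
                                    "half_normal", "log_normal")]),
               rep(3L, 4), ignore_attr = TRUE)
  expect_equal(unname(g[["IG(0.001,0.001)"]]$params), c(0.001, 0.001))
  expect_equal(unname(g[["U(0,100)"]]$params), 100)
  expect_equal(unname(g[["HN(0,2)"]]$params), 2)
  expect_equal(unname(g[["LN(-2.89,1.91)"]]$params), c(-2.89, 1.91))
})

test_that("densities match closed forms and handle support edges", {
  u <- prior_spec("uniform", c = 2)
  expect_equal(prior_density(u, 1), 0.5)
  expect_equal(prior_density(u, 3), 0)
  hn <- prior_spec("half_normal", sigma2 = 1)
  expect_equal(prior_density(hn, 0), sqrt(2 / pi))
  ln <- prior_spec("log_normal", mu = -2, sigma = 1.5)
  expect_equal(prior_density(ln, 0.1), dlnorm(0.1, -2, 1.5))
  ig <- prior_spec("inverse_gamma", alpha = 2, beta = 3)
  expect_equal(prior_density(ig, 1.5),
               3^2 / gamma(2) * 1.5^(-3) * exp(-3 / 1.5))
  expect_equal(prior_density(ig, 0), 0)
  expect_error(prior_density(ig, -1), "negative")
  expect_error(prior_spec("uniform", c = -1), "strictly positive")
})

test_that("every default-grid density integrates to one", {
  # quadrature on u = log(x): g(u) = f(e^u) e^u, evaluated entirely in
  # log space so the heavy tails (IG with tiny shape is nearly flat on
  # log tau^2 far beyond double range) are integrable
  for (sp in default_prior_grid("pharma_vs_placebo")) {
    g <- function(u) exp(prior_density(sp, u, log = TRUE, log_x = TRUE) + u)
    upper <- if (sp$family == "uniform") log(sp$params[["c"]]) else Inf
    total <- integrate(g, -Inf, upper, rel.tol = 1e-9,
                       subdivisions = 2000L)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("log-scale density evaluation agrees with the direct path", {
  sps <- list(prior_spec("inverse_gamma", alpha = 0.1, beta = 0.1),
              prior_spec("uniform", c = 10),
              prior_spec("half_normal", sigma2 = 2),
              prior_spec("log_normal", mu = -3, sigma = 1.9))
  x <- c(1e-8, 0.03, 1, 4.7, 90)
  for (sp in sps)
    expect_equal(prior_density(sp, log(x), log_x = TRUE),
                 prior_density(sp, x))
})

test_that("sampling is reproducible and matches closed-form quantiles", {
  sp <- prior_spec("half_normal", sigma2 = 2)
  expect_identical(prior_sample(sp, 10, seed = 4),
                   prior_sample(sp, 10, seed = 4))

  n <- 2e5
  # folded-normal mean: sqrt(2 * sigma2 / pi)
  x <- prior_sample(sp, n, seed = 11)
  expect_equal(mean(x), sqrt(2 * 2 / pi), tolerance = 4 * sd(x) / sqrt(n))

  # log-normal tau2 median = exp(mu)
  ln <- prior_spec("log_normal", mu = -4.06, sigma = 1.45)
  x <- prior_sample(ln, n, seed = 12)
  expect_equal(log(median(x)), -4.06, tolerance = 0.02)

  un <- prior_spec("uniform", c = 100)
  x <- prior_sample(un, n, seed = 13)
  expect_true(min(x) >= 0 && max(x) <= 100)
})

test_that("tau quantiles use the monotone square-root transform", {
  expect_equal(tau_quantiles(prior_spec("uniform", c = 2), 0.5), 1)
  expect_equal(tau_quantiles(prior_spec("log_normal", mu = -2.13,
                                        sigma = 1.58), 0.5),
               exp(-2.13 / 2))
  hn <- prior_spec("half_normal", sigma2 = 1)
  expect_equal(tau_quantiles(hn, 0.975), qnorm(0.9875), tolerance = 1e-10)

  # inverse-gamma tau median against Monte Carlo
  ig <- prior_spec("inverse_gamma", alpha = 0.5, beta = 0.5)
  mc <- sqrt(median(prior_sample(ig, 5e5, seed = 21)))
  expect_equal(tau_quantiles(ig, 0.5), mc, tolerance = 0.02)

  expect_error(tau_quantiles(hn, c(0, 0.5)), "strictly")
})

test_that("sampled quantiles converge to closed-form quantiles for all 12 priors", {
  n <- 1e5
  probs <- c(0.25, 0.5, 0.75)
  grid <- default_prior_grid("pharma_vs_pharma")
  for (i in seq_along(grid)) {
    sp <- grid[[i]]
    x <- prior_sample(sp, n, seed = 100 + i)
    tau_draws <- if (sp$target == "tau2") sqrt(x) else x
    q_mc <- quantile(tau_draws, probs, names = FALSE)
    q_cf <- tau_quantiles(sp, probs)
    # delta-method Monte-Carlo error on the log-quantile scale
    dens_tau <- function(t) {
      if (sp$target == "tau2") 2 * t * prior_density(sp, t^2)
      else prior_density(sp, t)
    }
    for (j in seq_along(probs)) {
      # quantiles beyond double-precision range (far IG tails) cannot
      # be compared numerically
      if (!is.finite(q_cf[j]) || !is.finite(q_mc[j])) next
      se_log <- sqrt(probs[j] * (1 - probs[j]) / n) /
        (dens_tau(q_cf[j]) * q_cf[j])
      expect_lt(abs(log(q_mc[j]) - log(q_cf[j])), 4 * se_log + 1e-12)
    }
  }
})
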