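# Shared fixtures and oracles, built in code at test time.

# short sampler config for tests (default full-length settings are far
# larger than needed to check correctness properties)
fast_config <- function(chains = 2, burn_in = 1000, iterations = 6000,
                        thin = 2, seed = 1) {
  sampler_config(chains = chains, burn_in = burn_in,
                 iterations = iterations, thin = thin, seed = seed)
}

test_config <- function(seed = 1) {
  sampler_config(chains = 3, burn_in = 2000, iterations = 10000,
                 thin = 2, seed = seed)
}

# a small well-behaved dataset
toy_dataset <- function() {
  meta_dataset(paste0("s", 1:6),
               r_t = c(12, 8, 15, 9, 20, 11),
               n_t = c(100, 90, 120, 80, 150, 95),
               r_c = c(6, 5, 8, 4, 12, 6),
               n_c = c(100, 90, 120, 80, 150, 95))
}

# swap treatment and control arms of every study
swap_arms <- function(data) {
  meta_dataset(data$study_id, r_t = data$r_c, n_t = data$n_c,
               r_c = data$r_t, n_c = data$n_t)
}

# Independent straight-from-formula DerSimonian-Laird oracle, written
# as an explicit loop so it shares no code path with dl_tau2().
dl_oracle <- function(y, v) {
  k <- length(y)
  w <- numeric(k); for (i in 1:k) w[i] <- 1 / v[i]
  ybar <- 0; for (i in 1:k) ybar <- ybar + w[i] * y[i]
  ybar <- ybar / sum(w)
  Q <- 0; for (i in 1:k) Q <- Q + w[i] * (y[i] - ybar)^2
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / denom)
}

# Dense grid-search oracle for the (restricted) marginal likelihood
# maximizer over tau2.
grid_tau2_oracle <- function(y, v, restricted, upper = 5, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  V <- outer(grid, v, "+")      # length(grid) x k
  W <- 1 / V
  theta <- as.vector((W %*% y) / rowSums(W))
  R <- sweep(matrix(y, length(grid), length(y), byrow = TRUE), 1, theta)
  ll <- -0.5 * rowSums(log(V)) - 0.5 * rowSums(W * R^2)
  if (restricted) ll <- ll - 0.5 * log(rowSums(W))
  grid[which.max(ll)]
}

# pooled draws of one parameter across chains
pooled_draws <- function(fit, param) {
  unlist(lapply(fit$draws, function(m) m[, param]))
}
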