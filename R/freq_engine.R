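#' DerSimonian-Laird moment estimator of the heterogeneity variance
#'
#' Computes Cochran's Q with fixed-effect weights `w = 1/v` and returns
#' the truncated moment estimate
#' `max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' @param effects an [effect_estimates] with at least two studies.
#' @return the tau^2 estimate, with attribute `Q` carrying Cochran's Q.
#' @export
dl_tau2 <- function(effects) {
  y <- effects$y; v <- effects$v
  k <- length(y)
  if (k < 2L) stop("heterogeneity not estimable from one study")
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  t2 <- max(0, (Q - (k - 1)) / denom)
  attr(t2, "Q") <- Q
  t2
}

# Marginal (restricted) log-likelihood of the normal-normal model
# y_i ~ N(theta, v_i + tau2), profiled over theta.
marginal_loglik <- function(tau2, y, v, restricted = FALSE) {
  wi <- 1 / (v + tau2)
  theta <- sum(wi * y) / sum(wi)
  ll <- -0.5 * sum(base::log(v + tau2)) - 0.5 * sum(wi * (y - theta)^2)
  if (restricted) ll <- ll - 0.5 * base::log(sum(wi))
  ll
}

#' Maximum-likelihood and REML estimators of the heterogeneity variance
#'
#' Maximizes the marginal normal-normal log-likelihood of
#' `y_i ~ N(theta, v_i + tau^2)` (profiled over theta; with the REML
#' adjustment `-log(sum(1/(v_i + tau^2)))/2` when `restricted = TRUE`)
#' over `tau^2` in `[0, tau2_max]` by bounded scalar optimization. The
#' boundary value 0 is always considered, so the estimate is truncated
#' at zero.
#'
#' @param effects an [effect_estimates] with at least two studies.
#' @param restricted logical; REML (`TRUE`) or ML (`FALSE`).
#' @param tau2_max upper bound of the search interval (default 100).
#' @param tol relative convergence tolerance of the optimizer.
#' @return the tau^2 estimate.
#' @export
ml_reml_tau2 <- function(effects, restricted = FALSE, tau2_max = 100,
                         tol = 1e-10) {
  y <- effects$y; v <- effects$v
  if (length(y) < 2L) stop("heterogeneity not estimable from one study")
  opt <- stats::optimize(marginal_loglik, c(0, tau2_max), y = y, v = v,
                         restricted = restricted, maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective))
    stop("likelihood maximization failed: non-finite objective at tau2 = ",
         opt$maximum)
  # optimize never evaluates exactly at the interval ends; take the
  # boundary when it beats the interior optimum
  if (marginal_loglik(0, y, v, restricted) >= opt$objective) 0
  else opt$maximum
}

#' Inverse-variance pooled effect under a given heterogeneity variance
#'
#' Random-effects pooling with weights `w* = 1/(v_i + tau^2)`:
#' `theta_hat = sum(w* y) / sum(w*)` with the Wald interval
#' `theta_hat +/- z_(1-level)/2 / sqrt(sum(w*))`.
#'
#' @param effects an [effect_estimates].
#' @param tau2 heterogeneity variance (>= 0).
#' @param level confidence level (default 0.95).
#' @return list with `theta_hat`, `ci` (length-2), and `se`.
#' @export
pool_effects <- function(effects, tau2, level = 0.95) {
  if (tau2 < 0) stop("tau2 must be non-negative")
  w <- 1 / (effects$v + tau2)
  theta <- sum(w * effects$y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(theta_hat = theta, ci = c(theta - z * se, theta + z * se), se = se)
}

# Generalized Q statistic at a trial heterogeneity variance.
q_gen <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  theta <- sum(w * y) / sum(w)
  sum(w * (y - theta)^2)
}

#' Q-profile confidence interval for the heterogeneity SD
#'
#' Inverts the generalized Cochran statistic
#' `Q_gen(tau^2) = sum((y_i - theta_hat(tau^2))^2 / (v_i + tau^2))`
#' against chi-square quantiles with `k - 1` degrees of freedom:
#' the bounds solve `Q_gen = qchisq(1 - alpha/2)` (lower) and
#' `Q_gen = qchisq(alpha/2)` (upper). `Q_gen` is decreasing in tau^2,
#' so each root is unique; a bound whose equation has no root in
#' `[0, Inf)` is truncated to 0. Roots are bracketed by geometric
#' expansion from `[0, 1]` and solved to absolute tolerance 1e-8 on
#' tau^2. The interval is returned on the tau scale.
#'
#' @param effects an [effect_estimates] with at least two studies.
#' @param level coverage (default 0.95).
#' @return length-2 numeric, the interval for tau.
#' @export
q_profile_ci <- function(effects, level = 0.95) {
  y <- effects$y; v <- effects$v
  k <- length(y)
  if (k < 2L) stop("heterogeneity not estimable from one study")
  alpha <- 1 - level
  solve_bound <- function(target) {
    f <- function(t2) q_gen(t2, y, v) - target
    if (f(0) <= 0) return(0)  # Q_gen(0) already below target: truncate
    upper <- 1
    tries <- 0L
    while (f(upper) > 0) {
      upper <- upper * 4
      tries <- tries + 1L
      if (tries > 60L)
        stop("Q-profile root bracketing failed: Q_gen still above ",
             signif(target, 4), " at tau2 = ", upper)
    }
    stats::uniroot(f, c(0, upper), tol = 1e-8)$root
  }
  lo2 <- solve_bound(stats::qchisq(1 - alpha / 2, df = k - 1))
  hi2 <- solve_bound(stats::qchisq(alpha / 2, df = k - 1))
  sqrt(c(lo2, hi2))
}

#' Frequentist random-effects meta-analysis of the log odds ratio
#'
#' Convenience wrapper: estimates tau^2 by the requested method
#' (DerSimonian-Laird moment estimator, maximum likelihood, or REML),
#' pools the per-study log ORs by inverse-variance weighting, and
#' attaches the Q-profile interval for tau.
#'
#' @param effects an [effect_estimates] (see [apply_sparse_policy]).
#' @param method `"DL"`, `"ML"`, or `"REML"`.
#' @param level confidence level for both intervals.
#' @return an object of class `freq_result` with fields `method`,
#'   `tau2_hat`, `tau_ci`, `theta_hat`, `theta_ci`, `Q`, `k_used`.
#' @examples
#' eff <- effect_estimates(y = c(0.1, 0.5, 0.3), v = c(0.04, 0.05, 0.06))
#' freq_meta(eff, method = "REML")
#' @export
freq_meta <- function(effects, method = c("DL", "ML", "REML"),
                      level = 0.95) {
  method <- match.arg(method)
  t2 <- switch(method,
    DL = dl_tau2(effects),
    ML = ml_reml_tau2(effects, restricted = FALSE),
    REML = ml_reml_tau2(effects, restricted = TRUE))
  dl <- dl_tau2(effects)  # Q is defined with fixed-effect weights
  pooled <- pool_effects(effects, t2, level = level)
  structure(list(method = method,
                 tau2_hat = as.numeric(t2),
                 tau_ci = q_profile_ci(effects, level = level),
                 theta_hat = pooled$theta_hat,
                 theta_ci = pooled$ci,
                 Q = attr(dl, "Q"),
                 k_used = effects$k_used,
                 level = level),
            class = "freq_result")
}

#' @export
print.freq_result <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), k = %d\n",
              x$method, x$k_used))
  cat(sprintf("  OR   %s  %g%% CI [%s, %s]\n",
              format(exp(x$theta_hat), digits = digits), 100 * x$level,
              format(exp(x$theta_ci[1]), digits = digits),
              format(exp(x$theta_ci[2]), digits = digits)))
  cat(sprintf("  tau  %s  %g%% CI [%s, %s]   (Q = %s)\n",
              format(sqrt(x$tau2_hat), digits = digits), 100 * x$level,
              format(x$tau_ci[1], digits = digits),
              format(x$tau_ci[2], digits = digits),
              format(x$Q, digits = digits)))
  invisible(x)
}
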