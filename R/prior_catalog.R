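#' Specify a prior for the between-studies heterogeneity
#'
#' Four families are supported, each acting on the scale conventional
#' for it:
#' \describe{
#'   \item{`inverse_gamma`}{IG(`alpha`, `beta`) on the variance tau^2
#'     (shape `alpha`, scale `beta`; density proportional to
#'     `x^(-alpha-1) exp(-beta/x)`).}
#'   \item{`uniform`}{U(0, `c`) on the standard deviation tau.}
#'   \item{`half_normal`}{HN(0, `sigma2`) on tau: the absolute value of
#'     a N(0, `sigma2`) variate (`sigma2` is the variance of the
#'     underlying normal).}
#'   \item{`log_normal`}{LN(`mu`, `sigma`^2) on tau^2, i.e.
#'     `log(tau^2) ~ N(mu, sigma^2)`; the evidence-based informative
#'     family (see [turner_prior]). `sigma` is the standard deviation.}
#' }
#'
#' @param family one of `"inverse_gamma"`, `"uniform"`, `"half_normal"`,
#'   `"log_normal"`.
#' @param alpha,beta inverse-gamma shape and scale.
#' @param c uniform upper bound.
#' @param sigma2 half-normal variance.
#' @param mu,sigma log-normal location and standard deviation of
#'   `log(tau^2)`.
#' @return an object of class `prior_spec` with fields `family`,
#'   `params`, and `target` (`"tau"` or `"tau2"`).
#' @examples
#' prior_spec("half_normal", sigma2 = 1)
#' prior_spec("inverse_gamma", alpha = 0.001, beta = 0.001)
#' @export
prior_spec <- function(family = c("inverse_gamma", "uniform",
                                  "half_normal", "log_normal"),
                       alpha = NULL, beta = NULL, c = NULL,
                       sigma2 = NULL, mu = NULL, sigma = NULL) {
  family <- match.arg(family)
  pos <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop("hyper-parameter '", nm, "' must be strictly positive for the ",
           family, " prior")
    as.numeric(x)
  }
  spec <- switch(family,
    inverse_gamma = list(family = family,
                         params = c(alpha = pos(alpha, "alpha"),
                                    beta = pos(beta, "beta")),
                         target = "tau2"),
    uniform = list(family = family,
                   params = c(c = pos(c, "c")),
                   target = "tau"),
    half_normal = list(family = family,
                       params = c(sigma2 = pos(sigma2, "sigma2")),
                       target = "tau"),
    log_normal = {
      if (is.null(mu) || !is.finite(mu))
        stop("hyper-parameter 'mu' must be a finite number for the ",
             "log_normal prior")
      list(family = family,
           params = c(mu = as.numeric(mu), sigma = pos(sigma, "sigma")),
           target = "tau2")
    })
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(format(x), "on", if (x$target == "tau2") "tau^2" else "tau", "\n")
  invisible(x)
}

#' @export
format.prior_spec <- function(x, ...) {
  p <- x$params
  switch(x$family,
    inverse_gamma = sprintf("IG(%g, %g)", p[["alpha"]], p[["beta"]]),
    uniform       = sprintf("U(0, %g)", p[["c"]]),
    half_normal   = sprintf("HN(0, %g)", p[["sigma2"]]),
    log_normal    = sprintf("LN(%g, %g^2)", p[["mu"]], p[["sigma"]]))
}

# Turner et al. catalogue of log-normal hyper-parameters for tau^2,
# indexed by treatment-comparison type and outcome type.
.turner_table <- list(
  pharma_vs_placebo = list(
    all_cause_mortality = c(mu = -4.06, sigma = 1.45),
    semi_objective      = c(mu = -3.02, sigma = 1.85),
    subjective          = c(mu = -2.13, sigma = 1.58)),
  pharma_vs_pharma = list(
    all_cause_mortality = c(mu = -4.27, sigma = 1.48),
    semi_objective      = c(mu = -3.23, sigma = 1.88),
    subjective          = c(mu = -2.34, sigma = 1.62)),
  non_pharma = list(
    all_cause_mortality = c(mu = -3.93, sigma = 1.51),
    semi_objective      = c(mu = -2.89, sigma = 1.91),
    subjective          = c(mu = -2.01, sigma = 1.64)))

#' Evidence-based log-normal heterogeneity prior (Turner catalogue)
#'
#' Returns the informative log-normal prior for tau^2 whose
#' hyper-parameters were derived by Turner and colleagues from a large
#' corpus of Cochrane meta-analyses, indexed by the type of treatment
#' comparison and of outcome.
#'
#' @param comparison `"pharma_vs_placebo"`, `"pharma_vs_pharma"`, or
#'   `"non_pharma"`.
#' @param outcome `"all_cause_mortality"`, `"semi_objective"`, or
#'   `"subjective"`.
#' @return a [prior_spec] of family `log_normal`.
#' @examples
#' turner_prior("pharma_vs_placebo", "subjective")  # LN(-2.13, 1.58^2)
#' @export
turner_prior <- function(comparison, outcome) {
  comps <- names(.turner_table)
  outs <- names(.turner_table[[1L]])
  if (!is.character(comparison) || length(comparison) != 1L ||
      !(comparison %in% comps))
    stop("unknown comparison '", paste(comparison, collapse = ","),
         "'; valid keys: ", paste(comps, collapse = ", "))
  if (!is.character(outcome) || length(outcome) != 1L ||
      !(outcome %in% outs))
    stop("unknown outcome '", paste(outcome, collapse = ","),
         "'; valid keys: ", paste(outs, collapse = ", "))
  hp <- .turner_table[[comparison]][[outcome]]
  prior_spec("log_normal", mu = hp[["mu"]], sigma = hp[["sigma"]])
}

#' Default 12-prior sensitivity grid
#'
#' The standard sensitivity-analysis grid: three inverse-gamma priors
#' IG(0.001, 0.001), IG(0.01, 0.01), IG(0.1, 0.1) on tau^2; three
#' uniform priors U(0, 2), U(0, 10), U(0, 100) on tau; three
#' half-normal priors HN(0, 0.1), HN(0, 1), HN(0, 2) on tau; and the
#' three Turner log-normal priors (one per outcome type) for the given
#' treatment-comparison type.
#'
#' @param comparison treatment-comparison key passed to [turner_prior].
#' @return a named list of 12 [prior_spec] objects.
#' @export
default_prior_grid <- function(comparison = c("pharma_vs_placebo",
                                              "pharma_vs_pharma",
                                              "non_pharma")) {
  comparison <- match.arg(comparison)
  g <- list()
  for (ab in c(0.001, 0.01, 0.1))
    g[[sprintf("IG(%g,%g)", ab, ab)]] <-
      prior_spec("inverse_gamma", alpha = ab, beta = ab)
  for (cc in c(2, 10, 100))
    g[[sprintf("U(0,%g)", cc)]] <- prior_spec("uniform", c = cc)
  for (s2 in c(0.1, 1, 2))
    g[[sprintf("HN(0,%g)", s2)]] <- prior_spec("half_normal", sigma2 = s2)
  for (out in c("all_cause_mortality", "semi_objective", "subjective")) {
    sp <- turner_prior(comparison, out)
    g[[sprintf("LN(%g,%g)", sp$params[["mu"]], sp$params[["sigma"]])]] <- sp
  }
  g
}

#' Prior density on the family's target scale
#'
#' Evaluates the density of a heterogeneity prior at points on its
#' declared target scale (tau^2 for inverse-gamma and log-normal, tau
#' for uniform and half-normal). Zero outside the support. With
#' `log_x = TRUE` the points are supplied as `log(x)` and all
#' arithmetic stays on the log scale, which is the only way to reach
#' the far tails of the heavy-tailed members (an IG prior with shape
#' near zero is close to flat on `log(tau^2)` and carries substantial
#' mass beyond the double-precision range).
#'
#' @param spec a [prior_spec].
#' @param x non-negative evaluation points (or their logarithms when
#'   `log_x = TRUE`).
#' @param log return the log density.
#' @param log_x interpret `x` as `log` of the evaluation points.
#' @return density values (or log densities) at `x`.
#' @export
prior_density <- function(spec, x, log = FALSE, log_x = FALSE) {
  stopifnot(inherits(spec, "prior_spec"))
  if (!log_x && any(x < 0))
    stop("density requested at negative value; the ",
         "heterogeneity scale is non-negative")
  p <- spec$params
  lx <- if (log_x) x else base::log(x)  # log(0) = -Inf handled per family
  ld <- switch(spec$family,
    inverse_gamma = {
      a <- p[["alpha"]]; b <- p[["beta"]]
      ifelse(is.finite(lx),
             a * base::log(b) - lgamma(a) - (a + 1) * lx - b * exp(-lx),
             -Inf)
    },
    uniform = ifelse(lx <= base::log(p[["c"]]), -base::log(p[["c"]]), -Inf),
    half_normal = base::log(2) - 0.5 * base::log(2 * pi * p[["sigma2"]]) -
      exp(2 * lx) / (2 * p[["sigma2"]]),
    log_normal = ifelse(is.finite(lx),
                        -lx - base::log(p[["sigma"]]) -
                          0.5 * base::log(2 * pi) -
                          (lx - p[["mu"]])^2 / (2 * p[["sigma"]]^2),
                        -Inf))
  if (log) ld else exp(ld)
}

# Log prior density of tau (standard-deviation scale) for any family.
# Families declared on tau^2 are transformed with the Jacobian 2*tau.
prior_log_density_tau <- function(spec, tau) {
  if (spec$target == "tau") {
    prior_density(spec, tau, log = TRUE)
  } else {
    ifelse(tau > 0,
           prior_density(spec, tau^2, log = TRUE) + base::log(2 * tau),
           -Inf)
  }
}

#' Draw random samples from a heterogeneity prior
#'
#' @param spec a [prior_spec].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return `n` i.i.d. draws on the family's target scale.
#' @export
prior_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$params
  switch(spec$family,
    inverse_gamma = 1 / stats::rgamma(n, shape = p[["alpha"]],
                                      rate = p[["beta"]]),
    uniform = stats::runif(n, 0, p[["c"]]),
    half_normal = abs(stats::rnorm(n, 0, sqrt(p[["sigma2"]]))),
    log_normal = stats::rlnorm(n, p[["mu"]], p[["sigma"]]))
}

#' Prior quantiles on the tau (standard deviation) scale
#'
#' Closed-form quantiles of the heterogeneity standard deviation tau
#' under any of the four families. For families declared on tau^2 the
#' quantiles are mapped through the monotone square root.
#'
#' @param spec a [prior_spec].
#' @param probs probabilities in (0, 1).
#' @return quantiles of tau at `probs`.
#' @examples
#' tau_quantiles(prior_spec("uniform", c = 2), 0.5)  # 1
#' @export
tau_quantiles <- function(spec, probs) {
  stopifnot(inherits(spec, "prior_spec"))
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  p <- spec$params
  q_target <- switch(spec$family,
    # if X ~ IG(a, b) then P(X <= x) = 1 - pgamma(1/x, a, rate = b)
    inverse_gamma = 1 / stats::qgamma(1 - probs, shape = p[["alpha"]],
                                      rate = p[["beta"]]),
    uniform = stats::qunif(probs, 0, p[["c"]]),
    half_normal = sqrt(p[["sigma2"]]) * stats::qnorm((1 + probs) / 2),
    log_normal = stats::qlnorm(probs, p[["mu"]], p[["sigma"]]))
  if (spec$target == "tau2") sqrt(q_target) else q_target
}
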