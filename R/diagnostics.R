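# Rank-normalize pooled draws: ranks mapped through the normal
# quantile function (Blom offsets), preserving the chain layout.
rank_normalize <- function(mat) {
  z <- stats::qnorm((rank(mat) - 3 / 8) / (length(mat) + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

# Split each column (chain) of an n x m draw matrix into halves,
# giving an (n/2) x 2m matrix.
split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  mat <- mat[seq_len(2L * half), , drop = FALSE]
  do.call(cbind, lapply(seq_len(ncol(mat)), function(j)
    cbind(mat[seq_len(half), j], mat[half + seq_len(half), j])))
}

# Classic potential-scale-reduction on an n x m matrix of chains.
rhat_from_matrix <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  means <- colMeans(mat)
  vars <- apply(mat, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (W == 0) {
    if (B == 0) return(1)
    return(Inf)
  }
  sqrt(var_plus / W)
}

# Effective sample size from split chains via Geyer's initial monotone
# positive sequence on the combined autocorrelations.
ess_from_matrix <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  vars <- apply(mat, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(mat))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(0)
  lag_max <- min(n - 2L, 2000L)
  # per-chain autocovariances (biased, as in standard ESS estimators)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(mat[, j], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(lag_max + 1L))
  acov <- rowMeans(acov)
  # rho[t] for lags 0..lag_max, with the between-chain correction
  rho <- c(1, 1 - (W - acov[-1L]) / var_plus)
  # Geyer initial monotone positive sequence over adjacent pairs
  # P_t = rho[2t] + rho[2t+1], t = 0, 1, ...
  max_pairs <- length(rho) %/% 2L
  p_sum <- rho[2 * seq_len(max_pairs) - 1L] + rho[2 * seq_len(max_pairs)]
  acc <- 0
  run_min <- Inf
  for (i in seq_len(max_pairs)) {
    if (!is.finite(p_sum[i]) || p_sum[i] <= 0) break
    run_min <- min(run_min, p_sum[i])
    acc <- acc + run_min
  }
  tau_int <- max(-1 + 2 * acc, 1 / (n * m))
  ess <- n * m / tau_int
  min(ess, n * m)
}

#' Split R-hat and effective sample size per parameter
#'
#' Computes the rank-normalized split potential-scale-reduction
#' statistic and an autocorrelation-based effective sample size for
#' each scalar parameter, from per-chain draws. Chains are split in
#' half (so within-chain drift registers as apparent between-chain
#' variance) and rank-normalized before the variance comparison, which
#' makes the statistic robust to heavy tails. Two chains stuck at
#' distinct constants give `Rhat = Inf`.
#'
#' @param draws a list of per-chain draw matrices with identical column
#'   names (as in `posterior_result$draws`), or a list of numeric
#'   vectors for a single parameter.
#' @param params optional character vector of columns to assess.
#' @return a data.frame with columns `param`, `rhat`, `ess`.
#' @export
compute_rhat_ess <- function(draws, params = NULL) {
  if (!is.list(draws) || length(draws) < 2L)
    stop(">=2 chains required for R-hat")
  if (is.numeric(draws[[1L]]) && is.null(dim(draws[[1L]])))
    draws <- lapply(draws, function(x) matrix(x, ncol = 1L,
                                              dimnames = list(NULL, "x")))
  n <- min(vapply(draws, nrow, integer(1)))
  if (n < 100L) stop("need at least 100 draws per chain")
  if (is.null(params)) params <- colnames(draws[[1L]])
  out <- lapply(params, function(p) {
    mat <- vapply(draws, function(m) m[seq_len(n), p], numeric(n))
    sm <- split_chains(mat)
    z <- rank_normalize(sm)
    data.frame(param = p,
               rhat = rhat_from_matrix(z),
               ess = ess_from_matrix(sm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect multimodality of a posterior sample
#'
#' Counts modes of a Gaussian kernel density estimate whose topographic
#' prominence (height above the deepest separating valley toward any
#' taller retained mode) exceeds `prominence` times the maximum
#' density. A count of 2 or more flags possible non-convergence or
#' subgroup structure.
#'
#' @param x pooled draws (>= 500).
#' @param prominence relative prominence threshold in (0, 1).
#' @return list with `flag` (logical) and `modes` (integer count).
#' @export
detect_multimodality <- function(x, prominence = 0.1) {
  if (length(x) < 500L) stop("need at least 500 draws")
  if (stats::sd(x) == 0) return(list(flag = FALSE, modes = 1L))
  d <- stats::density(x, n = 512)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) <= 1L) return(list(flag = FALSE, modes = max(1L, length(peaks))))
  ord <- peaks[order(y[peaks], decreasing = TRUE)]
  accepted <- ord[1L]
  ymax <- y[ord[1L]]
  for (p in ord[-1L]) {
    # deepest valley between p and each accepted peak; the candidate's
    # prominence is its height above the *highest* of those valley floors
    valleys <- vapply(accepted, function(a)
      min(y[seq(min(a, p), max(a, p))]), numeric(1))
    prom <- y[p] - max(valleys)
    if (prom >= prominence * ymax) accepted <- c(accepted, p)
  }
  modes <- length(accepted)
  list(flag = modes >= 2L, modes = as.integer(modes))
}

#' Default convergence thresholds
#'
#' `rhat_max`/`ess_min` define "converged"; a run is "failed" when any
#' monitored R-hat exceeds `rhat_fail`, any ESS falls below
#' `ess_fail`, or the pooled overall-effect draws look multimodal;
#' anything between is "suspect". All values are package defaults, not
#' universal constants, and can be overridden.
#'
#' @param rhat_max,ess_min thresholds for the converged verdict.
#' @param rhat_fail,ess_fail thresholds for the failed verdict.
#' @param prominence multimodality prominence (see
#'   [detect_multimodality]).
#' @return a named list of thresholds.
#' @export
diagnostic_thresholds <- function(rhat_max = 1.05, ess_min = 400,
                                  rhat_fail = 1.2, ess_fail = 100,
                                  prominence = 0.1) {
  list(rhat_max = rhat_max, ess_min = ess_min,
       rhat_fail = rhat_fail, ess_fail = ess_fail,
       prominence = prominence)
}

#' Build a convergence report for a posterior fit
#'
#' Assesses the two scientifically central parameters, the overall log
#' OR `theta` and the heterogeneity SD `tau`: split R-hat and ESS for
#' both, plus a kernel-density multimodality check on the pooled
#' `theta` draws. Verdicts: `converged` when all R-hat are at most
#' `rhat_max`, all ESS at least `ess_min`, and `theta` is unimodal;
#' `failed` when any R-hat exceeds `rhat_fail` (or is non-finite), any
#' ESS falls below `ess_fail`, or `theta` is multimodal; `suspect`
#' otherwise. A failed verdict carries remedies in order of priority,
#' and downstream reports suppress the posterior summaries as NA.
#'
#' @param result a `posterior_result` (or a list with a `draws` element
#'   of per-chain matrices containing `theta` and `tau` columns).
#' @param thresholds see [diagnostic_thresholds].
#' @return an object of class `convergence_report` with fields `rhat`,
#'   `ess`, `multimodal_flags`, `verdict`, `remedies`.
#' @export
build_report <- function(result, thresholds = diagnostic_thresholds()) {
  draws <- result$draws
  if (length(draws) < 2L) stop(">=2 chains required for R-hat")
  re <- compute_rhat_ess(draws, params = c("theta", "tau"))
  theta_pool <- unlist(lapply(draws, function(m) m[, "theta"]))
  mm <- if (length(theta_pool) >= 500L)
    detect_multimodality(theta_pool, prominence = thresholds$prominence)
  else list(flag = FALSE, modes = NA_integer_)  # too few draws to judge
  rhat <- stats::setNames(re$rhat, re$param)
  ess <- stats::setNames(re$ess, re$param)
  bad_rhat <- !all(is.finite(rhat)) || any(rhat > thresholds$rhat_fail)
  bad_ess <- any(ess < thresholds$ess_fail)
  ok <- all(is.finite(rhat)) && all(rhat <= thresholds$rhat_max) &&
    all(ess >= thresholds$ess_min) && !mm$flag
  verdict <- if (ok) "converged"
  else if (bad_rhat || bad_ess || mm$flag) "failed"
  else "suspect"
  remedies <- character()
  if (verdict != "converged") {
    remedies <- c("increase burn-in and sampling iterations",
                  "re-examine the heterogeneity prior (consider a more informative choice)")
    if (mm$flag)
      remedies <- c(remedies,
                    "multimodal posterior: consider separate subgroup meta-analyses")
    if (verdict == "failed")
      remedies <- c(remedies,
                    "treat results as unreliable; report summaries as NA")
  }
  structure(list(rhat = rhat, ess = ess,
                 multimodal_flags = c(theta = mm$flag),
                 modes = mm$modes,
                 verdict = verdict, remedies = remedies,
                 thresholds = thresholds),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("MCMC convergence report\n")
  for (p in names(x$rhat))
    cat(sprintf("  %-6s Rhat = %.3f  ESS = %.0f\n", p, x$rhat[[p]],
                x$ess[[p]]))
  cat("  theta multimodal:", x$multimodal_flags[["theta"]],
      sprintf("(%d mode%s)\n", x$modes, if (x$modes == 1L) "" else "s"))
  cat("  verdict:", x$verdict, "\n")
  if (length(x$remedies) > 0L)
    cat("  remedies:\n", paste0("   - ", x$remedies, collapse = "\n"), "\n")
  invisible(x)
}

#' Trace- and density-plot data export
#'
#' Returns the plain tables behind the standard visual diagnostics:
#' one long table of (iteration, chain, value) per parameter for trace
#' plots, and a kernel-density grid for density plots.
#'
#' @param result a `posterior_result`.
#' @param param parameter name (default `"theta"`).
#' @return list with `trace` and `density` data.frames.
#' @export
plot_data <- function(result, param = "theta") {
  draws <- result$draws
  trace <- do.call(rbind, lapply(seq_along(draws), function(j)
    data.frame(iteration = seq_len(nrow(draws[[j]])), chain = j,
               value = draws[[j]][, param])))
  pooled <- unlist(lapply(draws, function(m) m[, param]))
  d <- stats::density(pooled, n = 512)
  list(trace = trace,
       density = data.frame(grid = d$x, density = d$y))
}
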