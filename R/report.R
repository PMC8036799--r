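#' Multi-method comparison analysis
#'
#' Runs every requested frequentist estimator and one Bayesian fit per
#' heterogeneity prior on a dataset, and collects the results in a
#' single table of odds ratios and heterogeneity standard deviations
#' with their 95% intervals — the standard layout for a
#' prior-sensitivity analysis. Frequentist rows use the sparse-data
#' policy (double-zero exclusion plus continuity correction,
#' see [apply_sparse_policy]); Bayesian rows use all studies. Bayesian
#' rows whose convergence verdict is `failed` are reported as NA, with
#' the verdict retained.
#'
#' @param data a [meta_dataset].
#' @param priors named list of [prior_spec] objects (default: the
#'   12-prior grid of [default_prior_grid]); may be empty.
#' @param methods character subset of `c("DL", "ML", "REML")`; may be
#'   empty.
#' @param correction continuity constant for the frequentist path.
#' @param config a [sampler_config]; `config$seed` governs all chains.
#' @param comparison Turner comparison key used when `priors` is left
#'   at its default.
#' @return an object of class `results_table`: a data.frame with
#'   columns `method`, `or`, `or_lo`, `or_hi`, `tau`, `tau_lo`,
#'   `tau_hi`, `verdict`, `k_used`, plus attributes `fits` (the
#'   underlying result objects) and `log` (per-study policy actions and
#'   per-chain acceptance rates).
#' @export
run_analysis <- function(data, priors = default_prior_grid(comparison),
                         methods = c("DL", "ML", "REML"),
                         correction = 0.5, config = sampler_config(),
                         comparison = "pharma_vs_placebo") {
  validate_meta_dataset(data)
  if (length(priors) == 0L && length(methods) == 0L)
    stop("at least one frequentist method or one prior must be requested")
  rows <- list()
  fits <- list()
  log <- list(seed = config$seed, correction = correction)

  if (length(methods) > 0L) {
    effects <- apply_sparse_policy(data, correction = correction,
                                   mode = "frequentist")
    log$excluded <- effects$excluded_ids
    log$corrected <- effects$corrected_ids
    for (m in methods) {
      fr <- freq_meta(effects, method = m)
      fits[[m]] <- fr
      rows[[m]] <- data.frame(
        method = m,
        or = exp(fr$theta_hat),
        or_lo = exp(fr$theta_ci[1]), or_hi = exp(fr$theta_ci[2]),
        tau = sqrt(fr$tau2_hat),
        tau_lo = fr$tau_ci[1], tau_hi = fr$tau_ci[2],
        verdict = NA_character_, k_used = fr$k_used,
        stringsAsFactors = FALSE)
    }
  }

  if (length(priors) > 0L) {
    if (is.null(names(priors)))
      names(priors) <- vapply(priors, format, character(1))
    acc <- list()
    for (nm in names(priors)) {
      fit <- run_mcmc(data, priors[[nm]], config = config)
      fits[[nm]] <- fit
      acc[[nm]] <- fit$acceptance
      failed <- fit$diagnostics$verdict == "failed"
      rows[[nm]] <- data.frame(
        method = nm,
        or = if (failed) NA_real_ else fit$or_summary[["median"]],
        or_lo = if (failed) NA_real_ else fit$or_summary[["lower"]],
        or_hi = if (failed) NA_real_ else fit$or_summary[["upper"]],
        tau = if (failed) NA_real_ else fit$tau_summary[["median"]],
        tau_lo = if (failed) NA_real_ else fit$tau_summary[["lower"]],
        tau_hi = if (failed) NA_real_ else fit$tau_summary[["upper"]],
        verdict = fit$diagnostics$verdict, k_used = fit$k,
        stringsAsFactors = FALSE)
    }
    log$acceptance <- acc
    if (all(vapply(rows[names(priors)],
                   function(r) is.na(r$or), logical(1))))
      warning("all Bayesian fits failed convergence; their summaries are NA")
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "log") <- log
  class(out) <- c("results_table", "data.frame")
  out
}

#' @export
print.results_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(cl) signif(cl, digits))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write a results table to CSV
#'
#' @param x a `results_table` from [run_analysis].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Forest-plot data table
#'
#' Per-study odds ratios with 95% intervals (`exp(y_i +/- 1.96
#' sqrt(v_i))`), study labels and arm counts, the pooled row from a
#' frequentist or Bayesian fit, and excluded studies listed with the
#' reason.
#'
#' @param data the [meta_dataset].
#' @param effects the [effect_estimates] used for the per-study rows.
#' @param pooled a `freq_result` or `posterior_result`.
#' @return a data.frame with columns `study_id`, `r_t`, `n_t`, `r_c`,
#'   `n_c`, `or`, `or_lo`, `or_hi`, `row_type`, `note`.
#' @export
forest_data <- function(data, effects, pooled = NULL) {
  validate_meta_dataset(data)
  z <- stats::qnorm(0.975)
  idx <- match(effects$included_ids, data$study_id)
  rows <- data.frame(study_id = effects$included_ids,
                     r_t = data$r_t[idx], n_t = data$n_t[idx],
                     r_c = data$r_c[idx], n_c = data$n_c[idx],
                     or = exp(effects$y),
                     or_lo = exp(effects$y - z * sqrt(effects$v)),
                     or_hi = exp(effects$y + z * sqrt(effects$v)),
                     row_type = "study", note = "",
                     stringsAsFactors = FALSE)
  if (length(effects$excluded_ids) > 0L) {
    idx <- match(effects$excluded_ids, data$study_id)
    rows <- rbind(rows, data.frame(
      study_id = effects$excluded_ids,
      r_t = data$r_t[idx], n_t = data$n_t[idx],
      r_c = data$r_c[idx], n_c = data$n_c[idx],
      or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
      row_type = "excluded",
      note = "zero cells in both arms; not estimable",
      stringsAsFactors = FALSE))
  }
  if (!is.null(pooled)) {
    if (inherits(pooled, "freq_result")) {
      pr <- c(exp(pooled$theta_hat), exp(pooled$theta_ci))
      lbl <- paste0("Pooled (", pooled$method, ")")
    } else if (inherits(pooled, "posterior_result")) {
      pr <- c(pooled$or_summary[["median"]], pooled$or_summary[["lower"]],
              pooled$or_summary[["upper"]])
      lbl <- paste0("Pooled (Bayesian, ", format(pooled$prior), ")")
    } else stop("pooled must be a freq_result or posterior_result")
    rows <- rbind(rows, data.frame(
      study_id = lbl, r_t = NA, n_t = NA, r_c = NA, n_c = NA,
      or = pr[1], or_lo = pr[2], or_hi = pr[3],
      row_type = "pooled", note = "", stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

# Turn one YAML prior entry into a prior_spec (or, for default_grid,
# a list of them).
parse_prior_entry <- function(entry) {
  if (!is.null(entry$turner))
    return(turner_prior(entry$turner$comparison, entry$turner$outcome))
  if (!is.null(entry$default_grid))
    return(default_prior_grid(entry$default_grid))
  do.call(prior_spec, entry)
}

#' Read a declarative analysis configuration
#'
#' YAML schema (all blocks optional unless noted):
#' \preformatted{
#' data: studies.csv          # required for the CLI `run` command
#' seed: 1
#' sparse: {correction: 0.5}
#' frequentist: [DL, ML, REML]
#' priors:
#'   - {family: half_normal, sigma2: 1}
#'   - {turner: {comparison: pharma_vs_placebo, outcome: subjective}}
#'   - {default_grid: pharma_vs_placebo}
#' mcmc: {chains: 3, burn_in: 50000, iterations: 200000, thin: 2}
#' }
#'
#' @param path path to the YAML file.
#' @return a list with elements `data_path`, `priors`, `methods`,
#'   `correction`, `config`, ready for [run_analysis].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  mc <- y$mcmc
  config <- sampler_config(
    chains = if (is.null(mc$chains)) 3 else mc$chains,
    burn_in = if (is.null(mc$burn_in)) 50000 else mc$burn_in,
    iterations = if (is.null(mc$iterations)) 200000 else mc$iterations,
    thin = if (is.null(mc$thin)) 2 else mc$thin,
    seed = seed)
  priors <- list()
  for (entry in y$priors) {
    p <- parse_prior_entry(entry)
    if (inherits(p, "prior_spec")) priors[[format(p)]] <- p
    else priors <- c(priors, p)
  }
  methods <- if (is.null(y$frequentist)) character() else
    unlist(y$frequentist)
  correction <- if (is.null(y$sparse$correction)) 0.5 else
    y$sparse$correction
  list(data_path = y$data, priors = priors, methods = methods,
       correction = correction, config = config)
}
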