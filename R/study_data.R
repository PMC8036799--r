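#' Construct a meta-analysis dataset of 2x2 tables
#'
#' A `meta_dataset` holds one 2x2 table per study: event counts and
#' sample sizes for the treatment and control arms. It is a plain
#' `data.frame` with columns `study_id`, `r_t`, `n_t`, `r_c`, `n_c`,
#' validated on construction.
#'
#' @param study_id character or coercible; unique study labels.
#' @param r_t integer event counts in the treatment arm.
#' @param n_t integer sample sizes in the treatment arm.
#' @param r_c integer event counts in the control arm.
#' @param n_c integer sample sizes in the control arm.
#'
#' @return A `data.frame` of class `meta_dataset`. Row order is
#'   preserved and serves as the canonical study index.
#' @examples
#' d <- meta_dataset(c("A", "B"), r_t = c(10, 20), n_t = c(100, 200),
#'                   r_c = c(5, 10), n_c = c(100, 200))
#' nrow(d)
#' @export
meta_dataset <- function(study_id, r_t, n_t, r_c, n_c) {
  x <- data.frame(study_id = as.character(study_id),
                  r_t = as.numeric(r_t), n_t = as.numeric(n_t),
                  r_c = as.numeric(r_c), n_c = as.numeric(n_c),
                  stringsAsFactors = FALSE)
  class(x) <- c("meta_dataset", "data.frame")
  validate_meta_dataset(x)
}

#' Validate a meta-analysis dataset
#'
#' Checks the 2x2-table invariants: counts non-negative and not larger
#' than the arm size, arm sizes at least 1, unique study labels, and at
#' least one study.
#'
#' @param x a `meta_dataset` or a data.frame with the same columns.
#' @return `x`, invisibly classed as `meta_dataset`, or an error naming
#'   the offending column or study.
#' @export
validate_meta_dataset <- function(x) {
  required <- c("study_id", "r_t", "n_t", "r_c", "n_c")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) < 1L)
    stop("k >= 1 required: dataset contains no studies")
  num <- c("r_t", "n_t", "r_c", "n_c")
  for (cl in num) {
    if (any(!is.finite(x[[cl]])))
      stop("non-finite value in column ", cl)
  }
  if (anyDuplicated(x$study_id))
    stop("duplicated study_id: ",
         paste(unique(x$study_id[duplicated(x$study_id)]), collapse = ", "))
  bad <- x$n_t < 1 | x$n_c < 1
  if (any(bad))
    stop("arm sample size < 1 for study_id: ",
         paste(x$study_id[bad], collapse = ", "))
  bad <- x$r_t < 0 | x$r_c < 0 | x$r_t > x$n_t | x$r_c > x$n_c
  if (any(bad))
    stop("invalid counts (need 0 <= r <= n in both arms) for study_id: ",
         paste(x$study_id[bad], collapse = ", "))
  if (!inherits(x, "meta_dataset")) class(x) <- c("meta_dataset", class(x))
  invisible(x)
}

#' Read a meta-analysis dataset from a delimited file
#'
#' Expects a header row naming the five columns `study_id, r_t, n_t,
#' r_c, n_c` (any order; extra columns are ignored). Comma-delimited by
#' default; pass `delim = "\t"` for tab-separated files.
#'
#' @param path path to the file.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return a validated [meta_dataset] preserving file row order.
#' @export
read_meta_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           comment.char = "", quote = "\"")
  required <- c("study_id", "r_t", "n_t", "r_c", "n_c")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) < 1L) stop("k >= 1 required: dataset contains no studies")
  meta_dataset(raw$study_id, raw$r_t, raw$n_t, raw$r_c, raw$n_c)
}

#' Write a meta-analysis dataset to CSV
#'
#' Emits the `study_id,r_t,n_t,r_c,n_c` schema. When `effects` (an
#' [effect_estimates] from the frequentist sparse-data policy) is
#' supplied, two columns `policy` (`none`/`corrected`/`excluded`) and
#' `reason` are appended documenting the per-study action.
#'
#' @param x a `meta_dataset`.
#' @param path output file path.
#' @param effects optional `effect_estimates` with the policy applied.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(x, path, effects = NULL) {
  out <- as.data.frame(x)
  if (!is.null(effects)) {
    policy <- rep("none", nrow(out))
    reason <- rep("", nrow(out))
    policy[out$study_id %in% effects$corrected_ids] <- "corrected"
    reason[out$study_id %in% effects$corrected_ids] <-
      "zero cell in one arm; continuity correction applied"
    policy[out$study_id %in% effects$excluded_ids] <- "excluded"
    reason[out$study_id %in% effects$excluded_ids] <-
      "zero events (or zero non-events) in both arms; log OR not estimable"
    out$policy <- policy
    out$reason <- reason
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Log odds ratio and its sampling variance from a 2x2 table
#'
#' For cell counts `a` (treatment events), `b` (treatment non-events),
#' `c` (control events), `d` (control non-events), returns the log odds
#' ratio `log(a*d/(b*c))` and its large-sample variance
#' `1/a + 1/b + 1/c + 1/d`. All cells must be strictly positive; apply
#' a sparse-data policy first (see [apply_sparse_policy]).
#'
#' @param a,b,c,d cell counts (vectorized; strictly positive).
#' @return a list with components `y` (log OR) and `v` (variance).
#' @examples
#' log_or(10, 10, 10, 10)  # y = 0, v = 0.4
#' @export
log_or <- function(a, b, c, d) {
  if (any(a <= 0 | b <= 0 | c <= 0 | d <= 0))
    stop("all four cells must be strictly positive; ",
         "apply a sparse-data policy (continuity correction / exclusion) first")
  list(y = log(a * d / (b * c)), v = 1 / a + 1 / b + 1 / c + 1 / d)
}

#' Construct per-study effect estimates directly
#'
#' Low-level constructor for the container produced by
#' [apply_sparse_policy] in frequentist mode: per-study log odds ratios
#' and sampling variances together with the bookkeeping of which
#' studies were retained, corrected, or excluded.
#'
#' @param y numeric, per-study log OR.
#' @param v numeric, per-study sampling variance (strictly positive).
#' @param study_id labels of the retained studies (defaults to `1:k`).
#' @param corrected_ids labels that received a continuity correction.
#' @param excluded_ids labels dropped from the analysis.
#' @return an object of class `effect_estimates`.
#' @export
effect_estimates <- function(y, v, study_id = NULL,
                             corrected_ids = character(),
                             excluded_ids = character()) {
  if (length(y) != length(v)) stop("y and v must have equal length")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("sampling variances must be finite and strictly positive")
  if (is.null(study_id)) study_id <- as.character(seq_along(y))
  study_id <- as.character(study_id)
  if (length(study_id) != length(y))
    stop("study_id must match length of y")
  if (length(intersect(study_id, excluded_ids)) > 0L)
    stop("included and excluded study sets must be disjoint")
  if (!all(corrected_ids %in% study_id))
    stop("corrected_ids must be a subset of the retained studies")
  structure(list(y = as.numeric(y), v = as.numeric(v),
                 included_ids = study_id,
                 corrected_ids = as.character(corrected_ids),
                 excluded_ids = as.character(excluded_ids),
                 k_used = length(y)),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat("Per-study effect estimates (log OR scale)\n")
  cat("  studies retained :", x$k_used, "\n")
  if (length(x$corrected_ids) > 0L)
    cat("  continuity-corrected:", paste(x$corrected_ids, collapse = ", "), "\n")
  if (length(x$excluded_ids) > 0L)
    cat("  excluded (double-zero):", paste(x$excluded_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the sparse-data policy for zero event counts
#'
#' Frequentist analyses of the log odds ratio cannot use studies whose
#' 2x2 table has zero cells. Under `mode = "frequentist"`:
#' \itemize{
#'   \item studies with zero cells in \emph{both} arms (in particular
#'     double-zero-event studies) are excluded;
#'   \item studies with zero cells in a \emph{single} arm receive the
#'     continuity correction: `correction` (default 0.5) is added to all
#'     four cells (set `all_cells = FALSE` to correct only the studies'
#'     zero cells);
#'   \item all-positive studies pass through unchanged.
#' }
#' Arms with `r = n` (all events, i.e. a zero non-event cell) trigger
#' the same policy as zero-event arms. Under `mode = "bayesian"` the
#' dataset is returned unchanged: the exact binomial likelihood needs
#' no ad hoc correction and double-zero studies still contribute
#' baseline information.
#'
#' @param data a [meta_dataset].
#' @param correction continuity constant added to cells (default 0.5).
#' @param mode `"frequentist"` or `"bayesian"`.
#' @param all_cells logical; correct all four cells of an affected
#'   study (default, the Gart convention) or only its zero cells.
#' @return For `mode = "frequentist"`, an [effect_estimates]; for
#'   `mode = "bayesian"`, the input `meta_dataset` unchanged.
#' @examples
#' d <- meta_dataset(c("s1", "s2"), r_t = c(3, 0), n_t = c(50, 50),
#'                   r_c = c(0, 0), n_c = c(50, 50))
#' apply_sparse_policy(d, mode = "frequentist")
#' @export
apply_sparse_policy <- function(data, correction = 0.5,
                                mode = c("frequentist", "bayesian"),
                                all_cells = TRUE) {
  mode <- match.arg(mode)
  validate_meta_dataset(data)
  if (mode == "bayesian") return(data)
  if (correction <= 0) stop("correction must be strictly positive")

  a <- data$r_t; b <- data$n_t - data$r_t
  c_ <- data$r_c; d <- data$n_c - data$r_c
  zero_t <- a == 0 | b == 0
  zero_c <- c_ == 0 | d == 0
  excluded <- zero_t & zero_c
  needs_cc <- xor(zero_t, zero_c)
  if (all(excluded)) stop("no estimable studies: every study has zero ",
                          "cells in both arms")
  if (all_cells) {
    add <- ifelse(needs_cc, correction, 0)
    a <- a + add; b <- b + add; c_ <- c_ + add; d <- d + add
  } else {
    fix <- function(x) ifelse(needs_cc & x == 0, correction, x)
    a <- fix(a); b <- fix(b); c_ <- fix(c_); d <- fix(d)
  }
  keep <- !excluded
  est <- log_or(a[keep], b[keep], c_[keep], d[keep])
  effect_estimates(est$y, est$v,
                   study_id = data$study_id[keep],
                   corrected_ids = data$study_id[needs_cc & keep],
                   excluded_ids = data$study_id[excluded])
}
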