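#' Paired Wilcoxon signed-rank test for a pre/post index
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test of the change in an
#' index across visits. Zero differences are dropped (the classical Wilcoxon
#' convention); the exact null distribution is used for up to 25 non-zero
#' differences without ties in absolute value, otherwise the normal
#' approximation with continuity correction. If every difference is zero the
#' result is degenerate and `p_value = 1`.
#'
#' @param pre,post Numeric vectors of per-subject index values, aligned by
#'   subject, length >= 2.
#' @return A list of class `nox_wilcoxon`: `statistic` (V, the positive-rank
#'   sum), `p_value`, `n`, `n_effective` (non-zero differences), `method`,
#'   `degenerate`.
#' @export
#' @examples
#' wilcoxon_paired(c(5, 6, 7), c(5, 6, 7))$p_value  # 1, no signal
wilcoxon_paired <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- pre - post
  nz <- d[d != 0]
  if (!length(nz))
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n = length(d), n_effective = 0L,
                          method = "degenerate", degenerate = TRUE),
                     class = "nox_wilcoxon"))
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n = length(d), n_effective = length(nz),
                 method = if (exact) "exact" else "normal approximation",
                 degenerate = FALSE),
            class = "nox_wilcoxon")
}

#' @export
print.nox_wilcoxon <- function(x, ...) {
  cat(sprintf("<nox_wilcoxon> V = %s, p = %.3g (%s; %d/%d non-zero pairs)\n",
              format(x$statistic), x$p_value, x$method, x$n_effective, x$n))
  invisible(x)
}

#' ROC analysis with the Youden-optimal cutoff
#'
#' Empirical ROC curve for an index against a binary condition, with the AUC
#' by the trapezoidal rule, a 95% confidence interval (DeLong by default, or
#' a stratified bootstrap), and the operating point maximizing Youden's index
#' (sensitivity + specificity). Cutoff ties are broken toward higher
#' specificity (a screening result is typically confirmed downstream, so
#' false positives are the costlier error at the margin). The reported cutoff
#' is the midpoint between adjacent distinct observed values, read as
#' "positive if index > cutoff" under `greater_is_positive`.
#'
#' @param values Numeric index values, one per recording.
#' @param labels Logical (or 0/1) condition labels, `TRUE` = condition
#'   present. Both classes must be present.
#' @param direction `"greater_is_positive"` if larger index values indicate
#'   the condition (ODI, CSA, SSE, MOS), `"less_is_positive"` otherwise
#'   (e.g. mean SpO2).
#' @param ci_method `"delong"` (default, deterministic) or `"bootstrap"`
#'   (stratified, `boot_n` resamples; seed with [set.seed()] for
#'   reproducibility).
#' @param boot_n Bootstrap resamples.
#' @return A list of class `nox_roc`: `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `direction`, `ci_method`, `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' r <- roc_with_youden(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' r$auc      # 1: perfect separation
#' r$cutoff   # 3.5: midpoint between the classes
roc_with_youden <- function(values, labels,
                            direction = c("greater_is_positive",
                                          "less_is_positive"),
                            ci_method = c("delong", "bootstrap"),
                            boot_n = 2000) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  roc <- pROC::roc(response = labels, predictor = values,
                   levels = c(FALSE, TRUE),
                   direction = if (direction == "greater_is_positive") "<" else ">",
                   quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- withCallingHandlers(
    if (ci_method == "delong") pROC::ci.auc(roc, method = "delong")
    else pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n,
                      boot.stratified = TRUE),
    # a degenerate (AUC = 1) curve has a point-mass CI; that is expected on
    # perfectly separated data and not worth surfacing per call
    warning = function(w) {
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- pROC::coords(roc, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(-co$specificity), , drop = FALSE][1, ]
  structure(list(auc = auc,
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 cutoff = co$threshold,
                 sensitivity_pct = 100 * co$sensitivity,
                 specificity_pct = 100 * co$specificity,
                 direction = direction, ci_method = ci_method,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "nox_roc")
}

#' @export
print.nox_roc <- function(x, ...) {
  op <- if (x$direction == "greater_is_positive") ">" else "<"
  cat(sprintf("<nox_roc> AUC %.3f (%.3f-%.3f, %s); cutoff %s%.4g: Se %.1f%%, Sp %.1f%% (%d+/%d-)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, op, x$cutoff,
              x$sensitivity_pct, x$specificity_pct, x$n_pos, x$n_neg))
  invisible(x)
}

#' Spearman correlation matrix of per-subject indices
#'
#' Symmetric matrix of Spearman's rank correlation with average-rank tie
#' handling. A constant column has no defined rank correlation; its
#' off-diagonal entries (and diagonal) are reported as `NA`.
#'
#' @param columns A data.frame or named list of equal-length numeric vectors
#'   (one column per index), at least 3 subjects.
#' @return A numeric matrix of Spearman rho.
#' @export
#' @examples
#' spearman_matrix(data.frame(a = 1:5, b = c(2, 1, 4, 3, 5)))
spearman_matrix <- function(columns) {
  m <- as.matrix(as.data.frame(columns))
  if (nrow(m) < 3) stop("need at least 3 subjects", call. = FALSE)
  suppressWarnings(stats::cor(m, method = "spearman"))
}
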