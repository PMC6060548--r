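#' ROC area under the curve with DeLong interval
#'
#' AUC computed by the Mann-Whitney statistic (ties counted one half), with
#' a DeLong confidence interval, via the pROC package. `direction`
#' states which way the score indicates disease and is always explicit —
#' e.g. the free-to-total PSA ratio is *lower* in prostate cancer.
#'
#' @param scores numeric marker values.
#' @param labels binary disease status (1/TRUE = diseased).
#' @param direction `"greater"` if larger scores indicate disease,
#'   `"less"` otherwise.
#' @param level confidence level.
#' @return list of class `roc_result`: `auc`, `ci` (lower, upper),
#'   `direction`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels, direction = c("greater", "less"),
                    level = 0.95) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute an AUC")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1),
                 direction = if (direction == "greater") "<" else ">",
                 quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong"))
  ci <- structure(ci[c(1, 3)], level = level)
  structure(list(auc = as.numeric(pROC::auc(r)), ci = ci,
                 direction = direction,
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  lvl <- attr(x$ci, "level")
  if (is.null(lvl)) lvl <- 0.95
  cat(sprintf("<roc_result> AUC %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d controls, disease if score %s\n",
              x$auc, 100 * lvl, x$ci[1], x$ci[2],
              x$n_cases, x$n_controls,
              if (x$direction == "greater") "high" else "low"))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1) | is.na(labels)))
    stop("labels must be binary (0/1)")
  labels
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `lr_pos = sens / (1 - spec)` and `lr_neg = (1 - sens) / spec`. When the
#' case and control counts are supplied, log-method (Simel) confidence
#' intervals are attached; with perfect specificity the positive ratio is
#' reported as `Inf` with a one-sided interval from Haldane-corrected
#' counts.
#'
#' @param sens,spec sensitivity and specificity (proportions).
#' @param n_cases,n_controls class sizes (optional, for intervals).
#' @param level confidence level.
#' @return list with `lr_pos`, `lr_neg` and, when counts are given,
#'   `lr_pos_ci`, `lr_neg_ci`.
#' @examples
#' likelihood_ratios(0.677, 0.717)$lr_neg  # 0.45
#' @export
likelihood_ratios <- function(sens, spec, n_cases = NULL, n_controls = NULL,
                              level = 0.95) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("sensitivity and specificity must be proportions in [0, 1]")
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) Inf else (1 - sens) / spec
  out <- list(lr_pos = lr_pos, lr_neg = lr_neg)
  if (!is.null(n_cases) && !is.null(n_controls)) {
    tp <- sens * n_cases; fn <- n_cases - tp
    tn <- spec * n_controls; fp <- n_controls - tn
    out$lr_pos_ci <- lr_log_ci(tp, fn, fp, tn, positive = TRUE, level = level)
    out$lr_neg_ci <- lr_log_ci(tp, fn, fp, tn, positive = FALSE, level = level)
  }
  out
}

## Simel log-method interval; Haldane 0.5 correction when a cell is empty
lr_log_ci <- function(tp, fn, fp, tn, positive, level) {
  cells <- c(tp, fn, fp, tn)
  if (any(cells == 0)) cells <- cells + 0.5
  tp <- cells[1]; fn <- cells[2]; fp <- cells[3]; tn <- cells[4]
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (positive) {
    lr <- sens / (1 - spec)
    se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  } else {
    lr <- (1 - sens) / spec
    se <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  }
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic metrics at a decision cutoff
#'
#' Sensitivity and specificity at a cutoff (test positive when the score is
#' at or beyond the cutoff in the disease direction), with Clopper-Pearson
#' exact binomial intervals, plus positive and negative likelihood ratios
#' with log-method intervals.
#'
#' @param scores,labels,direction,level as in [roc_auc()].
#' @param cutoff decision threshold: `direction = "greater"` calls
#'   `score >= cutoff` positive, `"less"` calls `score <= cutoff` positive.
#' @return list of class `diagnostic_metrics`: `sensitivity`,
#'   `specificity` (each with `ci`), `lr_pos`, `lr_neg` (with `ci`),
#'   `cutoff`, `direction`, and the 2x2 counts.
#' @export
metrics_at_cutoff <- function(scores, labels, cutoff,
                              direction = c("greater", "less"),
                              level = 0.95) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  positive <- if (direction == "greater") scores >= cutoff else scores <= cutoff
  tp <- sum(positive & labels == 1); fn <- sum(!positive & labels == 1)
  fp <- sum(positive & labels == 0); tn <- sum(!positive & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  sens_ci <- stats::binom.test(tp, tp + fn, conf.level = level)$conf.int
  spec_ci <- stats::binom.test(tn, fp + tn, conf.level = level)$conf.int
  lr <- likelihood_ratios(sens, spec, n_cases = tp + fn,
                          n_controls = fp + tn, level = level)
  structure(list(sensitivity = sens, sensitivity_ci = as.numeric(sens_ci),
                 specificity = spec, specificity_ci = as.numeric(spec_ci),
                 lr_pos = lr$lr_pos, lr_pos_ci = lr$lr_pos_ci,
                 lr_neg = lr$lr_neg, lr_neg_ci = lr$lr_neg_ci,
                 cutoff = cutoff, direction = direction,
                 counts = c(tp = tp, fn = fn, fp = fp, tn = tn)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("<diagnostic_metrics> cutoff %g (positive if score %s)\n",
              x$cutoff, if (x$direction == "greater") ">= cutoff" else "<= cutoff"))
  cat(sprintf("  sensitivity %.1f%% (%.1f-%.1f)   specificity %.1f%% (%.1f-%.1f)\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  cat(sprintf("  LR+ %.2f (%.2f-%.2f)   LR- %.2f (%.2f-%.2f)\n",
              x$lr_pos, x$lr_pos_ci[1], x$lr_pos_ci[2],
              x$lr_neg, x$lr_neg_ci[1], x$lr_neg_ci[2]))
  invisible(x)
}

#' PCA3 score
#'
#' The urinary prostate cancer antigen 3 score:
#' `PCA3 mRNA / PSA mRNA * 1000`.
#'
#' @param pca3_mrna,psa_mrna mRNA quantities; `psa_mrna` must be positive.
#' @return the score (vectorized).
#' @examples
#' pca3_score(35, 1000)  # 35
#' @export
pca3_score <- function(pca3_mrna, psa_mrna) {
  if (any(psa_mrna <= 0, na.rm = TRUE))
    stop("PSA mRNA must be positive (zero denominator)")
  pca3_mrna / psa_mrna * 1000
}
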