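#' Intraclass correlation from variance components
#'
#' `icc_value()` is the reliability coefficient
#' `sigma_b2 / (sigma_b2 + sigma_w2)`: the proportion of total variance due
#' to real between-subject differences, and equally the attenuation factor
#' of a naive regression slope under classical measurement error.
#'
#' @param sigma_b2,sigma_w2 between- and within-subject variances (>= 0).
#' @return the ICC in `[0, 1]` (0 when `sigma_b2` is 0).
#' @examples
#' icc_value(9.01, 13.45)  # ~0.40, a typical urinary creatinine reliability
#' @export
icc_value <- function(sigma_b2, sigma_w2) {
  if (any(sigma_b2 < 0) || any(sigma_w2 < 0)) stop("variances must be >= 0")
  tot <- sigma_b2 + sigma_w2
  ifelse(sigma_b2 == 0, 0, sigma_b2 / tot)
}

#' One-way random-effects variance components
#'
#' Classical ANOVA (method-of-moments) estimator for the unbalanced one-way
#' random-effects model `y_ij = mu + b_i + e_ij`:
#' `sigma_w2 = MSW`, `sigma_b2 = (MSB - MSW) / n0` with
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`. A negative between-subject
#' estimate is clipped to 0 and flagged. The ICC follows as
#' `sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' @param values numeric observations.
#' @param subject grouping factor (one level per subject).
#' @return an object of class `variance_components` with fields
#'   `sigma_b2`, `sigma_w2`, `icc`, `n_subjects`, `group_sizes`, `ms_between`,
#'   `ms_within`, `n0`, `df_between`, `df_within`, `clipped`.
#' @examples
#' vc <- variance_components(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
#' vc$icc  # 3.75 / 4.25
#' @export
variance_components <- function(values, subject) {
  keep <- is.finite(values) & !is.na(subject)
  values <- values[keep]
  subject <- factor(subject[keep])
  ni <- tabulate(subject)
  k <- nlevels(subject)
  n_tot <- length(values)
  if (k < 2) stop("variance components need at least 2 subjects")
  if (all(ni < 2))
    stop("within-subject variance is inestimable: every subject has a ",
         "single observation")
  gm <- tapply(values, subject, mean)
  ssw <- sum((values - gm[subject])^2)
  grand <- mean(values)
  ssb <- sum(ni * (gm - grand)^2)
  df_w <- n_tot - k
  df_b <- k - 1
  msw <- ssw / df_w
  msb <- ssb / df_b
  n0 <- (n_tot - sum(ni^2) / n_tot) / df_b
  sb2 <- (msb - msw) / n0
  clipped <- sb2 < 0
  if (clipped) sb2 <- 0
  structure(list(sigma_b2 = sb2, sigma_w2 = msw,
                 icc = icc_value(sb2, msw),
                 n_subjects = k, group_sizes = as.integer(ni),
                 ms_between = msb, ms_within = msw, n0 = n0,
                 df_between = df_b, df_within = df_w, clipped = clipped),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> ", x$n_subjects, " subjects, N = ",
      sum(x$group_sizes), "\n", sep = "")
  cat(sprintf("  sigma_b2 = %.4g%s  sigma_w2 = %.4g  ICC = %.3f\n",
              x$sigma_b2, if (x$clipped) " (clipped)" else "",
              x$sigma_w2, x$icc))
  invisible(x)
}

#' F-based confidence interval for the one-way ICC
#'
#' Searle's interval for the intraclass correlation of a one-way
#' random-effects design, using the observed F ratio `MSB / MSW` and the
#' average group size `n0` (which makes the interval applicable, as an
#' approximation, to unbalanced designs; it is exact for balanced ones).
#' Bounds are clipped to `[0, 1]`.
#'
#' @param vc a [variance_components()] object.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` with attribute `level`.
#' @export
icc_confidence_interval <- function(vc, level = 0.95) {
  stopifnot(inherits(vc, "variance_components"))
  alpha <- 1 - level
  fobs <- vc$ms_between / vc$ms_within
  fu <- stats::qf(1 - alpha / 2, vc$df_between, vc$df_within)
  fl <- stats::qf(alpha / 2, vc$df_between, vc$df_within)
  lo <- (fobs / fu - 1) / (fobs / fu - 1 + vc$n0)
  hi <- (fobs / fl - 1) / (fobs / fl - 1 + vc$n0)
  out <- pmin(1, pmax(0, c(lo, hi)))
  attr(out, "level") <- level
  out
}

#' Per-feature ICC from a repeatability feature table
#'
#' The subject-versus-serial-sample reliability workflow: technical spot
#' replicates are averaged per (subject, serial sample) first — reliability
#' is a statement about biological sampling, not spotting — and a one-way
#' random-effects ANOVA across subjects is then fitted per feature.
#' Typically applied to an sLMNLT (log2) table.
#'
#' @param table a [feature_table] with `subject_id` metadata; `run_id`
#'   identifies the serial sample when spots are present.
#' @param average_spots average spot replicates per serial sample first
#'   (default `TRUE`).
#' @param level confidence level for the ICC intervals.
#' @return data frame with one row per feature: `mz`, `sigma_b2`,
#'   `sigma_w2`, `icc`, `ci_low`, `ci_high`.
#' @export
feature_icc <- function(table, average_spots = TRUE, level = 0.95) {
  stopifnot(inherits(table, "feature_table"))
  info <- table$samples
  if (is.null(info$subject_id))
    stop("feature_icc needs 'subject_id' sample metadata")
  y <- table$intensity
  if (average_spots && !is.null(info$run_id)) {
    key <- paste(info$subject_id, info$run_id)
    y <- apply(y, 2, function(col) tapply(col, key, mean, na.rm = TRUE))
    subj <- tapply(as.character(info$subject_id), key, `[`, 1)
  } else {
    subj <- as.character(info$subject_id)
  }
  out <- lapply(seq_along(table$mz), function(j) {
    vc <- variance_components(y[, j], subj)
    ci <- icc_confidence_interval(vc, level = level)
    data.frame(mz = table$mz[j], sigma_b2 = vc$sigma_b2,
               sigma_w2 = vc$sigma_w2, icc = vc$icc,
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, out)
}

#' Intra- and inter-assay CV from a nested precision design
#'
#' Per-feature two-level nested ANOVA of a run x replicate precision table
#' (runs as the random grouping): `sigma_rep2 = MSW`,
#' `sigma_run2 = (MSB - MSW) / n0` (clipped at 0), and coefficients of
#' variation on the intensity scale:
#' `intra_cv = 100 * sqrt(sigma_rep2) / mean`,
#' `inter_cv = 100 * sqrt(sigma_run2 + sigma_rep2) / mean`. Expected input
#' is a pre-log table (raw or median-normalized).
#'
#' @param table a [feature_table] with `run_id` metadata, at least 2 runs
#'   with at least 2 replicates each.
#' @return data frame with one row per feature: `mz`, `grand_mean`,
#'   `sigma_run2`, `sigma_rep2`, `intra_cv`, `inter_cv`.
#' @export
assay_cv <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  run <- table$samples$run_id
  if (is.null(run)) stop("assay_cv needs 'run_id' sample metadata")
  if (length(unique(run)) < 2)
    stop("between-run variance is inestimable from a single run")
  out <- lapply(seq_along(table$mz), function(j) {
    vc <- variance_components(table$intensity[, j], run)
    m <- mean(table$intensity[, j], na.rm = TRUE)
    data.frame(mz = table$mz[j], grand_mean = m,
               sigma_run2 = vc$sigma_b2, sigma_rep2 = vc$sigma_w2,
               intra_cv = 100 * sqrt(vc$sigma_w2) / m,
               inter_cv = 100 * sqrt(vc$sigma_b2 + vc$sigma_w2) / m)
  })
  do.call(rbind, out)
}

#' Median / IQR summary of per-feature statistics
#'
#' Distribution-free summary used for skewed per-feature statistics (ICCs,
#' CVs, variances): the median and the 25th/75th percentiles, with
#' linear-interpolation (type 7) quantiles so reported IQRs are
#' reproducible.
#'
#' @param x numeric vector of per-feature statistics.
#' @return named numeric vector `median`, `q25`, `q75`, `iqr`.
#' @export
summarize_features <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("nothing to summarize: no finite values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3], iqr = q[3] - q[1])
}
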