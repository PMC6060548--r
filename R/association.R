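#' Assign outcome groups from biopsy histology
#'
#' Maps the seven biopsy histology categories to analysis groups. The
#' two-group scheme compares a Reference group (no alteration, BPH,
#' inflammation; outcome 0) with a cancer-lesions group (PCa, HGPIN, ASAP;
#' outcome 1). The four-group scheme distinguishes A = no alteration,
#' B = BPH + inflammation, C = HGPIN + ASAP, D = PCa. Subjects with
#' atypical adenomatous hyperplasia (AAH) are excluded under both schemes.
#'
#' @param phenotypes a phenotype data frame with a `histology` column (see
#'   [phenotype_table()]).
#' @param scheme `"two_group"` or `"four_group"`.
#' @return an object of class `group_assignment`: list with `outcome`
#'   (integer 0/1, `NA` for excluded, under `two_group`), `group` (factor
#'   A-D under `four_group`, `NA` for excluded), `excluded` (logical),
#'   `scheme`, and `counts`.
#' @export
assign_groups <- function(phenotypes, scheme = c("two_group", "four_group")) {
  scheme <- match.arg(scheme)
  hist <- as.character(phenotypes$histology)
  valid <- c("no alteration", "BPH", "inflammation", "AAH",
             "ASAP", "HGPIN", "PCa")
  unknown <- setdiff(unique(hist), valid)
  if (length(unknown))
    stop("unknown histology label(s): ", paste(unknown, collapse = ", "))
  excluded <- hist == "AAH"
  if (scheme == "two_group") {
    outcome <- ifelse(hist %in% c("PCa", "HGPIN", "ASAP"), 1L,
                      ifelse(excluded, NA_integer_, 0L))
    counts <- c(reference = sum(outcome == 0, na.rm = TRUE),
                cancer_lesions = sum(outcome == 1, na.rm = TRUE),
                excluded = sum(excluded))
    group <- NULL
  } else {
    group <- rep(NA_character_, length(hist))
    group[hist == "no alteration"] <- "A"
    group[hist %in% c("BPH", "inflammation")] <- "B"
    group[hist %in% c("HGPIN", "ASAP")] <- "C"
    group[hist == "PCa"] <- "D"
    group <- factor(group, levels = c("A", "B", "C", "D"))
    outcome <- ifelse(group %in% c("C", "D"), 1L,
                      ifelse(excluded, NA_integer_, 0L))
    counts <- c(table(group), excluded = sum(excluded))
  }
  structure(list(outcome = outcome, group = group, excluded = excluded,
                 scheme = scheme, counts = counts),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> scheme:", x$scheme, "\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Logistic regression fit with Wald statistics
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 50 iterations), with
#' per-coefficient Wald tests and odds ratios. Fits that fail to converge
#' or show signs of separation (unbounded coefficients, exploding standard
#' errors) are flagged `converged = FALSE` and should not be interpreted.
#'
#' @param x predictor vector, or matrix/data frame with one column per
#'   predictor (an intercept is always added).
#' @param y binary outcome (0/1, logical, or two-level factor); rows with
#'   missing outcome are dropped.
#' @return an object of class `logistic_fit`: coefficients `beta` (named,
#'   including `(Intercept)`), `se`, `z`, `wald_p`, `or_` (`exp(beta)`),
#'   `converged`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- rbinom(200, 1, plogis(x))
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(x, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  X <- as.matrix(x)
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || !any(is.finite(v)))
  if (any(const))
    stop("constant predictor(s): ", paste(colnames(X)[const], collapse = ", "))
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("collinear predictors; could not estimate: ",
         paste(colnames(Xd)[is.na(beta)], collapse = ", "))
  p <- ncol(Xd)
  covm <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covm))
  names(se) <- names(beta)
  converged <- fit$converged && all(se < 50) && all(abs(beta) < 30)
  z <- beta / se
  structure(list(beta = beta, se = se, z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 or_ = exp(beta), converged = converged,
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("<logistic_fit> n =", x$n,
      if (!x$converged) " [NOT CONVERGED / separation]", "\n")
  print(data.frame(beta = x$beta, se = x$se, or = x$or_, wald_p = x$wald_p),
        digits = digits)
  invisible(x)
}

## slope (first non-intercept coefficient) helpers
fit_slope <- function(fit) fit$beta[2]
fit_slope_se <- function(fit) fit$se[2]

#' Regression calibration (RCAL) for a logistic coefficient
#'
#' Corrects the attenuation of a naive logistic slope under classical
#' measurement error by dividing the coefficient by the reliability
#' coefficient: `beta_star = beta / icc`. Confidence intervals follow
#' Rosner's approach: the naive Wald interval endpoints are divided by the
#' same ICC.
#'
#' @param fit a [fit_logistic()] result (the first non-intercept slope is
#'   corrected), or a plain numeric naive coefficient.
#' @param icc reliability coefficient in `(0, 1]`.
#' @param se naive standard error; only needed when `fit` is numeric and an
#'   interval is wanted (see [wald_se_from_p()]).
#' @param level confidence level.
#' @return an object of class `corrected_fit` with `method = "RCAL"`,
#'   `beta_star`, `ci_star`, `or_star`, `calibration` (the ICC used), and
#'   the naive `beta`.
#' @examples
#' rcal(0.435, icc = 0.459)$beta_star  # 0.948
#' @export
rcal <- function(fit, icc, se = NULL, level = 0.95) {
  if (length(icc) != 1 || is.na(icc) || icc <= 0 || icc > 1)
    stop("'icc' must lie in (0, 1]")
  if (inherits(fit, "logistic_fit")) {
    if (!fit$converged) stop("refusing to calibrate a non-converged fit")
    beta <- unname(fit_slope(fit))
    se <- unname(fit_slope_se(fit))
  } else {
    beta <- as.numeric(fit)
    if (length(beta) != 1) stop("'fit' must be a logistic_fit or one number")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (!is.null(se)) sort(c(beta - z * se, beta + z * se) / icc)
        else c(NA_real_, NA_real_)
  structure(list(method = "RCAL", beta_star = beta / icc, ci_star = ci,
                 or_star = exp(beta / icc),
                 calibration = list(icc = icc, level = level),
                 beta_naive = beta),
            class = "corrected_fit")
}

#' @export
print.corrected_fit <- function(x, ...) {
  cat("<corrected_fit> ", x$method,
      sprintf(": beta* = %.4g (naive %.4g), OR* = %.4g, CI (%.4g, %.4g)\n",
              x$beta_star, x$beta_naive, x$or_star,
              x$ci_star[1], x$ci_star[2]))
  invisible(x)
}

#' Wald standard error implied by a coefficient and its p-value
#'
#' Back-calculates `se = |beta| / z` from a two-sided Wald p-value. Useful
#' for reconstructing confidence intervals from reported coefficient /
#' p-value pairs.
#'
#' @param beta coefficient.
#' @param p two-sided Wald p-value in (0, 1).
#' @return the implied standard error.
#' @export
wald_se_from_p <- function(beta, p) {
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  abs(beta) / stats::qnorm(1 - p / 2)
}

#' SIMEX correction for a logistic slope
#'
#' Simulation-and-extrapolation for a single error-prone predictor with
#' known (classical, additive on the analysis scale) error variance
#' `sigma_w2`. For each `lambda` in the grid, `B` contaminated copies
#' `x + N(0, lambda * sigma_w2)` are refitted and the mean slope recorded;
#' the mean-slope trend over `lambda` (including the naive point at
#' `lambda = 0`) is then extrapolated to `lambda = -1` with a quadratic.
#' The Wald variance is extrapolated along the same path to form an
#' interval; if that extrapolation is not positive, the naive interval
#' width is rescaled by `|beta_star / beta|` instead.
#'
#' @param x error-prone predictor.
#' @param y binary outcome.
#' @param sigma_w2 measurement-error variance of `x` (>= 0; 0 returns the
#'   naive fit unchanged).
#' @param lambda positive contamination multipliers.
#' @param B refits per lambda (>= 2).
#' @param extrapolant only `"quadratic"` is implemented.
#' @param level confidence level.
#' @param seed optional RNG seed for the contamination draws.
#' @return a `corrected_fit` with `method = "SIMEX"`; `calibration` records
#'   `sigma_w2`, `lambda`, `B` and the extrapolant, and `lambda_curve`
#'   holds the mean slope per lambda.
#' @export
simex <- function(x, y, sigma_w2, lambda = c(0.5, 1, 1.5, 2), B = 100,
                  extrapolant = "quadratic", level = 0.95, seed = NULL) {
  extrapolant <- match.arg(extrapolant, "quadratic")
  if (sigma_w2 < 0) stop("'sigma_w2' must be >= 0")
  if (any(lambda <= 0)) stop("'lambda' grid must be positive")
  if (B < 2) stop("'B' must be >= 2")
  maybe_seed(seed)
  naive <- fit_logistic(x, y)
  if (!naive$converged) stop("naive fit did not converge; SIMEX aborted")
  b0 <- unname(fit_slope(naive))
  v0 <- unname(fit_slope_se(naive))^2
  if (sigma_w2 == 0) {
    return(structure(list(method = "SIMEX", beta_star = b0,
                          ci_star = b0 + c(-1, 1) *
                            stats::qnorm(1 - (1 - level) / 2) * sqrt(v0),
                          or_star = exp(b0),
                          calibration = list(sigma_w2 = 0, lambda = lambda,
                                             B = B, extrapolant = extrapolant),
                          beta_naive = b0,
                          lambda_curve = data.frame(lambda = 0, beta = b0)),
                     class = "corrected_fit"))
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  mean_beta <- mean_var <- numeric(length(lambda))
  for (i in seq_along(lambda)) {
    bs <- vs <- numeric(B)
    ok <- logical(B)
    for (b in seq_len(B)) {
      xb <- x + stats::rnorm(n, 0, sqrt(lambda[i] * sigma_w2))
      fb <- tryCatch(fit_logistic(xb, y), error = function(e) NULL)
      if (!is.null(fb) && fb$converged) {
        bs[b] <- unname(fit_slope(fb)); vs[b] <- unname(fit_slope_se(fb))^2
        ok[b] <- TRUE
      }
    }
    if (!all(ok))
      warning(sum(!ok), " non-convergent refit(s) dropped at lambda = ",
              lambda[i])
    if (!any(ok)) stop("all refits failed at lambda = ", lambda[i])
    mean_beta[i] <- mean(bs[ok]); mean_var[i] <- mean(vs[ok])
  }
  lam <- c(0, lambda)
  curve_beta <- c(b0, mean_beta)
  if (length(lam) < 3)
    stop("quadratic extrapolation needs at least 3 lambda points")
  beta_star <- simex_extrapolate(lam, curve_beta)
  var_star <- simex_extrapolate(lam, c(v0, mean_var))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.finite(var_star) && var_star > 0) {
    ci <- beta_star + c(-1, 1) * z * sqrt(var_star)
  } else {
    half <- z * sqrt(v0) * abs(beta_star / b0)
    ci <- beta_star + c(-1, 1) * half
  }
  structure(list(method = "SIMEX", beta_star = beta_star, ci_star = ci,
                 or_star = exp(beta_star),
                 calibration = list(sigma_w2 = sigma_w2, lambda = lambda,
                                    B = B, extrapolant = extrapolant),
                 beta_naive = b0,
                 lambda_curve = data.frame(lambda = lam, beta = curve_beta)),
            class = "corrected_fit")
}

#' Quadratic SIMEX extrapolation
#'
#' Fits `beta(lambda) = a + b*lambda + c*lambda^2` by least squares and
#' evaluates it at `lambda = -1` (the zero-measurement-error limit).
#'
#' @param lambda contamination levels (include 0 for the naive point).
#' @param beta mean coefficient at each level.
#' @return the extrapolated value at `lambda = -1`.
#' @export
simex_extrapolate <- function(lambda, beta) {
  if (length(lambda) < 3) stop("need at least 3 lambda points")
  co <- stats::lm.fit(cbind(1, lambda, lambda^2), beta)$coefficients
  sum(co * c(1, -1, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1),
#' with input validation.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Univariate measurement-error-corrected feature screen
#'
#' Fits, per feature, a one-predictor naive logistic model of outcome on
#' the log2 feature level, then corrects the slope by RCAL (using the
#' feature's ICC where available, otherwise the median ICC of the features
#' that have one) and by SIMEX (using the feature's within-subject variance
#' where available, otherwise the median). Benjamini-Hochberg adjustment is
#' applied across all successfully screened features. Degenerate features
#' (constant, separated, non-converged) are skipped and reported in the
#' `skipped` attribute.
#'
#' @param table a [feature_table] in state `"log2"` (sLMNLT).
#' @param groups a [assign_groups()] result (two-group scheme), or a binary
#'   outcome vector aligned with the table's samples.
#' @param icc per-feature ICC vector (NA where not estimable), or a single
#'   value used for all features.
#' @param sigma_w2 per-feature within-subject variances for SIMEX, or a
#'   single value; `NULL` skips SIMEX.
#' @param simex_B,simex_lambda SIMEX tuning (see [simex()]).
#' @param level confidence level.
#' @param seed RNG seed for the SIMEX draws.
#' @return a data frame of class `screen_result`, one row per screened
#'   feature: `mz`, `beta`, `se`, `or_`, `p`, `bh_p`, `icc_used`,
#'   `beta_star_rcal`, `rcal_lo`, `rcal_hi`, `or_rcal`, and (when SIMEX ran)
#'   `sigma_w2_used`, `beta_star_simex`, `simex_lo`, `simex_hi`, `or_simex`.
#' @export
univariate_screen <- function(table, groups, icc = NULL, sigma_w2 = NULL,
                              simex_B = 100, simex_lambda = c(0.5, 1, 1.5, 2),
                              level = 0.95, seed = NULL) {
  ft_require_state(table, "log2", "univariate screening")
  maybe_seed(seed)
  outcome <- if (inherits(groups, "group_assignment")) groups$outcome
             else as.integer(groups)
  if (length(outcome) != nrow(table$intensity))
    stop("outcome length does not match the number of samples")
  keep <- !is.na(outcome)
  y <- outcome[keep]
  p_feat <- length(table$mz)
  icc_vec <- if (is.null(icc)) rep(NA_real_, p_feat) else rep_len(icc, p_feat)
  icc_fallback <- stats::median(icc_vec, na.rm = TRUE)
  icc_used <- ifelse(is.na(icc_vec), icc_fallback, icc_vec)
  do_simex <- !is.null(sigma_w2)
  if (do_simex) {
    sw_vec <- rep_len(sigma_w2, p_feat)
    sw_used <- ifelse(is.na(sw_vec), stats::median(sw_vec, na.rm = TRUE),
                      sw_vec)
  }
  rows <- list()
  skipped <- character()
  for (j in seq_len(p_feat)) {
    xj <- table$intensity[keep, j]
    fit <- tryCatch(fit_logistic(xj, y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      skipped <- c(skipped, format_mz(table$mz[j]))
      next
    }
    row <- data.frame(mz = table$mz[j], beta = unname(fit_slope(fit)),
                      se = unname(fit_slope_se(fit)),
                      or_ = unname(exp(fit_slope(fit))),
                      p = unname(fit$wald_p[2]), icc_used = icc_used[j])
    if (!is.na(icc_used[j]) && icc_used[j] > 0) {
      rc <- rcal(fit, icc_used[j], level = level)
      row$beta_star_rcal <- rc$beta_star
      row$rcal_lo <- rc$ci_star[1]; row$rcal_hi <- rc$ci_star[2]
      row$or_rcal <- rc$or_star
    }
    if (do_simex) {
      sx <- tryCatch(simex(xj, y, sw_used[j], lambda = simex_lambda,
                           B = simex_B, level = level),
                     error = function(e) NULL)
      if (!is.null(sx)) {
        row$sigma_w2_used <- sw_used[j]
        row$beta_star_simex <- sx$beta_star
        row$simex_lo <- sx$ci_star[1]; row$simex_hi <- sx$ci_star[2]
        row$or_simex <- sx$or_star
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no screenable features")
  out <- do.call(rbind, rows)
  out$bh_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  if (length(skipped))
    message("skipped degenerate feature(s) at m/z: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Multivariate logistic fit of selected features
#'
#' Joint logistic regression of the outcome on a set of selected features,
#' with per-coefficient Wald tests. Requires more (non-excluded) samples
#' than coefficients; exactly collinear features (e.g. duplicates) raise an
#' error naming them.
#'
#' @param table a [feature_table] in state `"log2"`.
#' @param groups as in [univariate_screen()].
#' @param features m/z values of the features to include (matched exactly
#'   against `mz_values(table)`).
#' @return a [fit_logistic()] object with one named coefficient per feature.
#' @export
multivariate_fit <- function(table, groups, features) {
  ft_require_state(table, "log2", "multivariate fitting")
  if (!length(features)) stop("empty feature selection")
  idx <- match(features, table$mz)
  if (anyNA(idx))
    stop("feature(s) not in table: ",
         paste(features[is.na(idx)], collapse = ", "))
  outcome <- if (inherits(groups, "group_assignment")) groups$outcome
             else as.integer(groups)
  keep <- !is.na(outcome)
  X <- table$intensity[keep, idx, drop = FALSE]
  colnames(X) <- paste0("mz", format_mz(table$mz[idx]))
  if (sum(keep) <= ncol(X) + 1)
    stop("need more samples than coefficients (n = ", sum(keep),
         ", p = ", ncol(X) + 1, ")")
  fit_logistic(X, outcome[keep])
}
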