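#' Truncated-normal substitution expectations
#'
#' Fill values for left-censored log-scale data under a normal model
#' `Y ~ N(mu, sigma^2)` with censoring threshold `c`:
#' `richardson_ciampi_expectation()` is the conditional mean *below* the
#' threshold, `E(Y | Y < c) = mu - sigma * phi(a) / Phi(a)` with
#' `a = (c - mu) / sigma`; `schisterman_expectation()` is the conditional
#' mean *above* it, `E(Y | Y > c) = mu + sigma * phi(a) / (1 - Phi(a))`.
#' When the relevant tail probability underflows to zero, the threshold
#' itself is returned as a guard.
#'
#' @param c_log censoring threshold on the (log) analysis scale.
#' @param mu,sigma normal model parameters (`sigma > 0`).
#' @return the fill value (vectorized over `c_log`, `mu`, `sigma`).
#' @examples
#' richardson_ciampi_expectation(0, 0, 1)  # -sqrt(2/pi) = -0.7979
#' schisterman_expectation(0, 0, 1)        # +0.7979
#' @export
richardson_ciampi_expectation <- function(c_log, mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  a <- (c_log - mu) / sigma
  p <- stats::pnorm(a)
  out <- mu - sigma * stats::dnorm(a) / p
  bad <- p == 0 | !is.finite(out)
  if (any(bad)) out[bad] <- rep_len(c_log, length(out))[bad]
  out
}

#' @rdname richardson_ciampi_expectation
#' @export
schisterman_expectation <- function(c_log, mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  a <- (c_log - mu) / sigma
  p <- stats::pnorm(a, lower.tail = FALSE)
  out <- mu + sigma * stats::dnorm(a) / p
  bad <- p == 0 | !is.finite(out)
  if (any(bad)) out[bad] <- rep_len(c_log, length(out))[bad]
  out
}

#' Specification of an ICC reliability simulation
#'
#' Describes the Monte Carlo grid for assessing how reliably the one-way
#' ANOVA ICC estimates the true reliability when log-scale measurements
#' carry error of variance `sigma_eps2` and are left-censored at a limit of
#' detection. For each grid cell, `n_subjects` subjects with
#' `reps_per_subject` repeated log2-scale measurements
#' `y_ij = x_i + eps_ij`, `x_i ~ N(mu, sigma_b2)`,
#' `eps_ij ~ N(0, sigma_eps2)`, are simulated; values below the empirical
#' marginal quantile at the target censoring fraction are replaced per
#' strategy; and the ICC is re-estimated. The true reliability is
#' `sigma_b2 / (sigma_b2 + sigma_eps2)`.
#'
#' The default `sigma_b2 = 0.345` makes the uncensored ICC run from about
#' 0.97 down to 0.35 across the default error-variance grid
#' `0.01 ... 0.64`.
#'
#' @param sigma_eps2_grid measurement-error variances (log2 scale).
#' @param lod_fractions target censoring proportions in `[0, 1)`.
#' @param strategies subset of
#'   `c("richardson_ciampi", "schisterman", "zero", "lod_half")`.
#' @param sigma_b2 true between-subject variance.
#' @param mu log2 location of the features (the `zero` strategy's fill of 0
#'   is this many log2 units below a typical signal).
#' @param n_subjects,reps_per_subject design of each simulated dataset.
#' @param n_simulations Monte Carlo replicates per cell (>= 2).
#' @param seed RNG seed.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(sigma_eps2_grid = c(0.01, 0.04, 0.09, 0.16,
                                                0.25, 0.36, 0.49, 0.64),
                            lod_fractions = c(0.125, 0.25, 0.50),
                            strategies = lod_strategies(),
                            sigma_b2 = 0.345, mu = 5,
                            n_subjects = 20, reps_per_subject = 3,
                            n_simulations = 1000, seed = 1) {
  if (any(sigma_eps2_grid <= 0)) stop("sigma_eps2_grid must be positive")
  if (any(lod_fractions < 0 | lod_fractions >= 1))
    stop("lod_fractions must lie in [0, 1)")
  strategies <- match.arg(strategies, lod_strategies(), several.ok = TRUE)
  if (n_simulations < 2) stop("n_simulations must be >= 2")
  check_counts(n_subjects = n_subjects, reps_per_subject = reps_per_subject)
  structure(list(sigma_eps2_grid = sigma_eps2_grid,
                 lod_fractions = lod_fractions, strategies = strategies,
                 sigma_b2 = check_var(sigma_b2, "sigma_b2"), mu = mu,
                 n_subjects = as.integer(n_subjects),
                 reps_per_subject = as.integer(reps_per_subject),
                 n_simulations = as.integer(n_simulations), seed = seed),
            class = "simulation_spec")
}

## fast balanced one-way ICC on an n x r matrix of log-scale values
icc_oneway_matrix <- function(y) {
  n <- nrow(y); r <- ncol(y)
  mi <- rowMeans(y)
  msb <- r * sum((mi - mean(mi))^2) / (n - 1)
  msw <- sum((y - mi)^2) / (n * (r - 1))
  sb2 <- max(0, (msb - msw) / r)
  if (sb2 == 0) 0 else sb2 / (sb2 + msw)
}

#' Monte Carlo study of ICC reliability under LOD censoring
#'
#' Runs the simulation described by a [simulation_spec()]. Within each
#' error-variance level the same simulated datasets are reused across
#' censoring fractions and strategies, so strategy comparisons are paired.
#' An uncensored reference estimate (strategy `"none"`, fraction 0) is
#' always included.
#'
#' Substitution happens on the log2 analysis scale: `lod_half` fills with
#' `c - 1` (half the LOD intensity is one log2 unit below it), `zero` fills
#' with 0 (the log2 of unit intensity — the zero strategy's pathology of
#' non-positive raw values is handled by estimating on the already-log
#' scale), and the two conditional-mean strategies use plug-in normal
#' parameters estimated from the uncensored part of each dataset.
#'
#' @param spec a [simulation_spec()].
#' @return a data frame of class `icc_simulation` with columns
#'   `sigma_eps2`, `fraction`, `strategy`, `mean_icc`, `mc_se` (standard
#'   error of the mean over replicates), `mc_sd` (sampling SD of the
#'   estimator), `true_icc`, `n_simulations`.
#' @export
simulate_icc_reliability <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  maybe_seed(spec$seed)
  n <- spec$n_subjects; r <- spec$reps_per_subject
  cells <- expand.grid(fraction = spec$lod_fractions,
                       strategy = spec$strategies,
                       stringsAsFactors = FALSE)
  cells <- rbind(data.frame(fraction = 0, strategy = "none"), cells)
  res <- list()
  for (s2 in spec$sigma_eps2_grid) {
    draws <- matrix(NA_real_, spec$n_simulations, nrow(cells))
    for (sim in seq_len(spec$n_simulations)) {
      x <- stats::rnorm(n, spec$mu, sqrt(spec$sigma_b2))
      y <- matrix(x, n, r) + matrix(stats::rnorm(n * r, 0, sqrt(s2)), n, r)
      for (ci in seq_len(nrow(cells))) {
        draws[sim, ci] <- icc_oneway_matrix(
          censor_and_fill(y, cells$fraction[ci], cells$strategy[ci]))
      }
    }
    res[[length(res) + 1]] <- data.frame(
      sigma_eps2 = s2, fraction = cells$fraction, strategy = cells$strategy,
      mean_icc = colMeans(draws),
      mc_se = apply(draws, 2, stats::sd) / sqrt(spec$n_simulations),
      mc_sd = apply(draws, 2, stats::sd),
      true_icc = spec$sigma_b2 / (spec$sigma_b2 + s2),
      n_simulations = spec$n_simulations)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("icc_simulation", "data.frame")
  out
}

## censor the lowest `fraction` of values at the empirical quantile and
## substitute per strategy (log2 scale)
censor_and_fill <- function(y, fraction, strategy) {
  if (fraction <= 0 || strategy == "none") return(y)
  cc <- stats::quantile(y, fraction, names = FALSE)
  cens <- y < cc
  if (!any(cens)) return(y)
  obs <- y[!cens]
  fill <- switch(strategy,
    lod_half = cc - 1,
    zero = 0,
    richardson_ciampi =
      if (length(obs) >= 2 && stats::sd(obs) > 0)
        richardson_ciampi_expectation(cc, mean(obs), stats::sd(obs)) else cc,
    schisterman =
      if (length(obs) >= 2 && stats::sd(obs) > 0)
        schisterman_expectation(cc, mean(obs), stats::sd(obs)) else cc,
    stop("unknown strategy: ", strategy))
  y[cens] <- fill
  y
}

#' @export
print.icc_simulation <- function(x, ...) {
  cat("<icc_simulation> ", length(unique(x$sigma_eps2)),
      " error levels x ", length(unique(x$fraction)),
      " censoring fractions x ", length(unique(x$strategy)),
      " strategies (", x$n_simulations[1], " replicates)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 3)
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more rows\n")
  invisible(x)
}

#' Plot an ICC reliability simulation
#'
#' One panel per censoring fraction: mean estimated ICC against
#' measurement-error variance, one line per substitution strategy, with the
#' true reliability as a dashed reference.
#'
#' @param x an `icc_simulation` result.
#' @param ... ignored.
#' @export
plot.icc_simulation <- function(x, ...) {
  fr <- sort(unique(x$fraction[x$strategy != "none"]))
  strategies <- unique(x$strategy[x$strategy != "none"])
  old <- graphics::par(mfrow = c(1, max(1, length(fr))))
  on.exit(graphics::par(old))
  for (f in fr) {
    sub <- x[x$fraction == f, ]
    graphics::plot(NA, xlim = range(x$sigma_eps2), ylim = c(0, 1),
                   xlab = expression(sigma[epsilon]^2), ylab = "mean ICC",
                   main = paste0(100 * f, "% below LOD"))
    graphics::lines(sort(unique(x$sigma_eps2)),
                    x$true_icc[x$strategy == "none"][order(x$sigma_eps2[x$strategy == "none"])],
                    lty = 2)
    for (i in seq_along(strategies)) {
      s <- sub[sub$strategy == strategies[i], ]
      graphics::lines(s$sigma_eps2, s$mean_icc, col = i + 1, lwd = 2)
    }
    if (f == fr[1])
      graphics::legend("bottomleft", legend = c("true", strategies),
                       col = c(1, seq_along(strategies) + 1),
                       lty = c(2, rep(1, length(strategies))), cex = 0.7)
  }
  invisible(x)
}
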