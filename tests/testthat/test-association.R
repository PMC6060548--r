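test_that("histology labels map onto the analysis groups", {
  ph <- data.frame(histology = cohort_histology())
  g2 <- assign_groups(ph, "two_group")
  expect_equal(unname(g2$counts),
               c(57 + 7 + 12, 55 + 4 + 11, 2))  # 76 vs 70, 2 excluded
  expect_equal(sum(is.na(g2$outcome)), 2)
  g4 <- assign_groups(ph, "four_group")
  expect_equal(unname(g4$counts[c("A", "B", "C", "D")]), c(57, 19, 15, 55))
  all_pca <- assign_groups(data.frame(histology = rep("PCa", 5)), "two_group")
  expect_equal(unname(all_pca$outcome), rep(1L, 5))
  expect_error(assign_groups(data.frame(histology = "carcinoma")),
               "unknown histology")
})

test_that("logistic fits reproduce 2x2 closed forms", {
  # balanced table: no association
  x0 <- rep(c(1, 0), each = 20)
  y0 <- rep(c(1, 0, 1, 0), each = 10)
  expect_equal(unname(fit_logistic(x0, y0)$beta[2]), 0, tolerance = 1e-8)
  # a=20, b=10, c=10, d=20: beta = log(ad/bc) = log 4
  x1 <- c(rep(1, 30), rep(0, 30))
  y1 <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(x1, y1)
  expect_equal(unname(fit$beta[2]), log(4), tolerance = 1e-7)
  expect_equal(unname(fit$or_[2]), 4, tolerance = 1e-6)
  # Wald SE of a 2x2 log odds ratio: sqrt(sum of reciprocal cells)
  expect_equal(unname(fit$se[2]), sqrt(1/20 + 1/10 + 1/10 + 1/20),
               tolerance = 1e-6)
})

test_that("degenerate logistic inputs are flagged or rejected", {
  # complete separation: x = -1 for controls, +1 for cases
  sep <- fit_logistic(rep(c(-1, 1), each = 10), rep(c(0, 1), each = 10))
  expect_false(sep$converged)
  expect_error(fit_logistic(rep(1, 10), rbinom(10, 1, 0.5)), "constant")
  expect_error(fit_logistic(rnorm(10), rep(1, 10)), "both outcome classes")
  expect_error(rcal(sep, 0.5), "non-converged")
})

test_that("RCAL reproduces the worked-example coefficient tables", {
  ur <- screen_worked_example("urine")
  for (i in seq_len(nrow(ur))) {
    rc <- rcal(ur$beta[i], ur$icc[i],
               se = wald_se_from_p(ur$beta[i], ur$wald_p[i]))
    # coefficients printed to 3 decimals; intervals reconstructed from the
    # 2-3 significant digit p-values carry a little more rounding
    expect_lt(abs(rc$beta_star - ur$rcal_beta_star[i]), 0.003)
    expect_lt(abs(rc$ci_star[1] - ur$rcal_lo[i]), 0.025)
    expect_lt(abs(rc$ci_star[2] - ur$rcal_hi[i]), 0.025)
  }
  se <- screen_worked_example("serum")
  # inputs printed to 2 decimals: |error| <= 0.005/icc + 0.005 < 0.015
  expect_lt(max(abs(se$rcal_beta_star - se$beta / se$icc)), 0.015)
  # the two aligned features sharing rounded m/z 1418.6 diverge only
  # through their reliability coefficients
  twin <- se[se$mz == 1418.6, ]
  expect_equal(twin$beta[1], twin$beta[2])
  expect_false(twin$icc[1] == twin$icc[2])
})

test_that("RCAL divides coefficient and interval by the ICC", {
  fit <- fit_logistic(rnorm(100), rbinom(100, 1, 0.5))
  rc <- rcal(fit, 0.5)
  expect_equal(rc$beta_star, unname(fit$beta[2]) / 0.5)
  expect_equal(rc$or_star, exp(rc$beta_star))
  expect_true(abs(rc$beta_star) >= abs(unname(fit$beta[2])))
  id <- rcal(fit, 1)
  expect_equal(id$beta_star, unname(fit$beta[2]))  # ICC 1: identity
  expect_error(rcal(fit, 0), "\\(0, 1\\]")
  expect_error(rcal(fit, 1.2), "\\(0, 1\\]")
})

test_that("SIMEX extrapolation and degenerate error variance are exact", {
  lam <- c(0, 0.5, 1, 1.5, 2)
  expect_equal(simex_extrapolate(lam, 1 + lam + lam^2), 1, tolerance = 1e-10)
  expect_error(simex_extrapolate(c(0, 1), c(1, 2)), "at least 3")
  set.seed(2)
  x <- rnorm(300); y <- rbinom(300, 1, plogis(x))
  sx <- simex(x, y, sigma_w2 = 0, seed = 1)
  expect_equal(sx$beta_star, unname(fit_logistic(x, y)$beta[2]))
})

test_that("SIMEX pushes an attenuated slope back toward the truth", {
  set.seed(10)
  n <- 1500
  xt <- rnorm(n)                      # true exposure, ICC = 1/(1+0.6)
  w <- xt + rnorm(n, 0, sqrt(0.6))
  y <- rbinom(n, 1, plogis(xt))
  naive <- unname(fit_logistic(w, y)$beta[2])
  sx <- simex(w, y, sigma_w2 = 0.6, B = 50, seed = 11)
  expect_gt(sx$beta_star, naive)
  expect_lt(abs(sx$beta_star - 1), abs(naive - 1))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  # monotone and capped at 1
  p <- c(0.001, 0.5, 0.9, 0.9999)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a single-feature screen reduces to fit + RCAL", {
  cc <- generate_case_control_study(case_control_design(
    n_cases = 80, n_controls = 80, n_features = 1, beta_true = 0.8,
    seed = 19))
  # a one-feature spectrum has itself as median, so skip that step
  tab <- log2_transform(cc$features)
  g <- assign_groups(cc$phenotypes)
  scr <- univariate_screen(tab, g, icc = 0.6, seed = 1)
  expect_equal(nrow(scr), 1)
  keep <- !is.na(g$outcome)
  fit <- fit_logistic(intensities(tab)[keep, 1], g$outcome[keep])
  expect_equal(scr$beta, unname(fit$beta[2]))
  expect_equal(scr$beta_star_rcal, rcal(fit, 0.6)$beta_star)
  expect_equal(scr$bh_p, scr$p)  # single test: BH is the identity
})

test_that("screens fall back to the median ICC and skip degenerate features", {
  cc <- generate_case_control_study(case_control_design(
    n_cases = 70, n_controls = 70, n_features = 4,
    beta_true = c(1, 0, 0, 0), seed = 23))
  tab <- log2_transform(median_normalize(cc$features))
  g <- assign_groups(cc$phenotypes)
  icc <- c(0.4, NA, 0.6, NA)  # NAs take median of the rest = 0.5
  scr <- univariate_screen(tab, g, icc = icc)
  expect_equal(scr$icc_used, c(0.4, 0.5, 0.6, 0.5))
  expect_equal(scr$bh_p, bh_adjust(scr$p))
  # a constant feature cannot be fitted and is reported as skipped
  broken <- tab
  broken$intensity[, 2] <- 3
  expect_message(scr2 <- univariate_screen(broken, g, icc = 0.5),
                 "skipped degenerate")
  expect_equal(nrow(scr2), 3)
})

test_that("multivariate fits handle orthogonal and collinear selections", {
  set.seed(5)
  n <- 400
  x1 <- rep(c(-1, 1), n / 2)          # orthogonal coded predictors
  x2 <- rep(c(-1, 1), each = n / 2)
  y <- rbinom(n, 1, plogis(0.7 * x1 - 0.4 * x2))
  tab <- feature_table(cbind(x1, x2), c(1500, 2500),
                       data.frame(sample_id = sprintf("s%03d", 1:n)),
                       state = "log2")
  mv <- multivariate_fit(tab, y, features = c(1500, 2500))
  uni1 <- fit_logistic(x1, y)
  expect_equal(unname(mv$beta[2]), unname(uni1$beta[2]), tolerance = 0.1)
  expect_error(multivariate_fit(tab, y, features = c(1500, 1500)),
               "collinear")
  expect_error(multivariate_fit(tab, y, features = numeric(0)), "empty")
  expect_error(multivariate_fit(tab, y, features = 999), "not in table")
  small <- feature_table(cbind(x1, x2)[1:3, ], c(1500, 2500),
                         data.frame(sample_id = c("a", "b", "c")),
                         state = "log2")
  expect_error(multivariate_fit(small, y[1:3], c(1500, 2500)),
               "more samples than coefficients")
})
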