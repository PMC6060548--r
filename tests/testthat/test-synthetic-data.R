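test_that("design constructors validate counts and variances", {
  expect_error(repeatability_design(n_subjects = 0), "positive integer")
  expect_error(repeatability_design(sigma_w2 = -1), ">= 0")
  expect_error(precision_design(n_runs = 1.5), "positive integer")
  expect_error(case_control_design(beta_true = Inf), "finite")
  d <- repeatability_design(n_subjects = 3, samples_per_subject = c(2, 3),
                            n_features = 2)
  expect_length(d$samples_per_subject, 3)  # recycled
  expect_length(d$mu, 2)
})

test_that("generators are deterministic for a fixed seed", {
  d <- repeatability_design(n_subjects = 5, n_features = 4, seed = 11)
  expect_identical(intensities(generate_repeatability_study(d)),
                   intensities(generate_repeatability_study(d)))
  p <- precision_design(n_features = 2, seed = 11)
  expect_identical(intensities(generate_precision_study(p)),
                   intensities(generate_precision_study(p)))
  cd <- case_control_design(n_features = 2, seed = 11)
  expect_identical(intensities(generate_case_control_study(cd)$features),
                   intensities(generate_case_control_study(cd)$features))
})

test_that("no within-subject variance collapses a subject's samples", {
  d <- repeatability_design(n_subjects = 4, samples_per_subject = 3,
                            spots_per_sample = 1, n_features = 2,
                            sigma_w2 = 0, seed = 2)
  ft <- generate_repeatability_study(d)
  vals <- intensities(ft)
  for (s in unique(sample_info(ft)$subject_id)) {
    rows <- vals[sample_info(ft)$subject_id == s, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }
})

test_that("generated variance structure reproduces the design ICC", {
  # sigma_b2 = sigma_w2 = 1 over 200 subjects x 2, pooled over 20
  # independent features: mean ANOVA ICC ~ 0.5
  d <- repeatability_design(n_subjects = 200, samples_per_subject = 2,
                            spots_per_sample = 1, n_features = 20,
                            sigma_b2 = 1, sigma_w2 = 1, seed = 31)
  ft <- generate_repeatability_study(d)
  subj <- sample_info(ft)$subject_id
  iccs <- apply(log2(intensities(ft)), 2, function(y)
    variance_components(y, subj)$icc)
  expect_lt(abs(mean(iccs) - 0.5), 0.05)
  # and the estimator agrees with the aov route on the same data
  y <- log2(intensities(ft))[, 1]
  vc <- variance_components(y, subj)
  oracle <- aov_components(y, subj)
  expect_equal(vc$icc, oracle$icc, tolerance = 1e-10)
  expect_equal(vc$sigma_b2, oracle$sigma_b2, tolerance = 1e-10)
})

test_that("variance-component estimates are unbiased over replicates", {
  est <- t(replicate(150, {
    d <- repeatability_design(n_subjects = 30, samples_per_subject = 2,
                              spots_per_sample = 1, n_features = 1,
                              sigma_b2 = 0.4, sigma_w2 = 0.2, seed = NULL)
    ft <- generate_repeatability_study(d)
    vc <- variance_components(log2(intensities(ft))[, 1],
                              sample_info(ft)$subject_id)
    c(vc$sigma_b2, vc$sigma_w2)
  }))
  for (k in 1:2) {
    mc_se <- sd(est[, k]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, k]) - c(0.4, 0.2)[k]), 3 * mc_se)
  }
})

test_that("precision generator matches its nested ANOVA summaries", {
  # both variances zero: every log2 intensity equals mu
  p0 <- precision_design(n_features = 2, sigma_run2 = 0, sigma_rep2 = 0,
                         mu = 5, seed = 3)
  expect_equal(unname(log2(intensities(generate_precision_study(p0)))),
               matrix(5, 25, 2))
  cv0 <- assay_cv(generate_precision_study(p0))
  expect_equal(cv0$intra_cv, c(0, 0))
  expect_equal(cv0$inter_cv, c(0, 0))
  # no run effect: intra and inter CV agree within Monte Carlo error
  reps <- t(replicate(60, {
    p <- precision_design(n_runs = 5, reps_per_run = 5, n_features = 1,
                          sigma_run2 = 0, sigma_rep2 = 0.1, seed = NULL)
    cv <- assay_cv(generate_precision_study(p))
    c(cv$intra_cv, cv$inter_cv)
  }))
  expect_lt(abs(mean(reps[, 2] - reps[, 1])), 2)  # CV percentage points
})

test_that("case-control observation model censors and attenuates", {
  cd <- case_control_design(n_cases = 150, n_controls = 150, n_features = 1,
                            beta_true = 1, sigma_b2 = 0.5, sigma_w2 = 0,
                            slod = 0, seed = 5)
  cc <- generate_case_control_study(cd)
  expect_false(any(below_lod_flags(cc$features)))  # slod = 0: nothing censored
  # sigma_w2 = 0: the naive slope recovers beta_true within its Wald CI
  y <- cc$phenotypes$outcome
  x <- log2(intensities(cc$features))[, 1]
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$beta[2] - 1), 1.96 * fit$se[2])
  # target-fraction censoring lands at the requested quantile
  cdf <- case_control_design(n_cases = 200, n_controls = 200,
                             slod = list(fraction = 0.25), seed = 6)
  ccf <- generate_case_control_study(cdf)
  expect_equal(mean(below_lod_flags(ccf$features)), 0.25, tolerance = 0.01)
})

test_that("an infeasible prevalence raises a degenerate-outcome error", {
  cd <- case_control_design(n_cases = 10, n_controls = 10,
                            alpha_true = -60, beta_true = 0, seed = 1)
  expect_error(generate_case_control_study(cd), "degenerate outcome")
})

test_that("null features keep the naive type-I error near nominal", {
  pvals <- replicate(200, {
    cc <- generate_case_control_study(case_control_design(
      n_cases = 60, n_controls = 60, n_features = 1, beta_true = 0,
      sigma_w2 = 0.2, seed = NULL))
    fit_logistic(log2(intensities(cc$features))[, 1],
                 cc$phenotypes$outcome)$wald_p[2]
  })
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
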