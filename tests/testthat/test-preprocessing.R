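test_that("the sLOD rule is mean + k * SD of the noise", {
  expect_equal(estimate_slod(c(4, 4, 4))$slod, 4)  # zero spread
  expect_equal(estimate_slod(c(1, 2, 3), k = 3)$slod, 5)
  set.seed(8)
  noise <- pmax(0, rnorm(5000, 10, 2))
  expect_equal(estimate_slod(noise, k = 3)$slod, 16, tolerance = 0.02)
  expect_error(estimate_slod(numeric(0)), "at least 2")
  expect_error(estimate_slod(5), "at least 2")
})

test_that("below-LOD substitution fills flagged cells only", {
  ft <- toy_table(intensity = matrix(c(1, 40, 60, 80, 3, 120), 2, 3,
                                     byrow = TRUE))
  adj <- substitute_below_lod(ft, lod_model(10, "lod_half"))
  expect_equal(unname(intensities(adj)[1, 1]), 5)   # slod / 2
  expect_equal(unname(intensities(adj)[2, 2]), 5)
  expect_equal(sum(below_lod_flags(adj)), 2)
  # uncensored entries never altered; changed-cell count equals flag count
  changed <- intensities(adj) != intensities(ft)
  expect_equal(unname(changed), unname(below_lod_flags(adj)))
  z <- substitute_below_lod(ft, lod_model(10, "zero"))
  expect_equal(unname(intensities(z)[1, 1]), 0)
  expect_error(lod_model(10, "winsorize"), "arg")
  expect_error(lod_model(-1), "positive")
})

test_that("conditional-mean strategies fill from the truncated normal", {
  set.seed(42)
  vals <- 2^rnorm(400, mean = 6, sd = 1)
  ft <- feature_table(matrix(vals, ncol = 1), 1500,
                      data.frame(sample_id = paste0("s", 1:400)))
  slod <- 2^5  # censors the lower tail
  rc <- substitute_below_lod(ft, lod_model(slod, "richardson_ciampi"))
  filled <- log2(intensities(rc)[below_lod_flags(rc)])
  obs <- log2(vals[vals >= slod])
  expected <- richardson_ciampi_expectation(5, mean(obs), sd(obs))
  expect_equal(unique(round(filled, 10)), round(expected, 10))
  expect_true(all(filled < 5))  # fill sits below the threshold
  sch <- substitute_below_lod(ft, lod_model(slod, "schisterman"))
  expect_true(all(log2(intensities(sch)[below_lod_flags(sch)]) > 5))
})

test_that("median normalization gives unit medians and is scale-equivariant", {
  ft <- toy_table(intensity = matrix(c(2, 4, 6, 7, 7, 7), 2, 3, byrow = TRUE))
  mn <- median_normalize(ft)
  expect_equal(unname(intensities(mn)[1, ]), c(0.5, 1, 1.5))
  expect_equal(unname(intensities(mn)[2, ]), c(1, 1, 1))
  set.seed(9)
  rnd <- toy_table(intensity = matrix(rexp(30) + 0.1, 10, 3),
                   samples = data.frame(sample_id = paste0("s", 1:10)))
  expect_equal(unname(apply(intensities(median_normalize(rnd)), 1, median)),
               rep(1, 10))
  scaled <- toy_table(intensity = intensities(rnd) * c(3, rep(1, 9)),
                      samples = sample_info(rnd))
  expect_equal(intensities(median_normalize(scaled)),
               intensities(median_normalize(rnd)))
  zero <- toy_table(intensity = matrix(0, 1, 3),
                    samples = data.frame(sample_id = "bad"))
  expect_error(median_normalize(zero), "bad")
})

test_that("creatinine normalization rescales per sample", {
  ft <- toy_table(intensity = matrix(c(10, 20, 30, 8, 16, 24), 2, 3,
                                     byrow = TRUE))
  cn <- creatinine_normalize(ft, c(5, 1))
  expect_equal(unname(intensities(cn)[1, ]), c(2, 4, 6))
  expect_equal(unname(intensities(cn)[2, ]), c(8, 16, 24))  # creatinine 1
  # within-sample relative intensities unchanged
  expect_equal(intensities(cn)[1, ] / intensities(cn)[1, 1],
               intensities(ft)[1, ] / intensities(ft)[1, 1])
  expect_error(creatinine_normalize(ft, c(5, 0)), "s2")
  expect_error(creatinine_normalize(ft), "none in the sample metadata")
})

test_that("log2 transform is entrywise and guards non-positive input", {
  ft <- toy_table(intensity = matrix(c(8, 1, 2, 4, 16, 32), 2, 3))
  lg <- log2_transform(median_normalize(ft))
  expect_equal(unname(intensities(lg)),
               unname(log2(intensities(median_normalize(ft)))))
  z <- substitute_below_lod(toy_table(), lod_model(3, "zero"))
  expect_error(log2_transform(median_normalize(z)), "strictly positive")
})

test_that("slmnlt equals the manual substitution/median/log2 chain", {
  ft <- toy_table(intensity = matrix(c(1, 40, 60, 80, 100, 120), 2, 3,
                                     byrow = TRUE))
  lod <- lod_model(10, "lod_half")
  auto <- slmnlt(ft, lod)
  manual <- log2_transform(median_normalize(substitute_below_lod(ft, lod)))
  expect_equal(intensities(auto), intensities(manual))
  expect_identical(ft_state(auto), "log2")
  # hand arithmetic on the first sample: (5, 40, 60) / 40 -> log2
  expect_equal(unname(intensities(auto)[1, ]), log2(c(5, 40, 60) / 40))
  # a censoring-free table reduces to median normalization + log2
  clean <- toy_table(intensity = matrix(c(20, 40, 60, 80, 100, 120), 2, 3,
                                        byrow = TRUE))
  expect_equal(intensities(slmnlt(clean, lod)),
               intensities(log2_transform(median_normalize(clean))))
})

test_that("m/z matching is one-to-one within tolerance", {
  expect_equal(nrow(match_features(1000.0, 1000.2)), 1)
  expect_equal(nrow(match_features(1000.0, 1000.4)), 0)
  expect_error(match_features(c(2, 1), c(1, 2)), "sorted")
  # jittered copy of 20 features matches completely
  set.seed(4)
  a <- sort(runif(20, 1000, 4000))
  b <- sort(a + runif(20, -0.14, 0.14))
  m <- match_features(a, b)
  expect_equal(nrow(m), 20)
  expect_true(all(m$delta <= 0.3))
  expect_false(anyDuplicated(m$index_a) > 0)
  expect_false(anyDuplicated(m$index_b) > 0)
  # ties broken by smallest delta, then lower m/z
  tie <- match_features(1000.0, c(999.8, 1000.2))
  expect_equal(tie$index_b, 1)
})
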