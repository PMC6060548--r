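# shared fixtures and independent oracles

toy_table <- function(intensity = matrix(c(2, 4, 6, 8, 10, 12), 2, 3,
                                         byrow = TRUE),
                      mz = c(1000.1, 2000.2, 3000.3),
                      samples = NULL, ...) {
  if (is.null(samples))
    samples <- data.frame(sample_id = paste0("s", seq_len(nrow(intensity))))
  feature_table(intensity, mz, samples, ...)
}

# exhaustive concordant-pair AUC oracle (ties count one half)
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# one-way variance components via stats::aov, as an independent route
aov_components <- function(values, subject) {
  subject <- factor(subject)
  tab <- anova(aov(values ~ subject))
  msb <- tab$`Mean Sq`[1]
  msw <- tab$`Mean Sq`[2]
  ni <- tabulate(subject)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / (length(ni) - 1)
  sb2 <- max(0, (msb - msw) / n0)
  list(sigma_b2 = sb2, sigma_w2 = msw, icc = sb2 / (sb2 + msw))
}

# histology vector with the canonical biopsy-cohort composition
cohort_histology <- function() {
  rep(c("no alteration", "BPH", "inflammation", "AAH",
        "ASAP", "HGPIN", "PCa"),
      times = c(57, 7, 12, 2, 11, 4, 55))
}
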