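#' Designs for synthetic peptidomic studies
#'
#' Constructors for the three study designs the generator understands. All
#' variance parameters live on the log2 intensity scale, so additive normal
#' error there corresponds to multiplicative (log-normal) error on the raw
#' intensity scale — the error model appropriate for MALDI-TOF/MS feature
#' signals.
#'
#' `repeatability_design()` describes a biological repeatability study:
#' serial samples per subject, each spotted several times. Defaults mirror a
#' urinary study of 20 healthy donors (16 subjects with 2 serial samples,
#' 4 with 3, quintuplicate spots) with a median within-subject variance of
#' 0.184 log2 units and an ICC of 0.48, from which the between-subject
#' variance follows as `icc / (1 - icc) * sigma_w2`.
#'
#' `precision_design()` describes an analytical precision study of a pooled
#' specimen measured in `reps_per_run` replicates over `n_runs` runs (the
#' classical 5 x 5 design). Default variance components correspond to a
#' median intra-assay CV of about 25% and inter-assay CV of about 36% on
#' the intensity scale.
#'
#' `case_control_design()` describes a case-control cohort whose binary
#' disease status is driven by the *true* (error-free) subject-level feature
#' values through a logistic model — the classical-error assumption that
#' regression calibration and SIMEX require. Observed values add
#' within-subject noise and are left-censored below `slod`. When
#' `alpha_true` is `NULL` it is chosen so that the expected prevalence at
#' the feature location equals `n_cases / (n_cases + n_controls)`.
#'
#' @param n_subjects number of subjects.
#' @param samples_per_subject integer vector of serial samples per subject
#'   (unbalanced designs allowed); recycled to `n_subjects`.
#' @param spots_per_sample technical spot replicates per sample.
#' @param n_features number of features.
#' @param mu per-feature log2 location (recycled to `n_features`).
#' @param sigma_b2,sigma_w2 per-feature between- and within-subject
#'   variances on the log2 scale (recycled).
#' @param sigma_spot2 spot-to-spot variance on the log2 scale (recycled);
#'   0 makes the spots of a sample identical.
#' @param seed RNG seed used by the paired generator.
#' @return a design object (`repeatability_design`, `precision_design` or
#'   `case_control_design`).
#' @name designs
#' @examples
#' d <- repeatability_design(n_subjects = 4, n_features = 2, seed = 1)
#' generate_repeatability_study(d)
NULL

#' @rdname designs
#' @export
repeatability_design <- function(n_subjects = 20,
                                 samples_per_subject = c(rep(2L, 16), rep(3L, 4)),
                                 spots_per_sample = 5,
                                 n_features = 10,
                                 mu = 5,
                                 sigma_b2 = 0.48 / 0.52 * 0.184,
                                 sigma_w2 = 0.184,
                                 sigma_spot2 = 0,
                                 seed = NULL) {
  check_counts(n_subjects = n_subjects, spots_per_sample = spots_per_sample,
               n_features = n_features)
  samples_per_subject <- rep_len(as.integer(samples_per_subject), n_subjects)
  if (any(samples_per_subject < 1))
    stop("invalid design: samples_per_subject must be >= 1")
  d <- list(n_subjects = as.integer(n_subjects),
            samples_per_subject = samples_per_subject,
            spots_per_sample = as.integer(spots_per_sample),
            n_features = as.integer(n_features),
            mu = rep_len(as.numeric(mu), n_features),
            sigma_b2 = check_var(rep_len(sigma_b2, n_features), "sigma_b2"),
            sigma_w2 = check_var(rep_len(sigma_w2, n_features), "sigma_w2"),
            sigma_spot2 = check_var(rep_len(sigma_spot2, n_features), "sigma_spot2"),
            seed = seed)
  structure(d, class = "repeatability_design")
}

#' @rdname designs
#' @param n_runs,reps_per_run runs (e.g. days) and within-run replicates.
#' @param sigma_run2,sigma_rep2 between-run and within-run variance on the
#'   log2 scale.
#' @export
precision_design <- function(n_runs = 5, reps_per_run = 5,
                             n_features = 14, mu = 5,
                             sigma_run2 = 0.124, sigma_rep2 = 0.126,
                             seed = NULL) {
  check_counts(n_runs = n_runs, reps_per_run = reps_per_run,
               n_features = n_features)
  d <- list(n_runs = as.integer(n_runs),
            reps_per_run = as.integer(reps_per_run),
            n_features = as.integer(n_features),
            mu = rep_len(as.numeric(mu), n_features),
            sigma_run2 = check_var(rep_len(sigma_run2, n_features), "sigma_run2"),
            sigma_rep2 = check_var(rep_len(sigma_rep2, n_features), "sigma_rep2"),
            seed = seed)
  structure(d, class = "precision_design")
}

#' @rdname designs
#' @param n_cases,n_controls target case and control counts; the generator
#'   simulates `n_cases + n_controls` subjects and draws disease status from
#'   the logistic model, so realized counts vary by sampling error.
#' @param beta_true per-feature log-odds effect of the true log2 level.
#' @param alpha_true logistic intercept; `NULL` targets the design prevalence.
#' @param slod censoring threshold on the intensity scale (0 disables), or a
#'   target censoring fraction given as `list(fraction = f)` which places the
#'   threshold at the marginal intensity quantile `f`.
#' @param aah_rate probability that a subject is labelled with the atypical
#'   adenomatous hyperplasia (AAH) histology, which downstream group
#'   assignment excludes.
#' @export
case_control_design <- function(n_cases = 70, n_controls = 76,
                                n_features = 1, mu = 5,
                                sigma_b2 = 0.48 / 0.52 * 0.184,
                                sigma_w2 = 0.184,
                                beta_true = 1, alpha_true = NULL,
                                slod = 0, aah_rate = 2 / 148,
                                seed = NULL) {
  check_counts(n_cases = n_cases, n_controls = n_controls,
               n_features = n_features)
  beta_true <- rep_len(as.numeric(beta_true), n_features)
  if (any(!is.finite(beta_true))) stop("invalid design: beta_true must be finite")
  d <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
            n_features = as.integer(n_features),
            mu = rep_len(as.numeric(mu), n_features),
            sigma_b2 = check_var(rep_len(sigma_b2, n_features), "sigma_b2"),
            sigma_w2 = check_var(rep_len(sigma_w2, n_features), "sigma_w2"),
            beta_true = beta_true, alpha_true = alpha_true,
            slod = slod, aah_rate = aah_rate, seed = seed)
  structure(d, class = "case_control_design")
}

check_counts <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (length(v) != 1 || is.na(v) || v < 1 || v != as.integer(v))
      stop("invalid design: '", nm, "' must be a positive integer count")
  }
}

check_var <- function(v, nm) {
  v <- as.numeric(v)
  if (any(is.na(v) | v < 0)) stop("invalid design: '", nm, "' must be >= 0")
  v
}

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Generate a repeatability study feature table
#'
#' Simulates log2-scale feature values `x_i + e_ij (+ spot noise)` with
#' subject effects `x_i ~ N(mu, sigma_b2)` and sample effects
#' `e_ij ~ N(0, sigma_w2)`, then returns raw-scale intensities `2^value`
#' (the multiplicative error model). One table row per spot.
#'
#' @param design a [repeatability_design()].
#' @return a [feature_table] in state `"raw"` with columns `subject_id`,
#'   `run_id` (serial-sample index) and `spot_id` in its metadata.
#' @export
generate_repeatability_study <- function(design) {
  stopifnot(inherits(design, "repeatability_design"))
  maybe_seed(design$seed)
  ns <- design$samples_per_subject
  sp <- design$spots_per_sample
  p <- design$n_features
  subj <- rep(seq_len(design$n_subjects), ns * sp)
  samp <- unlist(lapply(ns, function(k) rep(seq_len(k), each = sp)))
  spot <- unlist(lapply(ns, function(k) rep(seq_len(sp), k)))
  n_samples_total <- sum(ns)
  ## per-feature draws, vectorized over rows
  b <- matrix(stats::rnorm(design$n_subjects * p), design$n_subjects, p)
  b <- sweep(b, 2, sqrt(design$sigma_b2), `*`)
  e <- matrix(stats::rnorm(n_samples_total * p), n_samples_total, p)
  e <- sweep(e, 2, sqrt(design$sigma_w2), `*`)
  sample_index <- cumsum(!duplicated(paste(subj, samp)))  # row -> serial sample
  y <- sweep(b[subj, , drop = FALSE] + e[sample_index, , drop = FALSE],
             2, design$mu, `+`)
  if (any(design$sigma_spot2 > 0)) {
    s <- matrix(stats::rnorm(length(subj) * p), length(subj), p)
    y <- y + sweep(s, 2, sqrt(design$sigma_spot2), `*`)
  }
  samples <- data.frame(
    sample_id = sprintf("S%02d.%d.%d", subj, samp, spot),
    subject_id = sprintf("S%02d", subj),
    run_id = samp, spot_id = spot)
  ft <- feature_table(2^y, default_mz(p), samples, state = "raw")
  attr(ft, "seed") <- design$seed
  ft
}

#' Generate an analytical precision study feature table
#'
#' Simulates the nested run/replicate design used for intra- and inter-assay
#' precision: log2 value `mu + r_k + e_kl` with run effects
#' `r_k ~ N(0, sigma_run2)` and replicate effects `e_kl ~ N(0, sigma_rep2)`,
#' returned as raw-scale intensities.
#'
#' @param design a [precision_design()].
#' @return a [feature_table] in state `"raw"` with `run_id` and `spot_id`
#'   metadata.
#' @export
generate_precision_study <- function(design) {
  stopifnot(inherits(design, "precision_design"))
  maybe_seed(design$seed)
  p <- design$n_features
  run <- rep(seq_len(design$n_runs), each = design$reps_per_run)
  rep_ <- rep(seq_len(design$reps_per_run), design$n_runs)
  r <- matrix(stats::rnorm(design$n_runs * p), design$n_runs, p)
  r <- sweep(r, 2, sqrt(design$sigma_run2), `*`)
  e <- matrix(stats::rnorm(length(run) * p), length(run), p)
  e <- sweep(e, 2, sqrt(design$sigma_rep2), `*`)
  y <- sweep(r[run, , drop = FALSE] + e, 2, design$mu, `+`)
  samples <- data.frame(
    sample_id = sprintf("R%d.%d", run, rep_),
    run_id = run, spot_id = rep_)
  ft <- feature_table(2^y, default_mz(p), samples, state = "raw")
  attr(ft, "seed") <- design$seed
  ft
}

#' Generate a case-control study
#'
#' Draws true subject-level log2 feature values `x_i ~ N(mu, sigma_b2)`,
#' assigns disease by `logit P(D = 1) = alpha + sum_f beta_f x_if` (so
#' disease depends on the true, error-free levels), then observes
#' `W = 2^(x + e)` with `e ~ N(0, sigma_w2)` and flags entries with
#' `W < slod` as below-LOD (intensities are kept as observed; substitution
#' is a preprocessing choice). Histology labels consistent with the binary
#' outcome are attached, including occasional AAH subjects that group
#' assignment later excludes.
#'
#' @param design a [case_control_design()].
#' @return a list with elements `features` (a raw-state [feature_table]),
#'   `phenotypes` (a phenotype data frame, see [phenotype_table()]), and
#'   `truth` (matrix of the true log2 levels, for validation studies).
#' @export
generate_case_control_study <- function(design) {
  stopifnot(inherits(design, "case_control_design"))
  maybe_seed(design$seed)
  n <- design$n_cases + design$n_controls
  p <- design$n_features
  x <- matrix(stats::rnorm(n * p), n, p)
  x <- sweep(sweep(x, 2, sqrt(design$sigma_b2), `*`), 2, design$mu, `+`)
  alpha <- design$alpha_true
  if (is.null(alpha))
    alpha <- stats::qlogis(design$n_cases / n) -
      sum(design$beta_true * design$mu)
  eta <- alpha + drop(x %*% design$beta_true)
  outcome <- stats::rbinom(n, 1, stats::plogis(eta))
  if (length(unique(outcome)) < 2)
    stop("degenerate outcome: all subjects fell in one class; ",
         "revise alpha_true/beta_true")
  e <- matrix(stats::rnorm(n * p), n, p)
  w <- 2^(x + sweep(e, 2, sqrt(design$sigma_w2), `*`))
  slod <- design$slod
  if (is.list(slod)) {
    frac <- slod$fraction
    slod <- if (frac > 0) stats::quantile(w, frac, names = FALSE) else 0
  }
  flags <- w < slod
  pheno <- phenotype_table(outcome, aah_rate = design$aah_rate)
  samples <- data.frame(sample_id = pheno$sample_id,
                        subject_id = pheno$subject_id,
                        group = pheno$histology,
                        creatinine = pheno$creatinine)
  ft <- feature_table(w, default_mz(p), samples,
                      below_lod = flags, state = "raw")
  attr(ft, "seed") <- design$seed
  list(features = ft, phenotypes = pheno, truth = x)
}

#' Synthetic phenotype table
#'
#' Builds per-subject clinical metadata around a binary disease outcome:
#' a biopsy histology label drawn from the seven standard categories
#' (controls from no alteration / BPH / inflammation, cases from
#' PCa / HGPIN / ASAP, plus rare AAH relabels), age, total and free PSA,
#' their ratio, a PCA3 score and urinary creatinine. The marginal
#' distributions are loosely calibrated to a LUTS biopsy cohort and are
#' meant for exercising group assignment and diagnostics code, not for
#' clinical realism.
#'
#' @param outcome binary vector (1 = cancer lesion).
#' @param aah_rate probability of relabelling a subject as AAH.
#' @return a data frame with columns `sample_id`, `subject_id`, `histology`,
#'   `outcome`, `age`, `tpsa`, `fpsa`, `f_tpsa`, `pca3`, `creatinine`.
#' @export
phenotype_table <- function(outcome, aah_rate = 2 / 148) {
  n <- length(outcome)
  ctrl_labels <- c("no alteration", "BPH", "inflammation")
  case_labels <- c("PCa", "HGPIN", "ASAP")
  histology <- ifelse(outcome == 1,
                      sample(case_labels, n, TRUE, prob = c(55, 4, 11)),
                      sample(ctrl_labels, n, TRUE, prob = c(57, 7, 12)))
  histology[stats::runif(n) < aah_rate] <- "AAH"
  age <- round(stats::rnorm(n, 66, 7))
  tpsa <- exp(stats::rnorm(n, log(5.5), 0.6))
  ## cases tend to lower free fraction (f/tPSA ~ 8% vs ~ 15%)
  frac <- stats::plogis(stats::rnorm(n, stats::qlogis(
    ifelse(outcome == 1, 0.081, 0.155)), 0.45))
  fpsa <- tpsa * frac
  pca3 <- exp(stats::rnorm(n, log(ifelse(outcome == 1, 50, 25)), 0.7))
  data.frame(sample_id = sprintf("P%03d", seq_len(n)),
             subject_id = sprintf("P%03d", seq_len(n)),
             histology = histology, outcome = as.integer(outcome),
             age = age, tpsa = tpsa, fpsa = fpsa,
             f_tpsa = 100 * frac, pca3 = pca3,
             creatinine = stats::rgamma(n, shape = 4, scale = 2.5))
}

default_mz <- function(p) 1000 + seq_len(p) * round(3000 / (p + 1), 1)
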