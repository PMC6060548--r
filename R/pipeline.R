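#' Pipeline configuration
#'
#' A `pipeline_config` collects every tunable of the end-to-end demo
#' analysis: the case-control generator, the repeatability generator used
#' to estimate per-feature error structures, the LOD model, the screening
#' stage, and output paths. Every random stage carries an explicit seed.
#' Configurations round-trip losslessly through YAML or JSON files.
#'
#' @param out_dir directory for stage outputs.
#' @param seed master seed; stage seeds default to offsets of it.
#' @param n_cases,n_controls,n_features,beta_true case-control generator
#'   settings (see [case_control_design()]); `beta_true` is recycled.
#' @param sigma_b2,sigma_w2 variance components (log2 scale) shared by the
#'   generators.
#' @param lod_strategy below-LOD substitution strategy for the sLMNLT stack.
#' @param slod_k noise multiplier for sLOD estimation.
#' @param simex_B,simex_lambda SIMEX tuning.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(out_dir = "pepticc-out", seed = 1,
                            n_cases = 70, n_controls = 76,
                            n_features = 20, beta_true = c(1, -1, rep(0, 18)),
                            sigma_b2 = 0.48 / 0.52 * 0.184, sigma_w2 = 0.184,
                            lod_strategy = "lod_half", slod_k = 3,
                            simex_B = 50, simex_lambda = c(0.5, 1, 1.5, 2)) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_cases = n_cases, n_controls = n_controls,
              n_features = n_features,
              beta_true = rep_len(beta_true, n_features),
              sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
              lod_strategy = match.arg(lod_strategy, lod_strategies()),
              slod_k = slod_k, simex_B = simex_B,
              simex_lambda = simex_lambda)
  structure(cfg, class = "pipeline_config")
}

#' Read / write pipeline configurations
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return `read_pipeline_config()` a [pipeline_config()];
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(plain, path, precision = 15)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end demo pipeline
#'
#' Executes the full analysis on synthetic data: (1) simulate a
#' repeatability study and estimate per-feature ICCs and within-subject
#' variances from its sLMNLT table; (2) simulate a case-control cohort;
#' (3) estimate the sLOD from synthetic noise draws and normalize the
#' cohort table with the sLMNLT stack; (4) run the naive + RCAL + SIMEX
#' univariate screen with BH correction; (5) compute ROC/cutoff
#' diagnostics for the f/tPSA covariate. Each stage writes a CSV under
#' `out_dir`, and a `manifest.json` records the seeds, stage files and
#' package version. A stage failure halts the pipeline with the stage name
#' in the error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(package = "pepticc",
                   version = as.character(utils::packageVersion("pepticc")),
                   seed = config$seed, files = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(name, df) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    manifest$files[[name]] <<- basename(path)
  }

  out$error_structure <- stage("variability", {
    rep_design <- repeatability_design(
      n_features = config$n_features,
      sigma_b2 = config$sigma_b2, sigma_w2 = config$sigma_w2,
      seed = config$seed + 1L)
    rep_tab <- generate_repeatability_study(rep_design)
    lod <- estimate_slod(noise_draws(rep_tab, config$seed + 2L),
                         k = config$slod_k, strategy = config$lod_strategy)
    icc_df <- feature_icc(slmnlt(rep_tab, lod))
    emit("feature_icc", icc_df)
    icc_df
  })

  out$cohort <- stage("simulate", {
    cc <- generate_case_control_study(case_control_design(
      n_cases = config$n_cases, n_controls = config$n_controls,
      n_features = config$n_features, beta_true = config$beta_true,
      sigma_b2 = config$sigma_b2, sigma_w2 = config$sigma_w2,
      seed = config$seed + 3L))
    write_feature_table(cc$features,
                        file.path(config$out_dir, "cohort_features.csv"))
    manifest$files$cohort_features <- "cohort_features.csv"
    emit("cohort_phenotypes", cc$phenotypes)
    cc
  })

  out$normalized <- stage("normalize", {
    lod <- estimate_slod(noise_draws(out$cohort$features, config$seed + 4L),
                         k = config$slod_k, strategy = config$lod_strategy)
    slmnlt(out$cohort$features, lod)
  })

  out$screen <- stage("associate", {
    groups <- assign_groups(out$cohort$phenotypes, "two_group")
    scr <- univariate_screen(
      out$normalized, groups,
      icc = out$error_structure$icc,
      sigma_w2 = out$error_structure$sigma_w2,
      simex_B = config$simex_B, simex_lambda = config$simex_lambda,
      seed = config$seed + 5L)
    emit("screen", as.data.frame(scr))
    scr
  })

  out$diagnostics <- stage("diagnose", {
    ph <- out$cohort$phenotypes
    groups <- assign_groups(ph, "two_group")
    keep <- !is.na(groups$outcome)
    roc <- roc_auc(ph$f_tpsa[keep], groups$outcome[keep], direction = "less")
    m <- metrics_at_cutoff(ph$f_tpsa[keep], groups$outcome[keep],
                           cutoff = 10, direction = "less")
    df <- data.frame(metric = c("auc", "auc_lo", "auc_hi", "sensitivity",
                                "specificity", "lr_pos", "lr_neg"),
                     value = c(roc$auc, roc$ci, m$sensitivity,
                               m$specificity, m$lr_pos, m$lr_neg))
    emit("diagnostics", df)
    df
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}

## synthetic instrument-noise intensities near the low end of a table's
## dynamic range, used to demo the sLOD rule on generated data
noise_draws <- function(table, seed, n = 200) {
  maybe_seed(seed)
  lo <- stats::quantile(table$intensity, 0.02, na.rm = TRUE, names = FALSE)
  pmax(0, stats::rnorm(n, mean = lo, sd = lo / 4))
}
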