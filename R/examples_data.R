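#' Worked-example screening tables
#'
#' Bundled reference tables of univariate feature-screening results for a
#' urinary and a serum peptidome panel from a prostate-biopsy cohort: per
#' feature, the naive logistic regression coefficient (`beta`, with odds
#' ratio and p-value — unadjusted Wald for the urine panel, BH-adjusted for
#' the serum panel), the reliability coefficient used for calibration
#' (`icc`; a feature-specific value where the error structure was
#' estimable, otherwise the panel median), and the regression-calibrated
#' coefficient with its Rosner-style interval and odds ratio. The tables
#' serve as arithmetic worked examples for [rcal()] and
#' [wald_se_from_p()]: every `rcal_*` column is reproducible from `beta`
#' and `icc` to the printed rounding.
#'
#' The serum panel deliberately contains two distinct aligned features
#' whose rounded m/z collide at 1418.6, one carrying its own reliability
#' estimate and one the panel median.
#'
#' @param matrix_type `"urine"` or `"serum"`.
#' @return a data frame with columns `mz`, `beta`, `or`, `wald_p` (urine)
#'   or `bh_p` (serum), `icc`, `rcal_beta_star`, `rcal_lo`, `rcal_hi`,
#'   `rcal_or`.
#' @examples
#' ex <- screen_worked_example("urine")
#' rcal(ex$beta[2], ex$icc[2])$beta_star   # ~ ex$rcal_beta_star[2]
#' @export
screen_worked_example <- function(matrix_type = c("urine", "serum")) {
  matrix_type <- match.arg(matrix_type)
  path <- system.file("extdata",
                      paste0(matrix_type, "_screen_example.csv"),
                      package = "pepticc", mustWork = TRUE)
  utils::read.csv(path)
}
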