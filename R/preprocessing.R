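#' Signal limit of detection (sLOD) model
#'
#' `estimate_slod()` estimates the instrument's signal limit of detection
#' from noise-region intensity observations as `mean(noise) + k * sd(noise)`
#' (`k = 3` by default). `lod_model()` builds the model directly from a
#' known threshold.
#'
#' @param noise_intensities non-negative noise intensity observations
#'   (pooled over spectra); at least two are required.
#' @param k noise multiplier.
#' @param strategy default below-LOD substitution strategy to carry with the
#'   model: one of `"lod_half"`, `"zero"`, `"richardson_ciampi"`,
#'   `"schisterman"`.
#' @return an object of class `lod_model` with fields `slod`, `strategy`, `k`.
#' @examples
#' estimate_slod(c(1, 2, 3), k = 3)  # slod = 2 + 3*1 = 5
#' @export
estimate_slod <- function(noise_intensities, k = 3, strategy = "lod_half") {
  noise_intensities <- noise_intensities[is.finite(noise_intensities)]
  if (length(noise_intensities) < 2)
    stop("sLOD estimation requires at least 2 noise observations")
  if (any(noise_intensities < 0))
    stop("noise intensities must be non-negative")
  lod_model(mean(noise_intensities) + k * stats::sd(noise_intensities),
            strategy = strategy, k = k)
}

#' @rdname estimate_slod
#' @param slod intensity threshold (> 0); global, or a per-feature vector.
#' @export
lod_model <- function(slod, strategy = "lod_half", k = NA_real_) {
  strategy <- match.arg(strategy, lod_strategies())
  if (any(!is.finite(slod)) || any(slod <= 0))
    stop("'slod' must be a positive intensity threshold")
  structure(list(slod = slod, strategy = strategy, k = k),
            class = "lod_model")
}

lod_strategies <- function() {
  c("lod_half", "zero", "richardson_ciampi", "schisterman")
}

#' @export
print.lod_model <- function(x, ...) {
  cat("<lod_model> slod =", format(x$slod, digits = 5),
      " strategy =", x$strategy,
      if (!is.na(x$k)) paste0(" (mean + ", x$k, "*SD rule)"), "\n")
  invisible(x)
}

#' Substitute below-LOD intensities
#'
#' Flags every intensity below the sLOD threshold (existing flags are kept)
#' and replaces flagged entries according to the model's strategy:
#' `lod_half` fills with `slod / 2`; `zero` with 0;
#' `richardson_ciampi` with the conditional mean below the threshold,
#' `E(W | W < slod)`; `schisterman` with the conditional mean above it,
#' `E(W | W > slod)`. The conditional means are computed per feature on the
#' log2 scale under a normal model with plug-in mean and SD estimated from
#' that feature's unflagged values (see
#' [richardson_ciampi_expectation()]), then mapped back to the intensity
#' scale. Unflagged entries are never altered.
#'
#' @param table a [feature_table] in state `"raw"`.
#' @param lod a [lod_model()].
#' @return the table in state `"lod-adjusted"`, with flags set.
#' @export
substitute_below_lod <- function(table, lod) {
  ft_require_state(table, "raw", "below-LOD substitution")
  if (!inherits(lod, "lod_model")) stop("'lod' must be a lod_model object")
  w <- table$intensity
  slod <- rep_len(lod$slod, ncol(w))
  flags <- table$below_lod | sweep(w, 2, slod, `<`)
  flags[is.na(flags)] <- FALSE
  fill <- switch(lod$strategy,
    lod_half = matrix(slod / 2, nrow(w), ncol(w), byrow = TRUE),
    zero = matrix(0, nrow(w), ncol(w)),
    richardson_ciampi = conditional_fill(w, flags, slod, lower = TRUE),
    schisterman = conditional_fill(w, flags, slod, lower = FALSE),
    stop("unknown below-LOD strategy: ", lod$strategy))
  w[flags] <- fill[flags]
  ft_update(table, intensity = w, below_lod = flags, state = "lod-adjusted")
}

## per-feature truncated-normal fills on the log2 scale, returned as a full
## matrix on the intensity scale
conditional_fill <- function(w, flags, slod, lower) {
  fill <- matrix(NA_real_, nrow(w), ncol(w))
  for (j in seq_len(ncol(w))) {
    obs <- w[!flags[, j] & !is.na(w[, j]) & w[, j] > 0, j]
    cj <- log2(slod[j])
    if (length(obs) >= 2 && stats::sd(log2(obs)) > 0) {
      mu <- mean(log2(obs))
      sg <- stats::sd(log2(obs))
      val <- if (lower) richardson_ciampi_expectation(cj, mu, sg)
             else schisterman_expectation(cj, mu, sg)
    } else {
      val <- cj  # too little information; fall back to the threshold
    }
    fill[, j] <- 2^val
  }
  fill
}

#' Per-spectrum median normalization
#'
#' Divides each sample's intensities by that sample's median over its
#' non-missing feature intensities, so every normalized spectrum has median
#' exactly 1. Scale-equivariant: multiplying a spectrum by a positive
#' constant leaves its normalized values unchanged.
#'
#' @param table a [feature_table] in state `"raw"` or `"lod-adjusted"`.
#' @return the table in state `"median-normalized"`.
#' @export
median_normalize <- function(table) {
  ft_require_state(table, c("raw", "lod-adjusted"), "median normalization")
  med <- apply(table$intensity, 1, stats::median, na.rm = TRUE)
  bad <- which(!is.finite(med) | med == 0)
  if (length(bad))
    stop("median normalization failed: zero or undefined median for sample(s) ",
         paste(rownames(table$intensity)[bad], collapse = ", "))
  ft_update(table, intensity = table$intensity / med,
            state = "median-normalized")
}

#' Creatinine normalization for urine tables
#'
#' Divides each sample's intensities by its urinary creatinine
#' concentration (mmol/L), correcting for urine dilution.
#'
#' @param table a [feature_table] in state `"raw"` or `"lod-adjusted"`.
#' @param creatinine per-sample creatinine (mmol/L); taken from the
#'   `creatinine` metadata column when omitted.
#' @return the table in state `"creatinine-normalized"`.
#' @export
creatinine_normalize <- function(table, creatinine = NULL) {
  ft_require_state(table, c("raw", "lod-adjusted"), "creatinine normalization")
  if (is.null(creatinine)) creatinine <- table$samples$creatinine
  if (is.null(creatinine))
    stop("no creatinine values given and none in the sample metadata")
  creatinine <- as.numeric(creatinine)
  bad <- which(is.na(creatinine) | creatinine <= 0)
  if (length(bad))
    stop("missing or non-positive creatinine for sample(s) ",
         paste(table$samples$sample_id[bad], collapse = ", "))
  ft_update(table, intensity = table$intensity / creatinine,
            state = "creatinine-normalized")
}

#' Log2 transformation
#'
#' Entrywise log2 of the intensities. Requires strictly positive entries,
#' which is guaranteed when the `lod_half` or `richardson_ciampi`
#' substitution preceded; the `zero` strategy leaves zeros that cannot be
#' log-transformed, and such tables are rejected with an error.
#'
#' @param table a [feature_table] in any pre-log2 state.
#' @return the table in state `"log2"`.
#' @export
log2_transform <- function(table) {
  ft_require_state(table, setdiff(ft_states(), "log2"), "log2 transformation")
  if (any(table$intensity <= 0, na.rm = TRUE))
    stop("log2 transformation requires strictly positive intensities ",
         "(found non-positive entries; the 'zero' substitution strategy ",
         "produces these)")
  ft_update(table, intensity = log2(table$intensity), state = "log2")
}

#' The sLMNLT normalization stack
#'
#' Applies, in order: below-LOD substitution, per-spectrum median
#' normalization, and log2 transformation (sLOD-adjusted,
#' Median-Normalized, Log2-Transformed). This is the composition under
#' which repeatability of peptidomic feature tables is highest, and the
#' state expected by the association stage. The substitution strategy is
#' taken from the LOD model; `lod_half` is the canonical sLMNLT choice.
#'
#' @param table a [feature_table] in state `"raw"`.
#' @param lod a [lod_model()].
#' @return the table in state `"log2"`.
#' @export
slmnlt <- function(table, lod) {
  ft_require_state(table, "raw", "sLMNLT normalization")
  log2_transform(median_normalize(substitute_below_lod(table, lod)))
}

#' Match features between two m/z lists
#'
#' Greedy one-to-one nearest-neighbour matching of two sorted m/z lists
#' within an absolute tolerance (default 0.3 Da, the window used to align
#' urinary and serum peptidome features). Candidate pairs are ranked by
#' `|delta m/z|`, ties broken by the lower m/z, and each feature is used at
#' most once.
#'
#' @param mz_a,mz_b sorted (non-decreasing) numeric m/z vectors.
#' @param tolerance_da maximum absolute m/z difference (Da).
#' @return a data frame with columns `index_a`, `index_b`, `mz_a`, `mz_b`,
#'   `delta` (one row per matched pair, ordered by `mz_a`).
#' @export
match_features <- function(mz_a, mz_b, tolerance_da = 0.3) {
  if (is.unsorted(mz_a) || is.unsorted(mz_b))
    stop("m/z lists must be sorted in increasing order")
  cand <- expand.grid(index_a = seq_along(mz_a), index_b = seq_along(mz_b))
  cand$delta <- abs(mz_a[cand$index_a] - mz_b[cand$index_b])
  cand <- cand[cand$delta <= tolerance_da, , drop = FALSE]
  cand <- cand[order(cand$delta, mz_a[cand$index_a], mz_b[cand$index_b]), ,
               drop = FALSE]
  used_a <- logical(length(mz_a))
  used_b <- logical(length(mz_b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ia <- cand$index_a[r]; ib <- cand$index_b[r]
    if (!used_a[ia] && !used_b[ib]) {
      keep[r] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  out <- cand[keep, c("index_a", "index_b", "delta"), drop = FALSE]
  out$mz_a <- mz_a[out$index_a]
  out$mz_b <- mz_b[out$index_b]
  out <- out[order(out$mz_a), c("index_a", "index_b", "mz_a", "mz_b", "delta")]
  rownames(out) <- NULL
  out
}
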