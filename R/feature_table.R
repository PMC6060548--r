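#' Feature table container
#'
#' A `feature_table` holds a samples x features intensity matrix from
#' MALDI-TOF/MS peptidomic profiling, together with per-sample metadata,
#' a congruent logical matrix of below-LOD (limit of detection) flags, and a
#' normalization-state tag. It is the common currency of every analysis
#' stage: generators emit it, the normalization stack transforms it, and the
#' variance-component and association stages consume it.
#'
#' Normalization states form a small state machine; transitions are only
#' allowed in the declared order
#' `raw -> lod-adjusted -> {median-normalized | creatinine-normalized} -> log2`
#' (the LOD-adjustment step may be skipped). Functions that transform a
#' table check the state of their input and refuse out-of-order calls.
#'
#' @param intensity numeric matrix, samples in rows and features in columns.
#'   All entries must be non-negative (or `NA`) unless `state = "log2"`.
#' @param mz numeric vector of feature m/z values (Da), strictly increasing,
#'   one per column of `intensity`.
#' @param samples data frame of per-sample metadata with at least a
#'   `sample_id` column (unique); optional columns `subject_id`, `run_id`,
#'   `spot_id`, `group`, `creatinine` are used by downstream stages.
#' @param below_lod logical matrix of the same shape as `intensity` flagging
#'   entries below the signal LOD; defaults to all-`FALSE`.
#' @param state normalization-state tag, one of `"raw"`, `"lod-adjusted"`,
#'   `"median-normalized"`, `"creatinine-normalized"`, `"log2"`.
#' @return an object of class `feature_table`.
#' @examples
#' ft <- feature_table(matrix(c(2, 4, 6, 8), 2, 2),
#'                     mz = c(1000.5, 1200.7),
#'                     samples = data.frame(sample_id = c("s1", "s2")))
#' ft
#' @export
feature_table <- function(intensity, mz, samples,
                          below_lod = NULL, state = "raw") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix (samples x features)")
  mz <- as.numeric(mz)
  if (length(mz) != ncol(intensity))
    stop("length of 'mz' (", length(mz), ") does not match the number of ",
         "feature columns (", ncol(intensity), ")")
  if (anyNA(mz)) stop("m/z values must be numeric and non-missing")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z values must be strictly increasing")
  if (!is.data.frame(samples) || is.null(samples$sample_id))
    stop("'samples' must be a data frame with a 'sample_id' column")
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (nrow(samples) != nrow(intensity))
    stop("'samples' has ", nrow(samples), " rows but 'intensity' has ",
         nrow(intensity))
  state <- match.arg(state, ft_states())
  if (state != "log2" && any(intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative before log2 transformation")
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(intensity), ncol(intensity))
  } else {
    if (!is.logical(below_lod) || !identical(dim(below_lod), dim(intensity)))
      stop("'below_lod' must be a logical matrix congruent with 'intensity'")
    below_lod[is.na(below_lod)] <- FALSE
  }
  dimnames(intensity) <- list(samples$sample_id, format_mz(mz))
  dimnames(below_lod) <- dimnames(intensity)
  structure(
    list(intensity = intensity, mz = mz, samples = samples,
         below_lod = below_lod, state = state),
    class = "feature_table")
}

ft_states <- function() {
  c("raw", "lod-adjusted", "median-normalized", "creatinine-normalized",
    "log2")
}

format_mz <- function(mz) formatC(mz, format = "fg", digits = 10)

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$intensity), " samples x ",
      length(x$mz), " features  [state: ", x$state, "]\n", sep = "")
  cat("  m/z range: ", min(x$mz), "-", max(x$mz), " Da\n", sep = "")
  n_cens <- sum(x$below_lod)
  cat("  below-LOD flags: ", n_cens, " (",
      round(100 * n_cens / length(x$below_lod), 1), "%)\n", sep = "")
  meta <- setdiff(names(x$samples), "sample_id")
  if (length(meta))
    cat("  sample metadata: ", paste(meta, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Accessors for feature tables
#'
#' @param x a [feature_table].
#' @return `intensities()` the numeric matrix; `mz_values()` the m/z vector;
#'   `sample_info()` the metadata data frame; `below_lod_flags()` the logical
#'   censoring matrix; `ft_state()` the normalization-state tag.
#' @name feature_table-accessors
NULL

#' @rdname feature_table-accessors
#' @export
intensities <- function(x) x$intensity

#' @rdname feature_table-accessors
#' @export
mz_values <- function(x) x$mz

#' @rdname feature_table-accessors
#' @export
sample_info <- function(x) x$samples

#' @rdname feature_table-accessors
#' @export
below_lod_flags <- function(x) x$below_lod

#' @rdname feature_table-accessors
#' @export
ft_state <- function(x) x$state

## internal: replace the matrix and advance the state tag
ft_update <- function(x, intensity = x$intensity, below_lod = x$below_lod,
                      state = x$state) {
  x$intensity <- intensity
  x$below_lod <- below_lod
  x$state <- state
  x
}

## internal: check that a table is in one of the allowed states
ft_require_state <- function(x, allowed, what) {
  if (!inherits(x, "feature_table"))
    stop("'table' must be a feature_table object")
  if (!x$state %in% allowed)
    stop(what, " requires a table in state ",
         paste(sQuote(allowed), collapse = " or "),
         ", not ", sQuote(x$state))
  invisible(x)
}
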