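#' Read a feature table from CSV/TSV
#'
#' Two dialects are supported. The *wide* dialect has one row per sample:
#' leading metadata columns (at least `sample_id`; optionally `subject_id`,
#' `run_id`, `spot_id`, `group`, `creatinine`) followed by one column per
#' feature whose header is the m/z value. The *long* dialect has one row per
#' (sample, feature) cell with columns
#' `sample_id, subject_id, run_id, spot_id, mz, intensity, below_lod`
#' (metadata columns other than `sample_id` optional). Empty cells are
#' missing values, which are distinct from below-LOD flags.
#'
#' @param path file to read; the delimiter is taken from the extension
#'   (`.tsv` means tab, anything else comma).
#' @param dialect `"wide"` or `"long"`.
#' @param state normalization-state tag to assign (files carry no state).
#' @return a [feature_table].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, dialect = c("wide", "long"),
                               state = "raw") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") parse_wide(df, path, state) else parse_long(df, path, state)
}

meta_columns <- function() {
  c("sample_id", "subject_id", "run_id", "spot_id", "group", "creatinine")
}

parse_wide <- function(df, path, state) {
  if (is.null(df$sample_id))
    stop("wide table ", path, " lacks the required 'sample_id' column")
  meta <- intersect(meta_columns(), names(df))
  feat_cols <- setdiff(names(df), meta)
  if (!length(feat_cols)) stop("wide table ", path, " has no feature columns")
  mz <- suppressWarnings(as.numeric(feat_cols))
  if (anyNA(mz)) {
    bad <- feat_cols[is.na(mz)]
    stop("non-numeric m/z column header(s) in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  mat <- as.matrix(df[feat_cols])
  if (!is.numeric(mat)) stop("non-numeric intensities in ", path)
  ord <- order(mz)
  feature_table(mat[, ord, drop = FALSE], mz[ord], df[meta], state = state)
}

parse_long <- function(df, path, state) {
  need <- c("sample_id", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df$mz <- suppressWarnings(as.numeric(df$mz))
  if (anyNA(df$mz)) {
    bad <- which(is.na(df$mz))
    stop("non-numeric m/z at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  }
  mz <- sort(unique(df$mz))
  ids <- unique(as.character(df$sample_id))
  mat <- matrix(NA_real_, length(ids), length(mz),
                dimnames = list(ids, format_mz(mz)))
  flg <- matrix(FALSE, length(ids), length(mz))
  i <- match(as.character(df$sample_id), ids)
  j <- match(df$mz, mz)
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate (sample_id, mz) cells in ", path)
  mat[cbind(i, j)] <- df$intensity
  if (!is.null(df$below_lod))
    flg[cbind(i, j)] <- parse_flag(df$below_lod)
  meta <- intersect(meta_columns(), names(df))
  samples <- unique(df[meta])
  if (anyDuplicated(samples$sample_id))
    stop("inconsistent metadata for a sample_id in ", path)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  feature_table(mat, mz, samples, below_lod = flg, state = state)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a feature table to CSV
#'
#' Writes either the wide or the long dialect described in
#' [read_feature_table()]. A `#`-prefixed header comment records the
#' normalization state (and a seed, when the table was generated with one).
#'
#' @param x a [feature_table].
#' @param path output file.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "feature_table"))
  hdr <- paste0("# pepticc feature_table  state=", x$state)
  seed <- attr(x, "seed")
  if (!is.null(seed)) hdr <- paste0(hdr, "  seed=", seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (dialect == "wide") {
    df <- cbind(x$samples,
                as.data.frame(x$intensity, check.names = FALSE))
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    meta <- x$samples[rep(seq_len(nrow(x$samples)), each = length(x$mz)), ,
                      drop = FALSE]
    df <- cbind(meta,
                data.frame(mz = rep(x$mz, nrow(x$intensity)),
                           intensity = as.vector(t(x$intensity)),
                           below_lod = as.vector(t(x$below_lod))))
    rownames(df) <- NULL
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}
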