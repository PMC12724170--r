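.SAMPLE_COLS <- c("sample_id", "system", "arm", "day")
.ARMS <- c("baseline", "timecourse", "control", "treated")

#' Construct a ScreenExperiment
#'
#' Bundles an sgRNA count matrix, the guide library and per-sample
#' metadata into a \linkS4class{SummarizedExperiment}-derived container.
#' Rows of \code{counts} must be a subset of the library's guide ids;
#' guide annotation is carried into \code{rowData} in count-matrix order.
#'
#' @param counts non-negative integer matrix, sgRNA x sample, with sgRNA
#'   row names and sample column names.
#' @param library a [GuideLibrary-class] covering all count rows.
#' @param samples a data.frame/DataFrame with columns \code{sample_id},
#'   \code{system} (\code{"2D"}/\code{"3D"}), \code{arm} (one of
#'   \code{baseline}, \code{timecourse}, \code{control}, \code{treated})
#'   and \code{day}; one row per count column, matched by
#'   \code{sample_id}.
#' @return a [ScreenExperiment-class].
#' @export
ScreenExperiment <- function(counts, library, samples) {
  stopifnot(is(library, "GuideLibrary"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stop2("validationError", "counts must have row and column names")
  unknown <- setdiff(rownames(counts), guideIds(library))
  if (length(unknown))
    .stop2("referenceError", "count rows absent from library: %s",
           paste(head(unknown, 10L), collapse = ", "))
  samples <- as.data.frame(samples)
  .require_cols(samples, .SAMPLE_COLS, "sample metadata")
  samples <- .validate_sample_meta(samples)
  idx <- match(colnames(counts), samples$sample_id)
  if (anyNA(idx))
    .stop2("referenceError", "count columns without sample metadata: %s",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  rd <- library[match(rownames(counts), guideIds(library)), ]
  cd <- DataFrame(samples, row.names = samples$sample_id)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = as(rd, "DFrame"), colData = cd)
  new("ScreenExperiment", se)
}

.validate_sample_meta <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    .stop2("validationError", "duplicated sample_id: %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$system %in% c("2D", "3D")))
    .stop2("validationError", "system must be '2D' or '3D'")
  if (!all(df$arm %in% .ARMS))
    .stop2("validationError", "arm must be one of %s",
           paste(.ARMS, collapse = "/"))
  df$day <- as.numeric(df$day)
  if (any(is.na(df$day) | df$day < 0 | df$day != round(df$day)))
    .stop2("validationError", "day must be a non-negative integer")
  df
}

#' Extract the guide library of a ScreenExperiment
#'
#' Rebuilds the [GuideLibrary-class] from the experiment's
#' \code{rowData}, in row order.
#'
#' @param se a [ScreenExperiment-class].
#' @return a [GuideLibrary-class].
#' @export
guideLibraryOf <- function(se) {
  stopifnot(is(se, "ScreenExperiment"))
  new("GuideLibrary", as(rowData(se)[, .GUIDE_COLS], "DFrame"))
}

#' Read sample metadata from TSV
#'
#' @param path TSV with header \code{sample_id system arm day}.
#' @return a validated data.frame.
#' @export
readSampleMeta <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, .SAMPLE_COLS, "sample metadata file")
  .validate_sample_meta(df)
}

#' Read / write an sgRNA count matrix
#'
#' The TSV layout has an \code{sgrna_id} first column and one column per
#' sample. Entries must be non-negative integers; violations are
#' reported with their coordinates.
#'
#' @param path file path.
#' @return \code{readCounts}: an integer matrix with sgRNA row names.
#' @export
readCounts <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, "sgrna_id", "count matrix file")
  ids <- as.character(df$sgrna_id)
  if (anyDuplicated(ids))
    .stop2("validationError", "duplicated sgrna_id in count matrix: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, setdiff(colnames(df), "sgrna_id"), drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    .stop2("validationError",
           "count matrix entries must be non-negative integers; first offence at row %d (sgRNA '%s'), sample '%s'",
           bad[1L, 1L], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname readCounts
#' @param x an integer matrix or [ScreenExperiment-class].
#' @return \code{writeCounts}: the path, invisibly.
#' @export
writeCounts <- function(x, path) {
  if (is(x, "ScreenExperiment")) x <- counts(x)
  df <- data.frame(sgrna_id = rownames(x), x, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname readCounts
#' @export
writeSampleMeta <- function(x, path) {
  if (is(x, "ScreenExperiment")) x <- as.data.frame(colData(x))
  .write_tsv(as.data.frame(x)[, .SAMPLE_COLS], path)
}
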