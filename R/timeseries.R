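#' Regional time-series container
#'
#' Holds one subject's region-by-time activation matrix together with region
#' labels and acquisition metadata. Rows are regions, columns are time points
#' (e.g. fMRI volumes after preprocessing and atlas extraction).
#'
#' @param data Numeric matrix, `n_regions x n_timepoints`. No missing values.
#' @param region_labels Character vector of unique region names, one per row.
#'   Defaults to rownames of `data` or `R1..Rn`.
#' @param subject_id Subject identifier string.
#' @param tr_seconds Repetition time in seconds (metadata only; lags are
#'   expressed in sampling steps, not seconds).
#'
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(data, region_labels = NULL, subject_id = "subject",
                      tr_seconds = 1) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("time series must not contain missing values")
  if (ncol(data) < 3L) stop("need at least 3 time points")
  if (is.null(region_labels)) {
    region_labels <- rownames(data)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(data)))
  }
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(data))
    stop("region_labels length must equal the number of rows")
  if (anyDuplicated(region_labels))
    stop("region_labels must be unique")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  rownames(data) <- region_labels
  structure(list(data = data, region_labels = region_labels,
                 subject_id = as.character(subject_id),
                 tr_seconds = tr_seconds),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> subject '%s': %d regions x %d time points (TR = %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$data)

n_regions <- function(ts) nrow(ts$data)
n_timepoints <- function(ts) ncol(ts$data)

as_region_ts <- function(x, subject_id = "subject") {
  if (inherits(x, "region_ts")) return(x)
  region_ts(x, subject_id = subject_id)
}

#' Read regional time series from delimited text
#'
#' Expects one row per region; the first column holds the region label and the
#' remaining columns the time points.
#'
#' @param path Path to a TSV (or other delimited) file.
#' @param sep Field separator, tab by default.
#' @param header Whether the file has a header row.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param tr_seconds Repetition time in seconds.
#' @return A [region_ts] object.
#' @export
read_region_ts <- function(path, sep = "\t", header = FALSE,
                           subject_id = NULL, tr_seconds = 1) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  region_ts(mat, region_labels = labels, subject_id = subject_id,
            tr_seconds = tr_seconds)
}

#' Write regional time series to delimited text
#'
#' @param ts A [region_ts] object.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_region_ts <- function(ts, path, sep = "\t") {
  df <- data.frame(region = ts$region_labels, ts$data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
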