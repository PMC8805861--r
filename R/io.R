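#' Write a connectivity matrix to delimited text
#'
#' Writes the square weight matrix as TSV with region labels as header row
#' and first column, plus a JSON sidecar (`<path>.meta.json`) recording
#' method, lag, clipped flag and subject.
#'
#' @param mat A [conn_matrix].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(mat, path, sep = "\t") {
  stopifnot(inherits(mat, "conn_matrix"))
  df <- data.frame(region = mat$region_labels, mat$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region", mat$region_labels)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  meta <- list(method = mat$method, lag = mat$lag, clipped = mat$clipped,
               subject_id = mat$subject_id)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a connectivity matrix written by [write_conn_matrix]
#'
#' Restores the matrix and, when the JSON sidecar is present, its metadata.
#'
#' @param path Path to the TSV matrix.
#' @param sep Field separator.
#' @return A [conn_matrix].
#' @export
read_conn_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  w <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(w) <- "double"
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    conn_matrix(w, meta$method, lag = meta$lag, clipped = isTRUE(meta$clipped),
                region_labels = labels, subject_id = meta$subject_id)
  } else {
    conn_matrix(w, "lagged", region_labels = labels)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Per-subject time-series TSVs, a `subjects.tsv` covariate table and a
#' `truth.json` ground-truth record.
#'
#' @param cohort Result of [make_group_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$series)
    write_region_ts(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  truth <- cohort$truth
  rec <- list(effect = unclass(truth$effect), jitter_sd = truth$jitter_sd,
              seed = truth$seed,
              control_coefficients = truth$control$coefficients,
              patient_coefficients = truth$patient$coefficients,
              noise_sd = truth$control$noise_sd)
  jsonlite::write_json(rec, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort]
#'
#' @param dir Cohort directory.
#' @return List with `series` and `subjects` (and `truth` when present).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  subjects$group <- factor(subjects$group)
  series <- lapply(subjects$subject_id, function(id)
    read_region_ts(file.path(dir, paste0(id, ".tsv")), subject_id = id))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  list(series = series, subjects = subjects, truth = truth)
}
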