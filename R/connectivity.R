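#' Connectivity matrix container
#'
#' A square weighted matrix tagged with the method that produced it, the
#' temporal lag (or Granger model order) and whether negatives and the
#' diagonal have been zeroed ("clipped").
#'
#' @param weights Square numeric matrix.
#' @param method One of `"lagged"`, `"antisymmetric"`, `"symmetric"`,
#'   `"zerolag"`, `"granger"`.
#' @param lag Nonnegative integer lag `d` (model order `p` for Granger).
#' @param clipped Logical; have negatives and self-connections been zeroed?
#' @param region_labels Optional region names.
#' @param subject_id Optional provenance.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(weights, method, lag = 0L, clipped = FALSE,
                        region_labels = NULL, subject_id = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectivity matrix must be square")
  method <- match.arg(method,
                      c("lagged", "antisymmetric", "symmetric", "zerolag", "granger"))
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, method = method, lag = as.integer(lag),
                 clipped = isTRUE(clipped), region_labels = region_labels,
                 subject_id = subject_id),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s (lag %d, %s): %d x %d\n",
              x$method, x$lag, if (x$clipped) "clipped" else "signed",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$weights)

conn_weights <- function(x) if (inherits(x, "conn_matrix")) x$weights else as.matrix(x)

#' Zero out negative weights and self-connections
#'
#' Negative correlation coefficients and self-connections are excluded from
#' all downstream analyses by setting them to zero. Clipping always happens
#' after the full signed matrix (and any symmetric/antisymmetric
#' decomposition of it) has been computed.
#'
#' @param mat A [conn_matrix].
#' @return The clipped [conn_matrix].
#' @export
clip_connectivity <- function(mat) {
  w <- conn_weights(mat)
  w[w < 0] <- 0
  diag(w) <- 0
  out <- mat
  out$weights <- w
  out$clipped <- TRUE
  out
}

#' Lagged correlation matrix
#'
#' Entry (j, k) is the Pearson correlation between the first `N - d` samples
#' of region j and the last `N - d` samples of region k, i.e. region k is
#' shifted `d` sampling steps back relative to region j. A positive lagged
#' correlation at entry (j, k) estimates directed functional connectivity
#' from j to k by temporal precedence. The matrix is generally asymmetric and
#' is returned unclipped (signed).
#'
#' Segments with zero variance yield a correlation of 0 for the pairs
#' involved, with a warning: a flat segment carries no connectivity
#' information and is treated as an absent connection.
#'
#' @param ts A [region_ts] (or bare region-by-time matrix).
#' @param d Nonnegative integer lag, in sampling steps; must satisfy
#'   `d < n_timepoints - 2`.
#' @return An unclipped [conn_matrix] with `method = "lagged"`.
#' @export
lagged_correlation <- function(ts, d = 1L) {
  ts <- as_region_ts(ts)
  d <- as.integer(d)
  N <- n_timepoints(ts)
  if (d < 0L) stop("lag d must be nonnegative")
  if (d >= N - 2L)
    stop(sprintf("lag d = %d too large for %d time points (need d < N - 2)", d, N))
  x <- ts$data
  lead <- t(x[, seq_len(N - d), drop = FALSE])        # first N-d samples
  trail <- t(x[, (d + 1L):N, drop = FALSE])           # last N-d samples
  sd_lead <- apply(lead, 2L, stats::sd)
  sd_trail <- apply(trail, 2L, stats::sd)
  bad_lead <- sd_lead == 0
  bad_trail <- sd_trail == 0
  L <- suppressWarnings(stats::cor(lead, trail))
  if (any(bad_lead) || any(bad_trail)) {
    warning(sprintf("zero-variance segment(s) in region(s) %s; affected entries set to 0",
                    paste(unique(ts$region_labels[bad_lead | bad_trail]), collapse = ", ")))
  }
  L[is.na(L)] <- 0
  # the segment-wise normalization can exceed |1| only through rounding noise
  over <- abs(L) > 1
  if (any(over)) {
    if (any(abs(L[over]) > 1 + 1e-8))
      warning("lagged correlations outside [-1, 1] clamped")
    L[over] <- sign(L[over])
  }
  conn_matrix(L, "lagged", lag = d, clipped = FALSE,
              region_labels = ts$region_labels, subject_id = ts$subject_id)
}

#' Antisymmetric part of a lagged correlation matrix
#'
#' Computes `A = L - t(L)` from the signed lagged matrix, then (by default)
#' zeroes negatives and the diagonal. After clipping, a positive entry (j, k)
#' encodes the net directed influence from region j to region k: each
#' connected pair is summarized by a single entry carrying both direction and
#' magnitude. The raw scale is kept (no division by 2); all downstream steps
#' are rank- and threshold-based, so the scale is immaterial.
#'
#' @param L An unclipped `lagged` [conn_matrix].
#' @param clip Zero negatives and diagonal (the analysis default). Set to
#'   `FALSE` to obtain the signed antisymmetric matrix (`A == -t(A)`).
#' @return A [conn_matrix] with `method = "antisymmetric"`.
#' @export
antisymmetric_part <- function(L, clip = TRUE) {
  w <- conn_weights(L)
  if (nrow(w) != ncol(w)) stop("input matrix must be square")
  if (inherits(L, "conn_matrix")) {
    if (L$method != "lagged")
      stop("antisymmetric_part expects a lagged correlation matrix")
    if (L$clipped)
      stop("antisymmetric_part expects the signed (unclipped) lagged matrix")
  }
  A <- w - t(w)
  out <- conn_matrix(A, "antisymmetric",
                     lag = if (inherits(L, "conn_matrix")) L$lag else 0L,
                     clipped = FALSE,
                     region_labels = if (inherits(L, "conn_matrix")) L$region_labels,
                     subject_id = if (inherits(L, "conn_matrix")) L$subject_id)
  if (clip) clip_connectivity(out) else out
}

#' Symmetric part of a lagged correlation matrix
#'
#' Computes `S = L + t(L)`: the undirected connection between two regions is
#' the sum of the weights of the two directed connections between them. At
#' lag 0 this is twice the zero-lag correlation matrix, so the binarized
#' networks coincide at every density.
#'
#' @inheritParams antisymmetric_part
#' @return A [conn_matrix] with `method = "symmetric"`.
#' @export
symmetric_part <- function(L, clip = TRUE) {
  w <- conn_weights(L)
  if (nrow(w) != ncol(w)) stop("input matrix must be square")
  if (inherits(L, "conn_matrix")) {
    if (L$method != "lagged")
      stop("symmetric_part expects a lagged correlation matrix")
    if (L$clipped)
      stop("symmetric_part expects the signed (unclipped) lagged matrix")
  }
  S <- w + t(w)
  out <- conn_matrix(S, "symmetric",
                     lag = if (inherits(L, "conn_matrix")) L$lag else 0L,
                     clipped = FALSE,
                     region_labels = if (inherits(L, "conn_matrix")) L$region_labels,
                     subject_id = if (inherits(L, "conn_matrix")) L$subject_id)
  if (clip) clip_connectivity(out) else out
}

#' Zero-lag (conventional) correlation matrix
#'
#' Entry (j, k) is the Pearson correlation between the full time courses of
#' regions j and k: `cov(x_j, x_k) / (sd_j sd_k)`. This is the conventional
#' undirected functional-connectivity estimate, and coincides with
#' [lagged_correlation] at `d = 0`. Clipping (negatives and diagonal zeroed)
#' is applied.
#'
#' @param ts A [region_ts] (or bare matrix).
#' @param clip Zero negatives and diagonal (default `TRUE`).
#' @return A [conn_matrix] with `method = "zerolag"`.
#' @export
zero_lag_correlation <- function(ts, clip = TRUE) {
  ts <- as_region_ts(ts)
  if (n_timepoints(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts$data, 1L, stats::sd)
  R <- suppressWarnings(stats::cor(t(ts$data)))
  if (any(sds == 0)) {
    warning(sprintf("constant region(s) %s; affected entries set to 0",
                    paste(ts$region_labels[sds == 0], collapse = ", ")))
  }
  R[is.na(R)] <- 0
  out <- conn_matrix(R, "zerolag", lag = 0L, clipped = FALSE,
                     region_labels = ts$region_labels, subject_id = ts$subject_id)
  if (clip) clip_connectivity(out) else out
}

#' Group-average connectivity matrix
#'
#' Elementwise arithmetic mean of per-subject weighted matrices, producing a
#' group-representative adjacency matrix. All inputs must share shape,
#' method and lag.
#'
#' @param mats List of [conn_matrix] objects.
#' @return A [conn_matrix] of the same method/lag with the mean weights.
#' @export
group_average_matrix <- function(mats) {
  if (!length(mats)) stop("need at least one matrix")
  mats <- lapply(mats, function(m) if (inherits(m, "conn_matrix")) m else
    conn_matrix(m, "lagged"))
  m1 <- mats[[1L]]
  for (m in mats[-1L]) {
    if (!identical(dim(m$weights), dim(m1$weights)))
      stop("all matrices must have the same shape")
    if (m$method != m1$method || m$lag != m1$lag)
      stop("all matrices must share method and lag")
  }
  avg <- Reduce(`+`, lapply(mats, conn_weights)) / length(mats)
  conn_matrix(avg, m1$method, lag = m1$lag,
              clipped = all(vapply(mats, function(m) m$clipped, logical(1))),
              region_labels = m1$region_labels, subject_id = "group_average")
}

#' Histogram of connection strengths
#'
#' Bins the off-diagonal entries of a (clipped) connectivity matrix. Exact
#' zeros — clipped negatives and absent connections — are excluded by
#' default, so the histogram describes the strength distribution of present
#' connections.
#'
#' @param mat A clipped [conn_matrix].
#' @param n_bins Number of equal-width bins (over the observed range).
#' @param include_zeros Keep exact-zero entries in the counts.
#' @return List with `breaks`, `counts`, `mids` and the summary `sd` of the
#'   binned weights.
#' @export
weight_histogram <- function(mat, n_bins = 30L, include_zeros = FALSE) {
  if (n_bins < 1L) stop("n_bins must be at least 1")
  w <- conn_weights(mat)
  off <- w[row(w) != col(w)]
  if (!include_zeros) off <- off[off != 0]
  if (!length(off))
    return(list(breaks = numeric(0), counts = integer(0), mids = numeric(0),
                sd = NA_real_, n = 0L))
  rng <- range(off)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1L]), 1e-8)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(off, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       sd = stats::sd(off), n = length(off))
}
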