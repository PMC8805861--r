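#' Proportional density thresholding
#'
#' Retains the strongest `floor(density * n * (n - 1))` off-diagonal entries
#' of a clipped connectivity matrix. In `binary` mode surviving edges are set
#' to 1; in `weighted` mode their original weights are retained after the
#' binarization step. Only strictly positive weights are eligible: clipped
#' (zero) entries are absent connections.
#'
#' An antisymmetric matrix has at most `n(n-1)/2` positive entries, which is
#' why the usable density range tops out at 50%. If the requested density
#' asks for more edges than there are positive weights, an error reports the
#' attainable maximum.
#'
#' Ties at the threshold weight are broken deterministically by
#' (weight descending, row index, column index).
#'
#' @param mat A clipped [conn_matrix] (or bare nonnegative matrix).
#' @param density Target edge density in `(0, 0.5]`, as a fraction of the
#'   `n(n-1)` possible directed edges.
#' @param mode `"binary"` or `"weighted"`.
#' @return An object of class `thresholded_network` with fields `adjacency`,
#'   `density`, `mode`, `source_method`, `lag`.
#' @export
threshold_by_density <- function(mat, density, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- conn_weights(mat)
  n <- nrow(w)
  if (n != ncol(w)) stop("matrix must be square")
  if (!is.numeric(density) || length(density) != 1L || density <= 0 || density > 0.5)
    stop("density must lie in (0, 0.5]")
  if (any(w[row(w) != col(w)] < 0) || any(diag(w) != 0))
    stop("threshold_by_density expects a clipped (nonnegative, zero-diagonal) matrix")
  m_possible <- n * (n - 1L)
  m <- floor(density * m_possible)
  if (m < 1L) stop("density too small: no edges would be retained")
  off <- which(row(w) != col(w))
  wv <- w[off]
  pos <- wv > 0
  n_pos <- sum(pos)
  if (m > n_pos)
    stop(sprintf(
      "requested density %.4f needs %d edges but only %d positive weights exist; attainable maximum density is %.4f",
      density, m, n_pos, n_pos / m_possible))
  ri <- row(w)[off]; ci <- col(w)[off]
  ord <- order(-wv, ri, ci)
  keep <- ord[seq_len(m)]
  adj <- matrix(0, n, n, dimnames = dimnames(w))
  idx <- off[keep]
  adj[idx] <- if (mode == "binary") 1 else w[idx]
  structure(list(adjacency = adj, density = density, mode = mode,
                 source_method = if (inherits(mat, "conn_matrix")) mat$method else NA_character_,
                 lag = if (inherits(mat, "conn_matrix")) mat$lag else NA_integer_),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("<thresholded_network> %s, density %.2f (%d edges), %d nodes [%s lag %s]\n",
              x$mode, x$density, sum(x$adjacency != 0), nrow(x$adjacency),
              x$source_method, x$lag))
  invisible(x)
}

#' Maximum attainable density of a clipped matrix
#'
#' Fraction of the `n(n-1)` possible directed edges with strictly positive
#' weight. For antisymmetric matrices this is at most 0.5.
#'
#' @param mat A clipped [conn_matrix] or nonnegative matrix.
#' @return A scalar in `[0, 1]`.
#' @export
attainable_density <- function(mat) {
  w <- conn_weights(mat)
  n <- nrow(w)
  sum(w[row(w) != col(w)] > 0) / (n * (n - 1L))
}

as_network <- function(x, mode = "binary") {
  if (inherits(x, "thresholded_network")) return(x)
  adj <- as.matrix(x)
  structure(list(adjacency = adj, density = sum(adj != 0) / (nrow(adj) * (nrow(adj) - 1L)),
                 mode = if (all(adj %in% c(0, 1))) "binary" else mode,
                 source_method = NA_character_, lag = NA_integer_),
            class = "thresholded_network")
}
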