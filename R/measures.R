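#' Node degrees of a directed network
#'
#' In-degree is the number of inward edges of a node (`d_in(i) = sum_j a_ji`),
#' out-degree the number of outward edges (`d_out(i) = sum_j a_ij`), and the
#' degree their sum. In weighted mode the sums run over edge weights
#' (strengths), the standard weighted generalization.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return List with numeric vectors `in_degree`, `out_degree`, `degree`.
#' @export
degrees <- function(net) {
  net <- as_network(net)
  a <- net$adjacency
  d_in <- colSums(a)
  d_out <- rowSums(a)
  list(in_degree = d_in, out_degree = d_out, degree = d_in + d_out)
}

net_igraph <- function(net) {
  a <- net$adjacency
  if (net$mode == "weighted") {
    # shortest paths use inverse-weight edge lengths
    len <- a
    len[a > 0] <- 1 / a[a > 0]
    igraph::graph_from_adjacency_matrix(len, mode = "directed", weighted = TRUE,
                                        diag = FALSE)
  } else {
    igraph::graph_from_adjacency_matrix(a, mode = "directed", diag = FALSE)
  }
}

#' Directed shortest-path distances and network diameter
#'
#' All-pairs shortest directed path lengths: entry (i, j) is the number of
#' edges in the shortest directed path from i to j (`Inf` when j is
#' unreachable from i). In weighted mode path lengths sum inverse weights.
#' The diameter is the largest finite maximal distance over nodes; networks
#' with unreachable pairs are flagged `disconnected`.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return List with `distances` (matrix, `Inf` off-diagonal when
#'   unreachable), `diameter`, `disconnected`.
#' @export
directed_distances <- function(net) {
  net <- as_network(net)
  n <- nrow(net$adjacency)
  if (n == 1L)
    return(list(distances = matrix(0, 1, 1), diameter = 0, disconnected = FALSE))
  g <- net_igraph(net)
  D <- igraph::distances(g, mode = "out")
  dimnames(D) <- dimnames(net$adjacency)
  off <- D[row(D) != col(D)]
  finite <- off[is.finite(off)]
  list(distances = D,
       diameter = if (length(finite)) max(finite) else Inf,
       disconnected = any(!is.finite(off)))
}

#' Global efficiency (in, out and total)
#'
#' The regional out-global efficiency of node i is the average inverse
#' distance from i to all other nodes over directed paths leaving i; the
#' in-efficiency uses paths ending at i. Unreachable pairs contribute 0
#' (1/Inf = 0). The network-level values average the regional ones, and the
#' total is `E = (E_in + E_out) / 2`.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @param dist Optional precomputed result of [directed_distances].
#' @return List with scalars `E_in`, `E_out`, `E` and nodal vectors `e_in`,
#'   `e_out`.
#' @export
global_efficiency <- function(net, dist = NULL) {
  net <- as_network(net)
  n <- nrow(net$adjacency)
  if (n < 2L)
    return(list(E_in = 0, E_out = 0, E = 0, e_in = numeric(n), e_out = numeric(n)))
  if (is.null(dist)) dist <- directed_distances(net)
  D <- dist$distances
  inv <- 1 / D
  diag(inv) <- 0
  e_out <- rowSums(inv) / (n - 1L)
  e_in <- colSums(inv) / (n - 1L)
  E_in <- mean(e_in); E_out <- mean(e_out)
  list(E_in = E_in, E_out = E_out, E = (E_in + E_out) / 2,
       e_in = e_in, e_out = e_out)
}

#' Local efficiency (in, out and total)
#'
#' For each node i, the global efficiency measures are evaluated on the
#' subgraph induced by the neighbors of i (union of in- and out-neighbors,
#' excluding i itself). Nodes with fewer than two neighbors contribute 0.
#' Network-level values average over all nodes; `LE = (LE_in + LE_out) / 2`.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return List with scalars `LE_in`, `LE_out`, `LE` and nodal vectors
#'   `le_in`, `le_out`.
#' @export
local_efficiency <- function(net) {
  net <- as_network(net)
  a <- net$adjacency
  n <- nrow(a)
  le_in <- numeric(n); le_out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which((a[i, ] > 0 | a[, i] > 0) & seq_len(n) != i)
    if (length(nb) < 2L) next
    sub <- structure(list(adjacency = a[nb, nb, drop = FALSE],
                          density = NA_real_, mode = net$mode,
                          source_method = net$source_method, lag = net$lag),
                     class = "thresholded_network")
    ge <- global_efficiency(sub)
    le_in[i] <- ge$E_in
    le_out[i] <- ge$E_out
  }
  names(le_in) <- names(le_out) <- rownames(a)
  LE_in <- mean(le_in); LE_out <- mean(le_out)
  list(LE_in = LE_in, LE_out = LE_out, LE = (LE_in + LE_out) / 2,
       le_in = le_in, le_out = le_out)
}

#' Directed (cycle) clustering coefficient
#'
#' A triangle around node i is counted as completed when its three edges
#' form a directed cycle in either orientation. The clustering coefficient
#' is \deqn{C_i = (A^3)_{ii} / (d_{in} d_{out} - d^{<->}_i),} where
#' `d<->_i = (A^2)_ii` is the number of bilateral edges at i. Nodes with a
#' nonpositive denominator get `C_i = 0`. In weighted mode the Fagiolo
#' generalization is used: cycle intensity from the elementwise cube root of
#' the max-normalized weights, with degrees taken from the binary pattern.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Numeric vector of per-node clustering coefficients.
#' @export
directed_clustering <- function(net) {
  net <- as_network(net)
  a <- net$adjacency
  bin <- (a > 0) * 1
  d_in <- colSums(bin); d_out <- rowSums(bin)
  d_bi <- diag(bin %*% bin)
  if (net$mode == "weighted") {
    mx <- max(a)
    w <- if (mx > 0) (a / mx)^(1 / 3) else a
    cyc <- diag(w %*% w %*% w)
  } else {
    cyc <- diag(bin %*% bin %*% bin)
  }
  denom <- d_in * d_out - d_bi
  C <- ifelse(denom > 0, cyc / denom, 0)
  names(C) <- rownames(a)
  C
}

#' Directed transitivity
#'
#' Network-level triangle density, counting a triangle only when its three
#' directed edges form a cycle: \deqn{T = trace(A^3) / \sum_i [d_i(d_i - 1)
#' - 2 (A^2)_{ii}],} with `d_i = d_in(i) + d_out(i)` summed over nodes. A
#' nonpositive denominator yields 0. Weighted mode uses the Fagiolo cycle
#' intensity (cube-root normalized weights) in the numerator with the binary
#' denominator.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Scalar transitivity in `[0, 1]`.
#' @export
transitivity_directed <- function(net) {
  net <- as_network(net)
  a <- net$adjacency
  bin <- (a > 0) * 1
  d_tot <- colSums(bin) + rowSums(bin)
  d_bi <- diag(bin %*% bin)
  if (net$mode == "weighted") {
    mx <- max(a)
    w <- if (mx > 0) (a / mx)^(1 / 3) else a
    num <- sum(diag(w %*% w %*% w))
  } else {
    num <- sum(diag(bin %*% bin %*% bin))
  }
  denom <- sum(d_tot * (d_tot - 1) - 2 * d_bi)
  if (denom <= 0) 0 else num / denom
}
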