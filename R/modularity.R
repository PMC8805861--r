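# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Directed modularity of a partition
#'
#' Leicht-Newman directed quality function
#' \deqn{Q = (1/m) \sum_{ij} [A_{ij} - \gamma k^{out}_i k^{in}_j / m]
#' \delta(c_i, c_j),} with `m` the total edge weight.
#'
#' @param adjacency Square (weighted) adjacency matrix.
#' @param membership Integer community labels, one per node.
#' @param gamma Resolution parameter (1 reproduces standard modularity).
#' @return Scalar Q in `[-1, 1]`.
#' @export
directed_modularity <- function(adjacency, membership, gamma = 1) {
  a <- as.matrix(adjacency)
  m <- sum(a)
  if (m <= 0) stop("modularity undefined for an empty network")
  k_out <- rowSums(a); k_in <- colSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    q <- q + sum(a[idx, idx]) - gamma * sum(k_out[idx]) * sum(k_in[idx]) / m
  }
  q / m
}

# one greedy local-move + aggregation cycle; order = node sweep order
louvain_level <- function(W, gamma, order) {
  n <- nrow(W)
  comm <- seq_len(n)
  k_out <- rowSums(W); k_in <- colSums(W); m <- sum(W)
  sig_out <- k_out; sig_in <- k_in    # per-community totals (comm = 1..n init)
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      # take i out of its community
      sig_out[ci] <- sig_out[ci] - k_out[i]
      sig_in[ci] <- sig_in[ci] - k_in[i]
      wi_to <- W[i, ]; wi_from <- W[, i]
      # candidate communities: those of in/out neighbors, plus current
      nb <- which((wi_to > 0 | wi_from > 0) & seq_len(n) != i)
      cand <- unique(c(ci, comm[nb]))
      best_c <- ci; best_gain <- -Inf
      for (c in cand) {
        idx <- comm == c
        idx[i] <- FALSE
        link <- sum(wi_to[idx]) + sum(wi_from[idx])
        gain <- (link - gamma * (k_out[i] * sig_in[c] + k_in[i] * sig_out[c]) / m) / m
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_c <- c
        }
      }
      comm[i] <- best_c
      sig_out[best_c] <- sig_out[best_c] + k_out[i]
      sig_in[best_c] <- sig_in[best_c] + k_in[i]
      if (best_c != ci) {
        moved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = match(comm, unique(comm)), improved = improved_any)
}

louvain_once <- function(A, gamma) {
  n <- nrow(A)
  membership <- seq_len(n)
  W <- A
  repeat {
    lvl <- louvain_level(W, gamma, sample.int(nrow(W)))
    if (!lvl$improved) break
    membership <- lvl$membership[membership]
    nc <- max(lvl$membership)
    if (nc == nrow(W)) break
    # aggregate communities into supernodes (self-loops keep internal weight)
    M <- matrix(0, nrow(W), nc)
    M[cbind(seq_len(nrow(W)), lvl$membership)] <- 1
    W <- t(M) %*% W %*% M
  }
  membership
}

#' Louvain community detection with directed modularity
#'
#' Greedy Louvain optimization of the directed (Leicht-Newman) modularity at
#' resolution `gamma`. The sweep order is randomized, so the algorithm is
#' restarted `n_restarts` times under a reproducible seed and the partition
#' with the best Q is returned. Weighted adjacencies are handled natively.
#'
#' @param net A `thresholded_network` (or adjacency matrix) with at least
#'   one edge.
#' @param gamma Resolution parameter; 1 is the standard choice.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed for the restart randomization (RNG state of the
#'   caller is restored).
#' @return List with `Q` (best modularity) and `membership` (integer
#'   community labels of the best partition).
#' @export
modularity_louvain <- function(net, gamma = 1, n_restarts = 100L, seed = 1L) {
  net <- as_network(net)
  A <- net$adjacency
  if (sum(A) <= 0) stop("modularity requires at least one edge")
  with_seed(seed, {
    best_q <- -Inf; best_m <- NULL
    for (r in seq_len(n_restarts)) {
      memb <- louvain_once(A, gamma)
      q <- directed_modularity(A, memb, gamma)
      if (q > best_q) {
        best_q <- q
        best_m <- memb
      }
    }
    list(Q = best_q, membership = best_m)
  })
}
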