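# Independent brute-force oracles. These deliberately avoid the package's
# code paths (igraph, vectorized correlation): textbook formulas, explicit
# loops and exhaustive enumeration only.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  sum((x - mx) * (y - my)) / ((n - 1) * sx * sy)
}

# slices segments explicitly and applies the textbook Pearson formula
oracle_lagged <- function(X, d) {
  n <- nrow(X); N <- ncol(X)
  out <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      xj <- X[j, 1:(N - d)]
      xk <- X[k, (d + 1):N]
      out[j, k] <- oracle_pearson(xj, xk)
    }
  }
  out
}

# Floyd-Warshall all-pairs shortest directed paths (unit edge lengths)
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(list(e_in = numeric(n), e_out = numeric(n),
                         E_in = 0, E_out = 0, E = 0))
  D <- oracle_distances(A)
  e_out <- numeric(n); e_in <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (is.finite(D[i, j])) e_out[i] <- e_out[i] + 1 / D[i, j]
      if (is.finite(D[j, i])) e_in[i] <- e_in[i] + 1 / D[j, i]
    }
  }
  e_out <- e_out / (n - 1); e_in <- e_in / (n - 1)
  list(e_in = e_in, e_out = e_out, E_in = mean(e_in), E_out = mean(e_out),
       E = (mean(e_in) + mean(e_out)) / 2)
}

# materializes each neighbor subgraph explicitly
oracle_local_eff <- function(A) {
  n <- nrow(A)
  le_in <- numeric(n); le_out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(which(A[i, ] > 0 | A[, i] > 0), i)
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    ge <- oracle_global_eff(sub)
    le_in[i] <- ge$E_in; le_out[i] <- ge$E_out
  }
  list(le_in = le_in, le_out = le_out, LE_in = mean(le_in),
       LE_out = mean(le_out), LE = (mean(le_in) + mean(le_out)) / 2)
}

# explicit ordered-triple enumeration of directed 3-cycles around each node
oracle_clustering <- function(A) {
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    cyc <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      cyc <- cyc + A[i, j] * A[j, k] * A[k, i]
    }
    d_in <- 0; d_out <- 0; d_bi <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      d_in <- d_in + A[j, i]; d_out <- d_out + A[i, j]
      d_bi <- d_bi + A[i, j] * A[j, i]
    }
    denom <- d_in * d_out - d_bi
    C[i] <- if (denom > 0) cyc / denom else 0
  }
  C
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  cyc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    cyc <- cyc + A[i, j] * A[j, k] * A[k, i]
  }
  denom <- 0
  for (i in seq_len(n)) {
    d_in <- sum(A[-i, i]); d_out <- sum(A[i, -i])
    d_bi <- sum(A[i, -i] * A[-i, i])
    denom <- denom + (d_in + d_out) * (d_in + d_out - 1) - 2 * d_bi
  }
  if (denom <= 0) 0 else cyc / denom
}

# all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(s, mx) {
    if (length(s) == n) {
      out[[length(out) + 1]] <<- s
      return(invisible())
    }
    for (v in seq_len(mx + 1)) recurse(c(s, v), max(mx, v))
  }
  recurse(integer(0), 0L)
  out
}

# independent directed-modularity evaluation (double loop over node pairs)
oracle_Q <- function(A, memb, gamma = 1) {
  n <- nrow(A)
  m <- sum(A)
  k_out <- rowSums(A); k_in <- colSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j])
      q <- q + A[i, j] - gamma * k_out[i] * k_in[j] / m
  }
  q / m
}

oracle_max_modularity <- function(A, gamma = 1) {
  parts <- all_partitions(nrow(A))
  best <- -Inf; best_p <- NULL
  for (p in parts) {
    q <- oracle_Q(A, p, gamma)
    if (q > best) {
      best <- q
      best_p <- p
    }
  }
  list(Q = best, membership = best_p)
}

# BH step-up by the book
oracle_bh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(n)) if (ps[i] <= q * i / n) k <- i
  rej <- logical(n)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

random_digraph <- function(n, p = 0.3) {
  A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

# adjacency matrix from the bits of an integer code (row-major off-diagonal)
digraph_from_code <- function(code, n) {
  bits <- as.integer(intToBits(code))[seq_len(n * (n - 1))]
  A <- matrix(0, n, n)
  k <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    A[i, j] <- bits[k]
    k <- k + 1
  }
  A
}

expect_measures_match_oracle <- function(A, tol = 1e-12) {
  dg <- dirconn::degrees(A)
  expect_equal(unname(dg$in_degree), colSums(A))
  expect_equal(unname(dg$out_degree), rowSums(A))
  D <- dirconn::directed_distances(A)
  Do <- oracle_distances(A)
  expect_equal(unname(D$distances), unname(Do), tolerance = tol)
  ge <- dirconn::global_efficiency(A)
  geo <- oracle_global_eff(A)
  expect_equal(unname(ge$e_in), geo$e_in, tolerance = tol)
  expect_equal(unname(ge$e_out), geo$e_out, tolerance = tol)
  expect_equal(ge$E, geo$E, tolerance = tol)
  le <- dirconn::local_efficiency(A)
  leo <- oracle_local_eff(A)
  expect_equal(unname(le$le_in), leo$le_in, tolerance = tol)
  expect_equal(unname(le$le_out), leo$le_out, tolerance = tol)
  expect_equal(le$LE, leo$LE, tolerance = tol)
  expect_equal(unname(dirconn::directed_clustering(A)), oracle_clustering(A),
               tolerance = tol)
  expect_equal(dirconn::transitivity_directed(A), oracle_transitivity(A),
               tolerance = tol)
}
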