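fx <- fixture_networks()

test_that("degrees satisfy hand cases and the handshake identity", {
  dag <- matrix(c(0, 1, 1, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  d <- degrees(dag)
  expect_equal(unname(d$out_degree), c(2, 1, 0))
  expect_equal(unname(d$in_degree), c(0, 1, 2))
  expect_equal(unname(d$degree), c(2, 2, 2))

  d3 <- degrees(fx$cycle3$adjacency)
  expect_equal(unname(d3$in_degree), c(1, 1, 1))
  expect_equal(unname(d3$out_degree), c(1, 1, 1))

  set.seed(13)
  for (r in 1:10) {
    A <- random_digraph(8)
    d <- degrees(A)
    expect_equal(sum(d$in_degree), sum(A))
    expect_equal(sum(d$out_degree), sum(A))
  }
})

test_that("distances and diameter match hand cases and handle disconnection", {
  dd <- directed_distances(fx$cycle3$adjacency)
  expect_true(all(dd$distances[row(dd$distances) != col(dd$distances)] %in% c(1, 2)))
  expect_equal(dd$diameter, 2)
  expect_false(dd$disconnected)

  k4 <- fx$complete4$adjacency
  dk <- directed_distances(k4)
  expect_equal(dk$diameter, 1)

  # two disconnected bidirectional dyads
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1
  ddy <- directed_distances(dy)
  expect_true(ddy$disconnected)
  expect_equal(ddy$diameter, 1)             # over finite distances only
  expect_equal(ddy$distances[1, 3], Inf)
})

test_that("efficiency hand values hold", {
  expect_equal(global_efficiency(fx$cycle3$adjacency)$E, 0.75)
  e3 <- global_efficiency(fx$cycle3$adjacency)
  expect_equal(unname(e3$e_out), rep(0.75, 3))
  expect_equal(global_efficiency(fx$complete4$adjacency)$E, 1)
  expect_equal(global_efficiency(matrix(0, 4, 4))$E, 0)
  expect_equal(local_efficiency(fx$complete4$adjacency)$LE, 1)
  expect_equal(unname(local_efficiency(fx$star5$adjacency)$le_in[1]), 0)
  expect_equal(unname(local_efficiency(fx$star5$adjacency)$le_out[1]), 0)
})

test_that("clustering and transitivity follow the cycle convention", {
  expect_equal(unname(directed_clustering(fx$cycle3$adjacency)), c(1, 1, 1))
  expect_equal(transitivity_directed(fx$cycle3$adjacency), 0.5)
  # fully bidirectional triangle: (A^3)_ii = 2, d_in = d_out = 2, d_bi = 2
  expect_equal(unname(directed_clustering(fx$bidir_triangle$adjacency)),
               c(1, 1, 1))
  # feed-forward (acyclic) triangle closes no cycle
  expect_equal(unname(directed_clustering(fx$dag_triangle$adjacency)),
               c(0, 0, 0))
  expect_equal(transitivity_directed(fx$dag_triangle$adjacency), 0)
  expect_equal(transitivity_directed(matrix(0, 5, 5)), 0)
})

test_that("all binary measures match the brute-force oracles on random digraphs", {
  set.seed(77)
  for (r in 1:40) {
    A <- random_digraph(sample(4:10, 1), runif(1, 0.1, 0.6))
    expect_measures_match_oracle(A)
  }
})

test_that("transitivity stays within [0, 1] on exhaustive 3-node digraphs", {
  for (code in 0:(2^6 - 1)) {
    A <- digraph_from_code(code, 3)
    T <- transitivity_directed(A)
    expect_gte(T, 0)
    expect_lte(T, 1)
  }
})

test_that("in/out variants coincide on symmetric matrices", {
  set.seed(31)
  A <- random_digraph(8, 0.4)
  A <- pmax(A, t(A))   # bidirectionalize
  d <- degrees(A)
  expect_equal(d$in_degree, d$out_degree)
  ge <- global_efficiency(A)
  expect_equal(ge$e_in, ge$e_out)
  expect_equal(ge$E_in, ge$E_out)
  le <- local_efficiency(A)
  expect_equal(le$LE_in, le$LE_out)
  # directed cycle clustering reduces to the undirected value on
  # bidirectionalized graphs: compare against igraph's undirected clustering
  und <- igraph::transitivity(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"),
    type = "local", isolates = "zero")
  expect_equal(unname(directed_clustering(A)), und, tolerance = 1e-12)
})

test_that("identities E = (E_in + E_out)/2 and LE = (LE_in + LE_out)/2 hold", {
  set.seed(19)
  for (r in 1:10) {
    A <- random_digraph(7, 0.35)
    ge <- global_efficiency(A)
    expect_identical(ge$E, (ge$E_in + ge$E_out) / 2)
    le <- local_efficiency(A)
    expect_identical(le$LE, (le$LE_in + le$LE_out) / 2)
  }
})

test_that("weighted generalizations behave sensibly", {
  set.seed(23)
  w <- matrix(runif(49), 7); diag(w) <- 0
  m <- conn_matrix(w, "lagged", clipped = TRUE)
  netb <- threshold_by_density(m, 0.3, "binary")
  netw <- threshold_by_density(m, 0.3, "weighted")
  # same edge pattern
  expect_identical(netw$adjacency > 0, netb$adjacency > 0)
  # weighted degree = strength
  dw <- degrees(netw)
  expect_equal(unname(dw$out_degree), unname(rowSums(netw$adjacency)))
  # weighted distances use inverse weights: stronger edges are shorter
  ddw <- directed_distances(netw)
  nz <- which(netw$adjacency > 0, arr.ind = TRUE)
  i <- nz[1, 1]; j <- nz[1, 2]
  expect_lte(ddw$distances[i, j], 1 / netw$adjacency[i, j])
  # weighted clustering bounded by [0, 1] after max-normalization
  cw <- directed_clustering(netw)
  expect_true(all(cw >= 0 & cw <= 1))
  expect_true(transitivity_directed(netw) >= 0 &&
                transitivity_directed(netw) <= 1)
  # uniform weights reduce weighted measures to binary ones
  u <- (w > 0.5) * 1
  netu <- structure(list(adjacency = u, density = NA, mode = "weighted",
                         source_method = NA, lag = NA),
                    class = "thresholded_network")
  expect_equal(directed_clustering(netu), directed_clustering(u))
})
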