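test_that("ring lattice realizes the prescribed nearest-neighbor structure", {
  cyc <- generate_ring_lattice(6, 2)
  expect_equal(n_edges(cyc), 6L)            # the 6-cycle
  expect_true(all(degrees_of(cyc) == 2L))

  lat <- generate_ring_lattice(1000, 4)
  expect_equal(n_edges(lat), 2000L)         # k_nn * N / 2 undirected edges
  expect_true(all(degrees_of(lat) == 4L))

  expect_error(generate_ring_lattice(10, 3), class = "netstab_invalid_parameter")
  expect_error(generate_ring_lattice(4, 4), class = "netstab_invalid_parameter")
})

test_that("rewiring moves exactly round(p_rew * edges) edges and keeps the graph simple", {
  lat <- generate_ring_lattice(1000, 4)
  expect_identical(rewire(lat, 0, 1), lat)

  rw <- rewire(lat, 0.05, 7)
  expect_equal(n_edges(rw), 2000L)
  moved <- length(setdiff(edge_key(rw), edge_key(lat)))
  expect_equal(moved, 100L)                 # round(0.05 * 2000)
  expect_true(all(rw$edges[, 1] < rw$edges[, 2]))   # no self-pairs
  expect_equal(anyDuplicated(edge_key(rw)), 0L)     # no duplicate edges
})

test_that("sparse rewiring keeps clustering high while path length collapses", {
  lat <- generate_ring_lattice(1000, 4)
  C0 <- clustering_coefficient(lat)
  L0 <- average_shortest_path(lat)
  seeds <- derive_seeds(321, 100)
  Cs <- Ls <- numeric(100)
  for (i in 1:100) {
    rw <- rewire(lat, 0.05, seeds[i])
    Cs[i] <- clustering_coefficient(rw)
    Ls[i] <- suppressWarnings(average_shortest_path(rw))
  }
  expect_gt(mean(Cs) / C0, 0.8)     # clustering stays near the regular value
  expect_lt(mean(Ls) / L0, 0.15)    # path length drops by an order of magnitude
})

test_that("preferential attachment grows simple trees and near-complete edge budgets", {
  tiny <- generate_ba(3, 1, 1, 11)
  expect_equal(n_edges(tiny), 2L)           # forced attachment: a tree
  expect_equal(sum(degrees_of(tiny)), 4L)

  for (s in c(2, 17, 300)) {
    ba <- generate_ba(1000, 2, 0, s)
    deficit <- 2 * 1000 - n_edges(ba)
    expect_lt(deficit, 10)                  # small edge deficit from the empty start
    expect_equal(anyDuplicated(edge_key(ba)), 0L)
  }
  expect_error(generate_ba(10, 10, 0, 1), class = "netstab_invalid_parameter")
})

test_that("Kronecker zero counts obey the product rule on small seeds", {
  cases <- expand.grid(dim = 2:3, power = 2:3)
  for (r in seq_len(nrow(cases))) {
    d <- cases$dim[r]; p <- cases$power[r]
    zeros <- d^2 - 2   # one symmetric off-diagonal pair nonzero
    K <- generate_kronecker(d, zeros, p, 100 + r)
    W <- as.matrix(K)
    expect_equal(nrow(W), d^p)
    expect_equal(count_zeros(K), as.integer(d^(2 * p) - 2^p))
    expect_identical(W, t(W))               # symmetric values
    expect_true(all(abs(W) <= 1))
  }
  # reference seed: 10 x 10 with 82 zeros, 9 symmetric nonzero pairs
  K2 <- generate_kronecker(10, 82, 2, 5)
  expect_equal(count_zeros(K2), as.integer(10^4 - 18^2))
})

test_that("Erdos-Renyi link counts follow the binomial law", {
  empty <- generate_er(100, 0, 1)
  expect_equal(count_zeros(empty, include_diagonal = FALSE), as.integer(100^2 - 100))
  full <- generate_er(50, 1, 1)
  expect_equal(count_zeros(full, include_diagonal = FALSE), 0L)

  M <- generate_er(100, 0.1, 99)
  nz <- (100^2 - 100) - count_zeros(M, include_diagonal = FALSE)
  expect_lt(abs(nz - 990), 3 * sqrt(9900 * 0.1 * 0.9))
  expect_error(generate_er(10, 1.2, 1), class = "netstab_invalid_parameter")
})

test_that("weight assignment is structurally symmetric with independent directions", {
  st <- rewire(generate_ring_lattice(200, 4), 0.05, 3)
  M <- as.matrix(assign_weights(st, 4))
  expect_identical(M != 0, t(M != 0))            # pattern symmetric
  idx <- st$edges
  expect_true(all(M[idx] != M[idx[, 2:1]]))      # values differ a.s.
  expect_true(all(abs(M) <= 1))
  expect_true(all(diag(M) == 0))
  # U[-1, 1] mean-zero check at 3 standard errors
  w <- c(M[idx], M[idx[, 2:1]])
  expect_lt(abs(mean(w)), 3 * (1 / sqrt(3)) / sqrt(length(w)))
  # edge case: empty structure gives the zero matrix
  expect_true(all(as.matrix(assign_weights(
    adjacency_structure(4, matrix(integer(0), ncol = 2)), 1)) == 0))
})

test_that("self-coupling fills the diagonal from the interval and touches nothing else", {
  M0 <- generate_er(200, 0.05, 8)
  iv <- varied_interval(-0.1)                    # the reference first interval
  M1 <- add_self_coupling(M0, iv, 9)
  d <- diag(as.matrix(M1))
  expect_true(all(d >= -1.0 & d <= -0.1))
  off <- row(as.matrix(M0)) != col(as.matrix(M0))
  expect_identical(as.matrix(M1)[off], as.matrix(M0)[off])
  expect_lt(abs(mean(d) - (-0.55)), 3 * (0.9 / sqrt(12)) / sqrt(200))
  expect_error(coupling_interval(-0.5, 0.4), class = "netstab_invalid_parameter")
  expect_error(coupling_interval(-0.3, -0.4), class = "netstab_invalid_parameter")
})

test_that("identical seeds reproduce bit-identical matrices", {
  for (topo in c("smallworld", "scalefree", "kronecker", "erdosrenyi")) {
    cfg <- if (topo == "kronecker") net_config(topo, power = 2)
           else net_config(topo, n_nodes = 100)
    a <- generate_network(cfg, 42)
    b <- generate_network(cfg, 42)
    expect_identical(as.matrix(a), as.matrix(b))
    c2 <- generate_network(cfg, 43)
    expect_false(identical(as.matrix(a), as.matrix(c2)))
  }
})

test_that("matched parameters give the same directed-link budget for both topologies", {
  sw <- generate_network(net_config("smallworld", n_nodes = 500), 21)
  sf <- generate_network(net_config("scalefree", n_nodes = 500), 22)
  links_sw <- sum(as.matrix(sw) != 0)
  links_sf <- sum(as.matrix(sf) != 0)
  expect_equal(links_sw, 4 * 500)                      # k_nn * N directed links
  expect_lt(links_sw - links_sf, 20)                   # BA deficit only
})
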