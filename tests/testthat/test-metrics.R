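test_that("clustering coefficient matches closed forms", {
  triangle <- adjacency_structure(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient(triangle), 1.0)

  star5 <- adjacency_structure(5, cbind(1, 2:5))
  expect_equal(clustering_coefficient(star5), 0.0)

  # k-regular ring lattice: C = 3 (k - 2) / (4 (k - 1))
  for (k in c(4, 6, 8)) {
    lat <- generate_ring_lattice(60, k)
    expect_equal(clustering_coefficient(lat), 3 * (k - 2) / (4 * (k - 1)))
  }
  expect_identical(clustering_coefficient(generate_ring_lattice(1000, 4)), 0.5)
})

test_that("average shortest path matches brute-force BFS", {
  complete5 <- adjacency_structure(5, t(combn(5, 2)))
  expect_equal(as.numeric(average_shortest_path(complete5)), 1.0)

  path3 <- adjacency_structure(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(as.numeric(average_shortest_path(path3)), 4 / 3)

  for (n in 4:12) {
    cyc <- generate_ring_lattice(n, 2)
    expect_equal(as.numeric(average_shortest_path(cyc)), bfs_mean_path(cyc))
  }
  # regular lattice used throughout: per-node distance sum 125250 over 999 pairs
  expect_equal(as.numeric(average_shortest_path(generate_ring_lattice(1000, 4))),
               125250 / 999, tolerance = 1e-12)

  two_comp <- adjacency_structure(4, rbind(c(1, 2), c(3, 4)))
  expect_warning(L <- average_shortest_path(two_comp), "disconnected")
  expect_equal(as.numeric(L), 1.0)          # reachable pairs only
  expect_false(attr(L, "connected"))
})

test_that("degree distributions are per-trial normalized then averaged", {
  cyc6 <- generate_ring_lattice(6, 2)
  h1 <- degree_distribution(list(cyc6))
  expect_equal(h1$k, 2)
  expect_equal(h1$p, 1)

  path6 <- adjacency_structure(6, cbind(1:5, 2:6))
  h2 <- degree_distribution(list(cyc6, path6))
  expect_equal(h2$p[h2$k == 2], (1 + 4 / 6) / 2)   # hand count
  expect_equal(h2$p[h2$k == 1], (2 / 6) / 2)
  expect_equal(sum(h2$p), 1, tolerance = 1e-9)

  expect_error(degree_distribution(list()), class = "netstab_invalid_parameter")
})

test_that("power-law fit recovers exact parameters from noiseless degree data", {
  k <- 5:200
  gamma <- 2.5; k_min <- 2
  h <- data.frame(k = k, p = (gamma - 1) * k_min^(gamma - 1) * k^(-gamma))
  class(h) <- c("degree_histogram", "data.frame")
  fit <- fit_degree_powerlaw(h, fit_floor = 5)
  expect_equal(fit$gamma, 2.5, tolerance = 1e-6)
  expect_equal(fit$k_min, 2, tolerance = 1e-6)
  expect_gt(fit$gamma, 1)                          # normalizability

  degenerate <- data.frame(k = c(5, 6), p = c(0.5, 0.5))
  expect_error(fit_degree_powerlaw(degenerate, 5), class = "netstab_fit_unreliable")
})

test_that("small-world degree distributions are not heavy-tailed", {
  seeds <- derive_seeds(77, 50)
  structs <- lapply(seeds, function(s)
    rewire(generate_ring_lattice(1000, 4), 0.05, s))
  h <- degree_distribution(structs)
  # mass concentrated at the lattice degree; nothing beyond a short tail
  expect_gt(h$p[h$k == 4], 0.8)
  expect_lt(max(h$k), 12)
  got <- tryCatch(fit_degree_powerlaw(h, 5), netstab_error = function(e) e)
  if (!inherits(got, "error")) expect_false(got$gamma >= 2 && got$gamma <= 3)
  else succeed("power-law fit rejected on small-world degrees")
})

test_that("connectance formulas agree under both matched parameter families", {
  expect_equal(connectance_sw(1000, 4), 4 / 999)
  expect_equal(connectance_sw(2, 1), 1.0)
  expect_equal(connectance_sf(1000, 2, 0), 4 / 999)
  expect_equal(connectance_sf(1000, 2, 1000), 0)   # m0 = N leaves no added nodes

  sols <- matched_parameters(4)
  expect_equal(sols[[1]], list(m = 2L, m0 = 0L))
  expect_equal(sols[[2]]$m, 4L)
  for (N in c(100, 500, 1000, 1500)) {
    expect_equal(connectance_sf(N, sols[[1]]$m, sols[[1]]$m0), connectance_sw(N, 4))
    expect_equal(connectance_sf(N, sols[[2]]$m, N / 2), connectance_sw(N, 4))
  }
  expect_error(matched_parameters(3), class = "netstab_invalid_parameter")
})

test_that("zero counting distinguishes full and off-diagonal conventions", {
  Z <- matrix(0, 10, 10)
  expect_equal(count_zeros(Z), 100L)
  expect_equal(count_zeros(Z, include_diagonal = FALSE), 90L)

  M <- add_self_coupling(generate_network(net_config("smallworld", n_nodes = 100), 3),
                         varied_interval(-0.1), 4)
  expect_equal(count_zeros(M), as.integer(100^2 - 400 - 100))
  expect_equal(count_zeros(M, include_diagonal = FALSE), as.integer(100^2 - 400 - 100))
})
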