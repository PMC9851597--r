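#' Regular ring lattice
#'
#' Builds the regular starting network of the Watts–Strogatz construction:
#' `n_nodes` nodes on a ring, each linked to its `k_nn` nearest neighbors
#' (`k_nn / 2` on each side).
#'
#' @param n_nodes Number of nodes; must exceed `k_nn`.
#' @param k_nn Even number of nearest neighbors per node.
#' @return An [adjacency_structure] with `n_nodes * k_nn / 2` edges.
#' @examples
#' generate_ring_lattice(6, 2)   # the 6-cycle
#' @export
generate_ring_lattice <- function(n_nodes, k_nn) {
  n_nodes <- as.integer(n_nodes); k_nn <- as.integer(k_nn)
  if (k_nn < 2L || k_nn %% 2L != 0L)
    stop_invalid("generate_ring_lattice: k_nn must be even and >= 2")
  if (n_nodes <= k_nn)
    stop_invalid("generate_ring_lattice: need n_nodes > k_nn")
  half <- k_nn %/% 2L
  i <- rep(seq_len(n_nodes), each = half)
  d <- rep(seq_len(half), times = n_nodes)
  j <- ((i - 1L + d) %% n_nodes) + 1L
  adjacency_structure(n_nodes, cbind(i, j))
}

#' Rewire an exact fraction of lattice edges
#'
#' Performs the exact-count variant of Watts–Strogatz rewiring:
#' `round(p_rew * n_edges)` distinct edges are selected and each has one
#' uniformly chosen endpoint replaced by a uniformly drawn new node, subject
#' to the constraints that no edge is rewired twice, no self-loop is created,
#' and no duplicate edge is created. Edge count is preserved exactly.
#'
#' @param lattice An [adjacency_structure] (typically from
#'   [generate_ring_lattice()]).
#' @param p_rew Rewiring fraction in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @param max_retries Retries per edge when a candidate endpoint collides.
#' @return A rewired [adjacency_structure] with the same edge count.
#' @export
rewire <- function(lattice, p_rew, rng_seed, max_retries = 1000L) {
  stopifnot(inherits(lattice, "adjacency_structure"))
  if (!is.finite(p_rew) || p_rew < 0 || p_rew > 1)
    stop_invalid("rewire: p_rew must lie in [0, 1]")
  m <- nrow(lattice$edges)
  n_rew <- round(p_rew * m)
  if (n_rew == 0L) return(lattice)
  n <- lattice$n_nodes
  edges <- lattice$edges
  withr::with_seed(as.integer(rng_seed), {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj[edges[, 2:1]] <- TRUE
    picked <- sample.int(m, n_rew)   # no edge rewired twice
    for (e in picked) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      keep <- if (stats::runif(1) < 0.5) a else b
      drop <- if (keep == a) b else a
      done <- FALSE
      for (r in seq_len(max_retries)) {
        cand <- sample.int(n, 1L)
        if (cand != keep && !adj[keep, cand]) {
          adj[keep, drop] <- adj[drop, keep] <- FALSE
          adj[keep, cand] <- adj[cand, keep] <- TRUE
          edges[e, ] <- c(min(keep, cand), max(keep, cand))
          done <- TRUE
          break
        }
      }
      if (!done)
        stop_generation("rewire: no admissible endpoint found (saturated node)")
    }
  })
  adjacency_structure(n, edges)
}

#' Scale-free network by preferential attachment
#'
#' Grows a Barabási–Albert-type network: starting from `m0` unconnected
#' nodes, each of the `n_nodes - m0` added nodes connects `min(m, #existing)`
#' distinct edges to existing nodes, sampled without replacement with
#' probability proportional to degree + 1 (the +1 smoothing gives isolated
#' nodes a nonzero attachment probability).
#'
#' With `m0 = 0` the first added node places no edge and the second places
#' one, so the realized edge count falls a few edges short of
#' `m * (n_nodes - m0)`.
#'
#' @param n_nodes Number of nodes; must exceed `m0`.
#' @param m Edges added per new node (`1 <= m < n_nodes`).
#' @param m0 Number of initially unconnected nodes.
#' @param rng_seed Integer seed.
#' @return An [adjacency_structure] (simple, undirected).
#' @export
generate_ba <- function(n_nodes, m, m0, rng_seed) {
  n_nodes <- as.integer(n_nodes); m <- as.integer(m); m0 <- as.integer(m0)
  if (m < 1L || m >= n_nodes)
    stop_invalid("generate_ba: need 1 <= m < n_nodes")
  if (m0 < 0L || m0 >= n_nodes)
    stop_invalid("generate_ba: need 0 <= m0 < n_nodes")
  deg <- integer(n_nodes)
  edges <- matrix(0L, nrow = n_nodes * m, ncol = 2L)
  ne <- 0L
  first <- max(m0, 1L) + 1L   # with m0 = 0 the first node only seeds the population
  withr::with_seed(as.integer(rng_seed), {
    if (first <= n_nodes) for (v in first:n_nodes) {
      n_exist <- v - 1L
      mm <- min(m, n_exist)
      targets <- if (n_exist == 1L) 1L
                 else sample.int(n_exist, mm, prob = deg[seq_len(n_exist)] + 1)
      edges[ne + seq_len(mm), 1L] <- targets
      edges[ne + seq_len(mm), 2L] <- v
      ne <- ne + mm
      deg[v] <- deg[v] + mm
      deg[targets] <- deg[targets] + 1L
    }
  })
  adjacency_structure(n_nodes, edges[seq_len(ne), , drop = FALSE])
}

#' Kronecker self-similar interaction matrix
#'
#' Draws a random symmetric seed matrix `S` of dimension `seed_dim` with
#' exactly `seed_zeros` zero entries (zero pattern symmetric; nonzero values
#' uniform on `[-1, +1]` and shared across the symmetric pair) and returns
#' the `power`-fold Kronecker product `S %x% S (%x% S ...)`. With the
#' reference parameters `seed_dim = 10`, `seed_zeros = 82` this yields
#' 100 x 100 (`power = 2`) and 1000 x 1000 (`power = 3`) matrices whose zero
#' counts are `10^(2 * power) - 18^power`.
#'
#' Nonzero seed entries are placed as uniformly chosen symmetric off-diagonal
#' pairs, keeping the diagonal zero (free for explicit self-coupling), with
#' single diagonal entries used only when the nonzero count forces them.
#'
#' @param seed_dim Seed matrix dimension.
#' @param seed_zeros Number of zero entries in the seed.
#' @param power Number of Kronecker factors (2 or 3 for the reference sizes).
#' @param rng_seed Integer seed.
#' @return An [interaction_matrix] of dimension `seed_dim^power`.
#' @export
generate_kronecker <- function(seed_dim, seed_zeros, power, rng_seed) {
  seed_dim <- as.integer(seed_dim); seed_zeros <- as.integer(seed_zeros)
  power <- as.integer(power)
  if (seed_dim < 2L) stop_invalid("generate_kronecker: seed_dim must be >= 2")
  if (power < 1L) stop_invalid("generate_kronecker: power must be >= 1")
  if (seed_zeros < 0L || seed_zeros > seed_dim^2)
    stop_invalid("generate_kronecker: seed_zeros out of range")
  nz <- seed_dim^2 - seed_zeros
  max_off_pairs <- (seed_dim^2 - seed_dim) %/% 2L
  n_diag <- max(0L, nz - 2L * max_off_pairs)
  if ((nz - n_diag) %% 2L == 1L) n_diag <- n_diag + 1L
  if (n_diag > seed_dim)
    stop_invalid("generate_kronecker: seed_zeros incompatible with a symmetric pattern")
  n_pairs <- (nz - n_diag) %/% 2L
  withr::with_seed(as.integer(rng_seed), {
    S <- matrix(0, seed_dim, seed_dim)
    ut <- which(upper.tri(S))
    pick <- if (n_pairs > 0L) ut[sample.int(length(ut), n_pairs)] else integer(0)
    vals <- stats::runif(n_pairs, -1, 1)
    S[pick] <- vals
    S <- S + t(S)   # shared value across the symmetric pair
    if (n_diag > 0L)
      diag(S)[sample.int(seed_dim, n_diag)] <- stats::runif(n_diag, -1, 1)
    K <- S
    if (power >= 2L) for (p in 2:power) K <- K %x% S
  })
  interaction_matrix(K, topology = "kronecker", rng_seed = as.integer(rng_seed))
}

#' Erdős–Rényi-type random interaction matrix
#'
#' Each off-diagonal entry is independently nonzero with probability
#' `connectance`, with value uniform on `[-1, +1]`; the diagonal is left zero
#' until [add_self_coupling()] is applied. This is the Gardner–Ashby /
#' May-style random interaction matrix.
#'
#' @param n_nodes Number of nodes.
#' @param connectance Probability in `[0, 1]` that a directed link exists.
#' @param rng_seed Integer seed.
#' @return An [interaction_matrix].
#' @export
generate_er <- function(n_nodes, connectance, rng_seed) {
  n_nodes <- as.integer(n_nodes)
  if (!is.finite(connectance) || connectance < 0 || connectance > 1)
    stop_invalid("generate_er: connectance must lie in [0, 1]")
  withr::with_seed(as.integer(rng_seed), {
    M <- matrix(0, n_nodes, n_nodes)
    off <- which(row(M) != col(M))
    on <- off[stats::runif(length(off)) < connectance]
    M[on] <- stats::runif(length(on), -1, 1)
  })
  interaction_matrix(M, topology = "erdosrenyi", rng_seed = as.integer(rng_seed))
}

#' Assign asymmetric bidirectional weights to a structure
#'
#' Turns an undirected structural edge set into a structurally symmetric but
#' value-asymmetric coupling matrix: for each edge `{i, j}`, `w[i, j]` and
#' `w[j, i]` are drawn independently from the uniform distribution on
#' `[-1, +1]`. All non-edge off-diagonal entries and the diagonal stay zero.
#'
#' @param structure An [adjacency_structure].
#' @param rng_seed Integer seed.
#' @return An [interaction_matrix].
#' @export
assign_weights <- function(structure, rng_seed) {
  stopifnot(inherits(structure, "adjacency_structure"))
  n <- structure$n_nodes
  e <- structure$edges
  withr::with_seed(as.integer(rng_seed), {
    M <- matrix(0, n, n)
    if (nrow(e) > 0L) {
      M[e] <- stats::runif(nrow(e), -1, 1)
      M[e[, 2:1, drop = FALSE]] <- stats::runif(nrow(e), -1, 1)
    }
  })
  interaction_matrix(M, topology = "weighted_structure",
                     rng_seed = as.integer(rng_seed))
}

#' Apply random negative self-coupling to every node
#'
#' Sets each diagonal entry of the interaction matrix to an independent draw
#' from the uniform distribution on `[interval$lower, interval$upper]`
#' (both strictly negative); off-diagonal entries are untouched.
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @param interval A [coupling_interval].
#' @param rng_seed Integer seed.
#' @return An [interaction_matrix] with strictly negative diagonal.
#' @export
add_self_coupling <- function(matrix, interval, rng_seed) {
  stopifnot(inherits(interval, "coupling_interval"))
  W <- coerce_weights(matrix)
  tag <- if (inherits(matrix, "interaction_matrix")) matrix$topology else "custom"
  withr::with_seed(as.integer(rng_seed), {
    diag(W) <- stats::runif(nrow(W), interval$lower, interval$upper)
  })
  interaction_matrix(W, topology = tag, rng_seed = as.integer(rng_seed))
}

#' Topology configuration for network generation
#'
#' Bundles the generative parameters for one of the four supported
#' topologies. Defaults follow the reference study conditions: small-world
#' with `k_nn = 4` nearest neighbors and 5% rewiring, scale-free with
#' `m = 2`, `m0 = 0`, Kronecker with a dimension-10 seed carrying 82 zeros.
#'
#' @param topology One of `"smallworld"`, `"scalefree"`, `"kronecker"`,
#'   `"erdosrenyi"`.
#' @param n_nodes Network size (for `"kronecker"` derived as
#'   `seed_dim^power` when omitted).
#' @param k_nn,p_rew Small-world parameters.
#' @param m,m0 Preferential-attachment parameters; `m0` may be the string
#'   `"N/2"` to request half the network size.
#' @param seed_dim,seed_zeros,power Kronecker parameters.
#' @param connectance Erdős–Rényi link probability.
#' @return A validated object of class `net_config`.
#' @export
net_config <- function(topology = c("smallworld", "scalefree", "kronecker", "erdosrenyi"),
                       n_nodes = 1000L, k_nn = 4L, p_rew = 0.05,
                       m = 2L, m0 = 0L, seed_dim = 10L, seed_zeros = 82L,
                       power = NULL, connectance = 0.1) {
  topology <- match.arg(topology)
  if (identical(m0, "N/2")) m0 <- as.integer(n_nodes) %/% 2L
  cfg <- structure(list(topology = topology, n_nodes = as.integer(n_nodes),
                        k_nn = as.integer(k_nn), p_rew = p_rew,
                        m = as.integer(m), m0 = as.integer(m0),
                        seed_dim = as.integer(seed_dim),
                        seed_zeros = as.integer(seed_zeros),
                        power = if (is.null(power)) NULL else as.integer(power),
                        connectance = connectance),
                   class = "net_config")
  validate_net_config(cfg)
}

validate_net_config <- function(cfg) {
  switch(cfg$topology,
    smallworld = {
      if (cfg$k_nn %% 2L != 0L || cfg$k_nn < 2L)
        stop_invalid("net_config: k_nn must be even and >= 2")
      if (cfg$n_nodes <= cfg$k_nn)
        stop_invalid("net_config: need n_nodes > k_nn")
      if (cfg$p_rew < 0 || cfg$p_rew > 1)
        stop_invalid("net_config: p_rew must lie in [0, 1]")
    },
    scalefree = {
      if (cfg$m < 1L || cfg$m >= cfg$n_nodes)
        stop_invalid("net_config: need 1 <= m < n_nodes")
      if (cfg$m0 < 0L || cfg$m0 >= cfg$n_nodes)
        stop_invalid("net_config: need 0 <= m0 < n_nodes")
    },
    kronecker = {
      if (is.null(cfg$power)) {
        p <- round(log(cfg$n_nodes) / log(cfg$seed_dim))
        if (cfg$seed_dim^p != cfg$n_nodes)
          stop_invalid("net_config: n_nodes must be a power of seed_dim")
        cfg$power <- as.integer(p)
      }
      cfg$n_nodes <- cfg$seed_dim^cfg$power
    },
    erdosrenyi = {
      if (cfg$connectance < 0 || cfg$connectance > 1)
        stop_invalid("net_config: connectance must lie in [0, 1]")
    })
  cfg
}

#' @export
print.net_config <- function(x, ...) {
  detail <- switch(x$topology,
    smallworld = sprintf("k_nn=%d, p_rew=%g", x$k_nn, x$p_rew),
    scalefree  = sprintf("m=%d, m0=%d", x$m, x$m0),
    kronecker  = sprintf("seed_dim=%d, seed_zeros=%d, power=%d",
                         x$seed_dim, x$seed_zeros, x$power),
    erdosrenyi = sprintf("connectance=%g", x$connectance))
  cat(sprintf("<net_config: %s, N=%d, %s>\n", x$topology, x$n_nodes, detail))
  invisible(x)
}

#' Generate one weighted interaction matrix from a configuration
#'
#' Runs the full generation pipeline for one trial (topology construction
#' plus weight assignment, but no self-coupling): small-world networks are
#' built by ring lattice + exact rewiring + weight assignment, scale-free by
#' preferential attachment + weight assignment; Kronecker and Erdős–Rényi
#' matrices carry their values directly.
#'
#' @param config A [net_config].
#' @param rng_seed Integer seed for this trial.
#' @return An [interaction_matrix] with zero diagonal.
#' @export
generate_network <- function(config, rng_seed) {
  stopifnot(inherits(config, "net_config"))
  rng_seed <- as.integer(rng_seed)
  sub <- derive_seeds(rng_seed, 2L)
  out <- switch(config$topology,
    smallworld = {
      lat <- generate_ring_lattice(config$n_nodes, config$k_nn)
      rw <- rewire(lat, config$p_rew, sub[1L])
      assign_weights(rw, sub[2L])
    },
    scalefree = {
      st <- generate_ba(config$n_nodes, config$m, config$m0, sub[1L])
      assign_weights(st, sub[2L])
    },
    kronecker = generate_kronecker(config$seed_dim, config$seed_zeros,
                                   config$power, sub[1L]),
    erdosrenyi = generate_er(config$n_nodes, config$connectance, sub[1L]))
  out$topology <- config$topology
  out$rng_seed <- rng_seed
  out
}

#' Extract the structural edge set of an interaction matrix
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @return An [adjacency_structure] over the symmetrized nonzero pattern of
#'   the off-diagonal entries.
#' @export
structure_of <- function(matrix) {
  W <- coerce_weights(matrix)
  nz <- (W != 0) | t(W != 0)
  diag(nz) <- FALSE
  idx <- which(nz & upper.tri(nz), arr.ind = TRUE)
  adjacency_structure(nrow(W), idx)
}
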