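#' Structural edge set of an undirected network
#'
#' An `adjacency_structure` holds the pre-weighting topology of a network:
#' the number of nodes and the set of undirected edges, stored as a two-column
#' integer matrix with 1-based node indices and `edges[, 1] < edges[, 2]`.
#' No self-loops and no duplicate edges are allowed.
#'
#' @param n_nodes Positive integer, number of nodes.
#' @param edges Two-column integer matrix of node pairs (1-based). May have
#'   zero rows for an edgeless network.
#' @return An object of class `adjacency_structure`.
#' @export
adjacency_structure <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    # canonical order i < j
    flip <- edges[, 1L] > edges[, 2L]
    if (any(flip)) edges[flip, ] <- edges[flip, 2:1]
    if (any(edges[, 1L] == edges[, 2L]))
      stop_invalid("adjacency_structure: self-pairs are not allowed")
    if (any(edges < 1L) || any(edges > n_nodes))
      stop_invalid("adjacency_structure: node index out of range")
    if (anyDuplicated(edge_keys(edges, n_nodes)))
      stop_invalid("adjacency_structure: duplicate edges are not allowed")
  }
  structure(list(n_nodes = n_nodes, edges = edges),
            class = "adjacency_structure")
}

# unique scalar key per unordered pair, used for duplicate detection
edge_keys <- function(edges, n_nodes) {
  (edges[, 1L] - 1) * as.double(n_nodes) + (edges[, 2L] - 1)
}

#' @export
print.adjacency_structure <- function(x, ...) {
  cat(sprintf("<adjacency_structure: %d nodes, %d undirected edges>\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of an adjacency structure
#' @param structure An `adjacency_structure`.
#' @return Integer edge count.
#' @export
n_edges <- function(structure) {
  stopifnot(inherits(structure, "adjacency_structure"))
  nrow(structure$edges)
}

#' Weighted interaction matrix of a recurrent network
#'
#' An `interaction_matrix` wraps the dense \eqn{N \times N} real coupling
#' matrix interpreted as the Jacobian of a linearized dynamical system:
#' off-diagonal entries are directed coupling weights, diagonal entries are
#' node self-couplings (zero until [add_self_coupling()] is applied).
#'
#' @param weights Square numeric matrix.
#' @param topology Character tag of the generating scheme (e.g. "smallworld").
#' @param rng_seed Integer seed used for generation, or `NA`.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(weights, topology = "custom", rng_seed = NA_integer_) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop_invalid("interaction_matrix: weights must be square")
  if (!all(is.finite(weights)))
    stop_invalid("interaction_matrix: weights must be finite")
  structure(list(n_nodes = nrow(weights), weights = weights,
                 topology = topology, rng_seed = rng_seed),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  nz <- sum(x$weights != 0) - sum(diag(x$weights) != 0)
  cat(sprintf("<interaction_matrix: %d x %d, topology '%s', %d nonzero off-diagonal entries>\n",
              x$n_nodes, x$n_nodes, x$topology, nz))
  invisible(x)
}

#' @export
as.matrix.interaction_matrix <- function(x, ...) x$weights

# Accept either an interaction_matrix or a bare numeric matrix.
coerce_weights <- function(matrix) {
  if (inherits(matrix, "interaction_matrix")) return(matrix$weights)
  m <- as.matrix(matrix)
  if (!is.numeric(m) || nrow(m) != ncol(m))
    stop_invalid("expected a square numeric matrix or an interaction_matrix")
  m
}

#' Interval for drawing node self-coupling strengths
#'
#' Self-couplings are drawn uniformly from a strictly negative interval
#' `[lower, upper]`. Two sweep schemes are supported: `"varied_position"`
#' keeps the interval width fixed at 0.9 while its position shifts
#' (general scheme `[x - 0.9, x]`), and `"fixed_upper"` pins the upper bound
#' at -0.4 while the lower bound moves (`[x, -0.4]`).
#'
#' @param lower,upper Negative reals with `lower < upper < 0`.
#' @param scheme `"varied_position"` or `"fixed_upper"`.
#' @return An object of class `coupling_interval`.
#' @export
coupling_interval <- function(lower, upper,
                              scheme = c("varied_position", "fixed_upper")) {
  scheme <- match.arg(scheme)
  if (!is.finite(lower) || !is.finite(upper) || !(lower < upper) || !(upper < 0))
    stop_invalid("coupling_interval: need lower < upper < 0")
  if (scheme == "varied_position" && abs((upper - lower) - 0.9) > 1e-12)
    stop_invalid("coupling_interval: varied_position requires width exactly 0.9")
  if (scheme == "fixed_upper" && abs(upper - (-0.4)) > 1e-12)
    stop_invalid("coupling_interval: fixed_upper requires upper bound -0.4")
  structure(list(lower = lower, upper = upper, scheme = scheme),
            class = "coupling_interval")
}

#' @rdname coupling_interval
#' @param x Upper bound (varied-position scheme) or lower bound (fixed-upper
#'   scheme) of the interval.
#' @export
varied_interval <- function(x) coupling_interval(x - 0.9, x, "varied_position")

#' @rdname coupling_interval
#' @export
fixed_upper_interval <- function(x) coupling_interval(x, -0.4, "fixed_upper")

#' @export
print.coupling_interval <- function(x, ...) {
  cat(sprintf("<coupling_interval [%g, %g], scheme '%s'>\n",
              x$lower, x$upper, x$scheme))
  invisible(x)
}

# ---- error signalling -------------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("netstab_invalid_parameter", "netstab_error")))
}

stop_generation <- function(msg) {
  stop(errorCondition(msg, class = c("netstab_generation_failure", "netstab_error")))
}

stop_fit <- function(msg, class = "netstab_fit_failure") {
  stop(errorCondition(msg, class = c(class, "netstab_error")))
}

# ---- seed handling ----------------------------------------------------------

#' Derive reproducible sub-seeds from a master seed
#'
#' Expands one master seed into `n` independent 31-bit seeds so that every
#' Monte-Carlo trial (and every sweep point, and every network size) has its
#' own replayable seed. The derivation is a fixed function of
#' `(master_seed, n)`; derived seed `i` can be recovered in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(2147483646L, n, replace = TRUE))
}
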