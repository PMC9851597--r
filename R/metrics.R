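#' Convert an adjacency structure to an igraph graph
#' @param structure An [adjacency_structure].
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(structure) {
  stopifnot(inherits(structure, "adjacency_structure"))
  if (nrow(structure$edges) == 0L)
    return(igraph::make_empty_graph(structure$n_nodes, directed = FALSE))
  igraph::make_graph(as.vector(t(structure$edges)),
                     n = structure$n_nodes, directed = FALSE)
}

#' Watts–Strogatz clustering coefficient
#'
#' Average over all nodes of the local clustering coefficient (fraction of
#' realized links among pairs of neighbors); nodes of degree < 2 contribute 0.
#' For the regular ring lattice with `k_nn` neighbors this equals
#' `3 (k_nn - 2) / (4 (k_nn - 1))`, i.e. exactly 0.5 for `k_nn = 4`.
#'
#' @param structure An [adjacency_structure].
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(structure) {
  g <- as_igraph(structure)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Average shortest-path length
#'
#' Mean geodesic (BFS) distance over all unordered pairs of distinct,
#' mutually reachable nodes. For a disconnected structure the mean is taken
#' over reachable pairs only and a warning flags the disconnection; the
#' returned value carries the attribute `connected`.
#'
#' @param structure An [adjacency_structure].
#' @return Average path length (`>= 1` for any structure with edges), with
#'   logical attribute `connected`.
#' @export
average_shortest_path <- function(structure) {
  g <- as_igraph(structure)
  conn <- igraph::is_connected(g)
  if (!conn)
    warning("average_shortest_path: structure is disconnected; averaging over reachable pairs")
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  structure(L, connected = conn)
}

#' Degree sequence of a structure
#' @param structure An [adjacency_structure].
#' @return Integer vector of node degrees.
#' @export
degrees_of <- function(structure) {
  stopifnot(inherits(structure, "adjacency_structure"))
  tabulate(structure$edges, nbins = structure$n_nodes)
}

#' Trial-averaged degree distribution
#'
#' Normalizes the degree frequencies of each structure separately, then
#' averages the per-trial distributions across trials (so each trial carries
#' equal weight regardless of degree support).
#'
#' @param structures List of [adjacency_structure] objects sharing `n_nodes`.
#' @return A `degree_histogram`: data frame with columns `k` (degree) and
#'   `p` (mean relative frequency), plus attribute `n_trials`.
#' @export
degree_distribution <- function(structures) {
  if (length(structures) == 0L)
    stop_invalid("degree_distribution: need at least one structure")
  n <- unique(vapply(structures, function(s) s$n_nodes, integer(1)))
  if (length(n) != 1L)
    stop_invalid("degree_distribution: all structures must share n_nodes")
  kmax <- max(vapply(structures, function(s) max(c(0L, degrees_of(s))), integer(1)))
  acc <- numeric(kmax + 1L)   # index = degree + 1
  for (s in structures) {
    d <- degrees_of(s)
    f <- tabulate(d + 1L, nbins = kmax + 1L) / length(d)
    acc <- acc + f
  }
  p <- acc / length(structures)
  keep <- p > 0
  out <- data.frame(k = (0:kmax)[keep], p = p[keep])
  class(out) <- c("degree_histogram", "data.frame")
  attr(out, "n_trials") <- length(structures)
  out
}

#' Fit a normalized power law to a degree distribution
#'
#' Fits \eqn{P(k) = (\gamma - 1) k_{min}^{\gamma - 1} k^{-\gamma}} by
#' unweighted nonlinear least squares on the linear scale, using only
#' degrees `k >= fit_floor`. Both the slope `gamma` and the location
#' `k_min` of the presumed distribution maximum are free parameters.
#'
#' @param hist A `degree_histogram` from [degree_distribution()].
#' @param fit_floor Minimum degree included in the fit (default 5).
#' @return A list of class `degree_powerlaw_fit` with elements `gamma`,
#'   `k_min`, `gamma_err`, `k_min_err`, `fit_floor` and the underlying
#'   `nls` fit.
#' @export
fit_degree_powerlaw <- function(hist, fit_floor = 5L) {
  d <- hist[hist$k >= fit_floor, , drop = FALSE]
  if (nrow(d) < 3L)
    stop_fit("fit_degree_powerlaw: need >= 3 degrees at or above fit_floor",
             class = "netstab_fit_unreliable")
  if (length(unique(d$k)) < 2L)
    stop_fit("fit_degree_powerlaw: degenerate histogram")
  # log-linear initialization: log P = log(g-1) + (g-1) log kmin - g log k
  lf <- stats::lm(log(d$p) ~ log(d$k))
  g0 <- max(1.1, -unname(stats::coef(lf)[2L]))
  k0 <- max(1, exp((unname(stats::coef(lf)[1L]) - log(g0 - 1)) / (g0 - 1)))
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ (gamma - 1) * k_min^(gamma - 1) * k^(-gamma),
                      data = d, start = list(gamma = g0, k_min = k0),
                      lower = c(gamma = 1 + 1e-8, k_min = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop_fit(paste0("fit_degree_powerlaw: ", conditionMessage(e))))
  co <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  structure(list(gamma = unname(co["gamma"]), k_min = unname(co["k_min"]),
                 gamma_err = unname(se["gamma"]), k_min_err = unname(se["k_min"]),
                 fit_floor = fit_floor, fit = fit),
            class = "degree_powerlaw_fit")
}

#' @export
print.degree_powerlaw_fit <- function(x, ...) {
  cat(sprintf("<degree power-law fit: gamma = %.4f +/- %.4f, k_min = %.4f (k >= %d)>\n",
              x$gamma, x$gamma_err, x$k_min, x$fit_floor))
  invisible(x)
}

#' Connectance of structured topologies
#'
#' `connectance_sw` gives the connectance of the `k_nn`-regular small-world
#' construction, `k_nn * N / (N^2 - N) = k_nn / (N - 1)`; `connectance_sf`
#' gives the connectance of the preferential-attachment construction,
#' `2 m (N - m0) / (N^2 - N)`. Connectance counts realized directed links
#' over all `N^2 - N` possible off-diagonal links.
#'
#' @param n_nodes Network size.
#' @param k_nn Nearest-neighbor count (small-world).
#' @param m,m0 Preferential-attachment parameters.
#' @return Connectance as a fraction.
#' @export
connectance_sw <- function(n_nodes, k_nn) {
  if (n_nodes < 2L) stop_invalid("connectance_sw: need n_nodes >= 2")
  k_nn / (n_nodes - 1)
}

#' @rdname connectance_sw
#' @export
connectance_sf <- function(n_nodes, m, m0) {
  if (n_nodes < m0 || m0 < 0) stop_invalid("connectance_sf: need n_nodes >= m0 >= 0")
  2 * m * (n_nodes - m0) / (n_nodes^2 - n_nodes)
}

#' Preferential-attachment parameters matching a small-world connectance
#'
#' Solves `0 = (2m - k_nn) N - 2 m0 m` for the two printed solution
#' families: `(m = k_nn / 2, m0 = 0)` and `(m = k_nn, m0 = N / 2)`; both
#' make `connectance_sf` equal `connectance_sw` identically in `N`.
#'
#' @param k_nn Even nearest-neighbor count.
#' @return List of two solutions; each has `m` and `m0` (an integer or the
#'   rule string `"N/2"`).
#' @export
matched_parameters <- function(k_nn) {
  k_nn <- as.integer(k_nn)
  if (k_nn %% 2L != 0L)
    stop_invalid("matched_parameters: no integer solution for odd k_nn")
  list(list(m = k_nn %/% 2L, m0 = 0L),
       list(m = k_nn, m0 = "N/2"))
}

#' Count exactly-zero entries of a matrix
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @param include_diagonal Count diagonal zeros too (full-matrix count) or
#'   off-diagonal only.
#' @return Integer count of zero entries.
#' @export
count_zeros <- function(matrix, include_diagonal = TRUE) {
  W <- coerce_weights(matrix)
  z <- sum(W == 0)
  if (!include_diagonal) z <- z - sum(diag(W) == 0)
  as.integer(z)
}
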