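# Independent oracles used across the test suite. None of these call the
# package's own computational path for the quantity they check.

# Characteristic polynomial coefficients of det(lambda I - M) =
# lambda^n + a1 lambda^(n-1) + ... + an, by the Faddeev-LeVerrier trace
# recursion (matrix products only; no eigensolver involved).
char_poly_coefs <- function(M) {
  n <- nrow(M)
  a <- numeric(n)
  Nk <- diag(n)
  for (k in seq_len(n)) {
    Nk <- M %*% Nk
    a[k] <- -sum(diag(Nk)) / k
    Nk <- Nk + a[k] * diag(n)
  }
  a
}

# Routh-Hurwitz stability conditions for monic polynomials of degree <= 4:
# all roots in the open left half-plane.
routh_hurwitz_stable <- function(a) {
  n <- length(a)
  switch(n,
         a[1] > 0,
         a[1] > 0 && a[2] > 0,
         a[1] > 0 && a[3] > 0 && a[1] * a[2] > a[3],
         a[1] > 0 && a[3] > 0 && a[4] > 0 &&
           a[1] * a[2] * a[3] > a[3]^2 + a[1]^2 * a[4])
}

# All-pairs shortest-path mean over unordered reachable pairs, by plain BFS
# on an adjacency list.
bfs_mean_path <- function(structure) {
  n <- structure$n_nodes
  adj <- vector("list", n)
  for (r in seq_len(nrow(structure$edges))) {
    i <- structure$edges[r, 1]; j <- structure$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  total <- 0; count <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reached <- which(!is.na(dist) & seq_len(n) != s)
    total <- total + sum(dist[reached]); count <- count + length(reached)
  }
  total / count   # ordered pairs; symmetric, equals unordered-pair mean
}

# Random matrix with strictly dominant negative diagonal (Gershgorin
# guarantees stability).
random_dominant_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(runif(n * n, -1, 1), n, n)
    diag(M) <- 0
    diag(M) <- -(rowSums(abs(M)) + runif(n, 0.01, 1))
    M
  })
}

# Canonical string keys of an edge set, for set comparisons.
edge_key <- function(structure) {
  paste(structure$edges[, 1], structure$edges[, 2])
}
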