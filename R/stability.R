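#' Spectral abscissa of an interaction matrix
#'
#' Maximum real part over all eigenvalues of the matrix, computed with the
#' dense nonsymmetric eigensolver (LAPACK QR iteration). The system the
#' matrix linearizes is asymptotically stable iff this value is strictly
#' negative.
#'
#' @param matrix An [interaction_matrix] or square numeric matrix.
#' @return The maximum eigenvalue real part.
#' @export
spectral_abscissa <- function(matrix) {
  W <- coerce_weights(matrix)
  ev <- tryCatch(eigen(W, only.values = TRUE)$values,
                 error = function(e)
                   stop_fit(paste0("spectral_abscissa: eigensolver failed: ",
                                   conditionMessage(e)),
                            class = "netstab_computation_failure"))
  max(Re(ev))
}

#' Asymptotic stability test
#'
#' `TRUE` iff every eigenvalue of the matrix has strictly negative real
#' part. A zero real part counts as unstable; no tolerance is applied, since
#' under continuous weight distributions the boundary has probability zero.
#'
#' @inheritParams spectral_abscissa
#' @return Logical.
#' @examples
#' is_stable(diag(c(-1, -1)))                  # TRUE
#' is_stable(matrix(c(0, -1, 2, -3), 2, 2))    # eigenvalues -1, -2: TRUE
#' @export
is_stable <- function(matrix) {
  spectral_abscissa(matrix) < 0
}

stability_estimate <- function(n_trials, n_stable, n_failed = 0L) {
  p <- n_stable / n_trials
  structure(list(n_trials = n_trials, n_stable = n_stable,
                 probability = p,
                 error_propagated = sqrt(p * (1 - p) / n_trials),
                 error_bound = 1 / sqrt(n_trials),
                 n_failed = n_failed),
            class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf("<stability_estimate: P = %.4f (%d/%d trials), sd = %.4f, bound = %.4f>\n",
              x$probability, x$n_stable, x$n_trials,
              x$error_propagated, x$error_bound))
  invisible(x)
}

#' Monte-Carlo probability of stability
#'
#' Generates `n_trials` independent interaction matrices (fresh topology,
#' weights and self-couplings per trial, each with its own derived seed),
#' classifies each as stable or unstable by the eigenvalue criterion, and
#' returns the fraction of stable trials together with two error measures:
#' the propagated per-trial standard deviation `sqrt(P (1 - P) / T)` and its
#' distribution-free upper bound `1 / sqrt(T)`.
#'
#' Trials whose generation fails are retried with the next derived seed
#' (bounded); trials whose eigensolver fails are discarded and reported via
#' `n_failed` rather than counted as unstable.
#'
#' @param generator_config A [net_config].
#' @param interval A [coupling_interval] for the diagonal self-couplings.
#' @param n_trials Number of Monte-Carlo trials `T`.
#' @param rng_seed Master seed; per-trial seeds are derived from it.
#' @return A `stability_estimate`.
#' @export
probability_of_stability <- function(generator_config, interval, n_trials, rng_seed) {
  stopifnot(inherits(generator_config, "net_config"),
            inherits(interval, "coupling_interval"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop_invalid("probability_of_stability: n_trials must be >= 1")
  # 2 seeds per trial (generation, self-coupling) + spares for bounded retries
  seeds <- derive_seeds(rng_seed, 2L * n_trials + 20L)
  spare <- 2L * n_trials
  n_stable <- 0L; n_failed <- 0L
  for (i in seq_len(n_trials)) {
    M <- tryCatch(generate_network(generator_config, seeds[2L * i - 1L]),
                  netstab_generation_failure = function(e) NULL)
    r <- 0L
    while (is.null(M) && r < 20L) {
      r <- r + 1L
      M <- tryCatch(generate_network(generator_config, seeds[spare + r]),
                    netstab_generation_failure = function(e) NULL)
    }
    if (is.null(M))
      stop_generation("probability_of_stability: repeated generation failures")
    M <- add_self_coupling(M, interval, seeds[2L * i])
    s <- tryCatch(is_stable(M),
                  netstab_computation_failure = function(e) NA)
    if (is.na(s)) n_failed <- n_failed + 1L
    else if (s) n_stable <- n_stable + 1L
  }
  valid <- n_trials - n_failed
  est <- stability_estimate(valid, n_stable, n_failed)
  est
}
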