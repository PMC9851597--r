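#' Stabilization parameter across network sizes
#'
#' Runs the adaptive self-coupling sweep ([sweep_auto()]) for each requested
#' network size, fits the Hill function per size, and records the
#' stabilization parameter (\eqn{\mu} for the varied-position scheme,
#' \eqn{\mu^*} for the fixed-upper scheme) with its propagated error.
#' Generative parameters are held constant across sizes, so connectance
#' varies with `N` as in the reference protocol.
#'
#' @param topology_config A [net_config]; its `n_nodes` field is overridden
#'   per size.
#' @param sizes Strictly increasing integer vector of network sizes.
#' @param scheme `"varied_position"` or `"fixed_upper"`.
#' @param n_trials Monte-Carlo trials per sweep point.
#' @param rng_seed Master seed; each size gets a derived seed.
#' @param ... Passed to [sweep_auto()].
#' @return An object of class `scaling_curve`: list with `sizes`,
#'   `mu_values`, `mu_errors`, `scheme`, `topology`, and the per-size
#'   `hill_fits`. Sizes whose Hill fit fails are dropped with a warning.
#' @export
scaling_curve <- function(topology_config, sizes,
                          scheme = c("varied_position", "fixed_upper"),
                          n_trials, rng_seed, ...) {
  stopifnot(inherits(topology_config, "net_config"))
  scheme <- match.arg(scheme)
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE))
    stop_invalid("scaling_curve: sizes must be strictly increasing")
  seeds <- derive_seeds(rng_seed, length(sizes))
  mu <- mu_err <- rep(NA_real_, length(sizes))
  fits <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    cfg <- topology_config
    cfg$n_nodes <- sizes[i]
    cfg <- validate_net_config(cfg)
    fit <- tryCatch({
      cv <- sweep_auto(cfg, scheme, n_trials, seeds[i], ...)
      fit_hill(cv)
    }, netstab_error = function(e) {
      warning(sprintf("scaling_curve: size %d excluded (%s)",
                      sizes[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) {
      mu[i] <- fit$mu
      mu_err[i] <- fit$mu_err
      fits[[i]] <- fit
    }
  }
  keep <- !is.na(mu)
  structure(list(sizes = sizes[keep], mu_values = mu[keep],
                 mu_errors = mu_err[keep], scheme = scheme,
                 topology = topology_config$topology,
                 hill_fits = fits[keep]),
            class = "scaling_curve")
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat(sprintf("<scaling_curve (%s, %s): %d sizes %d..%d>\n",
              x$topology, x$scheme, length(x$sizes),
              min(x$sizes), max(x$sizes)))
  print(data.frame(N = x$sizes, mu = x$mu_values, mu_err = x$mu_errors))
  invisible(x)
}

#' Power-law fit of the stabilization parameter over network size
#'
#' Nonlinear least squares of \eqn{\mu(N) = A (N - 1)^p} to a scaling
#' curve. The form pins \eqn{\mu(1) = 0}: a single node needs no coupling
#' balance, only any negative self-coupling. Asymptotic standard errors use
#' the residual-variance-scaled covariance (gnuplot convention). The fit is
#' unweighted by default; set `weighted = TRUE` to weight by the inverse
#' squared propagated errors.
#'
#' @param curve A `scaling_curve` with at least 3 sizes, or a list/data
#'   frame with `sizes` and `mu_values` (optionally `mu_errors`).
#' @param weighted Use `1 / mu_errors^2` weights (default `FALSE`).
#' @return An object of class `power_law_fit` with `A`, `p`, `A_err`,
#'   `p_err` and the underlying `nls` fit.
#' @export
fit_power_law <- function(curve, weighted = FALSE) {
  sizes <- curve$sizes
  mu <- curve$mu_values
  if (length(sizes) < 3L)
    stop_fit("fit_power_law: need at least 3 sizes",
             class = "netstab_fit_unreliable")
  x <- sizes - 1
  lf <- stats::lm(log(mu) ~ log(x))
  start <- c(A = exp(unname(stats::coef(lf)[1L])),
             p = unname(stats::coef(lf)[2L]))
  sw <- if (weighted) 1 / curve$mu_errors else rep(1, length(mu))
  resid_fn <- function(par) sw * (mu - par[1L] * x^par[2L])
  jac_fn <- function(par)
    -sw * cbind(x^par[2L], par[1L] * x^par[2L] * log(x))
  opt <- minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                            lower = c(A = 1e-12, p = -10),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  if (opt$info %in% c(0, 5, 9))
    stop_fit(paste0("fit_power_law: ", opt$message))
  co <- opt$par
  # asymptotic standard errors: covariance scaled by the reduced chi-square
  dof <- length(mu) - 2L
  s2 <- sum(opt$fvec^2) / dof
  J <- jac_fn(co)
  V <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(A = unname(co["A"]), p = unname(co["p"]),
                 A_err = sqrt(V[1L, 1L]), p_err = sqrt(V[2L, 2L]),
                 fit = opt),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit: mu(N) = A (N-1)^p, A = %.4f +/- %.4f, p = %.4f +/- %.4f>\n",
              x$A, x$A_err, x$p, x$p_err))
  invisible(x)
}

#' Replicate the topology-by-scheme scaling table
#'
#' Runs the size-scan experiment for every combination of topology
#' (small-world with `k_nn = 4`, `p_rew = 0.05`; scale-free with `m = 2`,
#' `m0 = 0`) and interval scheme (varied position; fixed upper bound),
#' fitting \eqn{\mu(N) = A (N - 1)^p} for each cell.
#'
#' @param sizes Network sizes (default fast-mode grid 100..500; the full
#'   reference protocol used sizes up to 1500 with 1000 trials per point).
#' @param n_trials Trials per sweep point (default 100).
#' @param rng_seed Master seed.
#' @param topologies Topologies to include.
#' @param ... Passed to [scaling_curve()].
#' @return Data frame with one row per scheme-topology cell: columns
#'   `scheme`, `topology`, `A`, `A_err`, `p`, `p_err`; the underlying
#'   `scaling_curve` objects are attached as attribute `"curves"`.
#' @export
replicate_table2 <- function(sizes = c(100L, 200L, 300L, 400L, 500L),
                             n_trials = 100L, rng_seed = 1L,
                             topologies = c("smallworld", "scalefree"), ...) {
  cells <- expand.grid(scheme = c("varied_position", "fixed_upper"),
                       topology = topologies,
                       stringsAsFactors = FALSE)
  seeds <- derive_seeds(rng_seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  curves <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- net_config(cells$topology[i], n_nodes = max(sizes))
    cv <- scaling_curve(cfg, sizes, cells$scheme[i], n_trials, seeds[i], ...)
    pl <- fit_power_law(cv)
    rows[[i]] <- data.frame(scheme = cells$scheme[i],
                            topology = cells$topology[i],
                            A = pl$A, A_err = pl$A_err,
                            p = pl$p, p_err = pl$p_err)
    curves[[i]] <- cv
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
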