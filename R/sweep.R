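#' Hill function for the stability transition
#'
#' \eqn{P(stable | x) = |x|^n / (c + |x|^n)}: the sigmoid used to model the
#' probability of stability as a function of the (absolute) self-coupling
#' abscissa.
#'
#' @param x Abscissa (signed or absolute; only `|x|` enters).
#' @param c Half-saturation parameter (`c > 0`).
#' @param n Steepness exponent (`n > 0`).
#' @return Probability in `[0, 1]`.
#' @export
hill_function <- function(x, c, n) {
  a <- abs(x)^n
  a / (c + a)
}

#' Stabilization parameter from Hill fit parameters
#'
#' The absolute abscissa at which the fitted Hill curve crosses probability
#' 0.5: \eqn{\mu = c^{1/n}}.
#'
#' @param c,n Positive Hill parameters.
#' @return `c^(1/n)`.
#' @export
stabilization_parameter <- function(c, n) {
  if (!is.finite(c) || !is.finite(n) || c <= 0 || n <= 0)
    stop_invalid("stabilization_parameter: c and n must be positive")
  c^(1 / n)
}

#' Stability curve container
#'
#' Pairs a monotone abscissa (mean self-coupling strength for the
#' varied-position scheme, interval lower bound for the fixed-upper scheme)
#' with per-point probability-of-stability estimates. `estimates` may be a
#' list of estimates produced by [probability_of_stability()] or, for
#' externally supplied data, a bare numeric vector of probabilities
#' (optionally with `n_trials` to reconstruct the binomial error measures).
#'
#' @param abscissa Strictly monotone numeric vector.
#' @param estimates List of `stability_estimate` objects, or numeric
#'   probabilities in `[0, 1]`.
#' @param scheme `"varied_position"` or `"fixed_upper"`.
#' @param config Optional [net_config] echoed into the curve.
#' @param n_trials Trial count used when `estimates` is numeric.
#' @return An object of class `stability_curve`.
#' @export
stability_curve <- function(abscissa, estimates, scheme, config = NULL,
                            n_trials = NA_integer_) {
  if (is.numeric(estimates)) {
    if (any(estimates < 0 | estimates > 1))
      stop_invalid("stability_curve: probabilities must lie in [0, 1]")
    estimates <- lapply(estimates, function(p)
      structure(list(n_trials = n_trials,
                     n_stable = if (is.na(n_trials)) NA_integer_
                                else as.integer(round(p * n_trials)),
                     probability = p,
                     error_propagated = sqrt(p * (1 - p) / n_trials),
                     error_bound = 1 / sqrt(n_trials), n_failed = 0L),
                class = "stability_estimate"))
  }
  if (length(abscissa) != length(estimates))
    stop_invalid("stability_curve: abscissa and estimates must have equal length")
  d <- diff(abscissa)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop_invalid("stability_curve: abscissa must be strictly monotone")
  structure(list(abscissa = abscissa, estimates = estimates,
                 scheme = scheme, config = config),
            class = "stability_curve")
}

#' Probabilities of a stability curve
#' @param curve A `stability_curve`.
#' @return Numeric vector of per-point probabilities of stability.
#' @export
curve_probabilities <- function(curve) {
  vapply(curve$estimates, function(e) e$probability, numeric(1))
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve (%s): %d points, abscissa [%g, %g]>\n",
              x$scheme, length(x$abscissa), min(x$abscissa), max(x$abscissa)))
  invisible(x)
}

#' @export
as.data.frame.stability_curve <- function(x, ...) {
  data.frame(abscissa = x$abscissa,
             probability = curve_probabilities(x),
             n_trials = vapply(x$estimates, function(e) e$n_trials, numeric(1)),
             n_stable = vapply(x$estimates, function(e) e$n_stable, numeric(1)),
             error_propagated = vapply(x$estimates, function(e) e$error_propagated, numeric(1)),
             error_bound = vapply(x$estimates, function(e) e$error_bound, numeric(1)))
}

#' Self-coupling sweep with intervals of varied position
#'
#' For each upper bound `x` in `positions`, draws self-couplings from the
#' width-0.9 interval `[x - 0.9, x]` and estimates the probability of
#' stability. The curve abscissa is the interval mean `x - 0.45`.
#'
#' @param generator_config A [net_config].
#' @param positions Strictly monotone vector of negative upper bounds `x`.
#' @param n_trials Monte-Carlo trials per point.
#' @param rng_seed Master seed; each point gets a derived seed.
#' @return A `stability_curve` (scheme `"varied_position"`).
#' @export
sweep_varied_position <- function(generator_config, positions, n_trials, rng_seed) {
  if (any(positions >= 0))
    stop_invalid("sweep_varied_position: positions must be negative")
  seeds <- derive_seeds(rng_seed, length(positions))
  est <- lapply(seq_along(positions), function(i)
    probability_of_stability(generator_config, varied_interval(positions[i]),
                             n_trials, seeds[i]))
  stability_curve(positions - 0.45, est, "varied_position", generator_config)
}

#' Self-coupling sweep with fixed upper bound
#'
#' For each lower bound `x` in `lower_bounds`, draws self-couplings from
#' `[x, -0.4]` and estimates the probability of stability. The curve
#' abscissa is the lower bound `x` itself.
#'
#' @param generator_config A [net_config].
#' @param lower_bounds Strictly monotone vector of bounds `< -0.4`.
#' @inheritParams sweep_varied_position
#' @return A `stability_curve` (scheme `"fixed_upper"`).
#' @export
sweep_fixed_upper <- function(generator_config, lower_bounds, n_trials, rng_seed) {
  if (any(lower_bounds >= -0.4))
    stop_invalid("sweep_fixed_upper: lower bounds must be < -0.4")
  seeds <- derive_seeds(rng_seed, length(lower_bounds))
  est <- lapply(seq_along(lower_bounds), function(i)
    probability_of_stability(generator_config, fixed_upper_interval(lower_bounds[i]),
                             n_trials, seeds[i]))
  stability_curve(lower_bounds, est, "fixed_upper", generator_config)
}

# map an absolute abscissa t > 0 to the sweep's interval position argument
abscissa_to_position <- function(t, scheme) {
  if (scheme == "varied_position") 0.45 - t else -t
}

# smallest admissible |abscissa| per scheme (interval must stay negative /
# strictly below the fixed upper bound)
min_abscissa <- function(scheme) {
  if (scheme == "varied_position") 0.46 else 0.41
}

#' Adaptive sweep across the stability transition
#'
#' Two-phase protocol used by the scaling experiments. Phase 1 brackets the
#' transition cheaply: a geometric search (factor 2) over the absolute
#' abscissa with a small trial count finds bounds with probability below and
#' above 0.5, refined by four bisection steps. Phase 2 places a relative
#' grid across the transition and estimates each point with the full trial
#' count: a linear grid of `n_points` within `1 +/- half_width` of the
#' crossing for the steep varied-position scheme, and a geometric grid
#' (at least 9 points, spanning roughly `0.45x` to `2.5x` the crossing at
#' the default `half_width`) for the shallow fixed-upper scheme. The grid
#' is extended outward (up to three times) if the measured curve does not
#' cross 0.5 on both sides. Only phase-2 points enter the returned curve.
#'
#' @param generator_config A [net_config].
#' @param scheme `"varied_position"` or `"fixed_upper"`.
#' @param n_trials Trials per refined point.
#' @param rng_seed Master seed.
#' @param n_points Refined grid size (default 7).
#' @param bracket_trials Trials per bracketing evaluation (default 16).
#' @param half_width Relative half-width of the refined grid around the
#'   bracketed crossing; defaults to 0.25 (varied position) or 0.55 (fixed
#'   upper, whose transition is broader and uses a geometric grid).
#' @return A `stability_curve`.
#' @export
sweep_auto <- function(generator_config,
                       scheme = c("varied_position", "fixed_upper"),
                       n_trials, rng_seed, n_points = 7L,
                       bracket_trials = 16L, half_width = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(half_width))
    half_width <- if (scheme == "varied_position") 0.25 else 0.55
  seeds <- derive_seeds(rng_seed, 200L)
  used <- 0L
  est_at <- function(t, trials) {
    used <<- used + 1L
    if (used > 200L) stop_generation("sweep_auto: seed pool exhausted")
    iv <- if (scheme == "varied_position")
      varied_interval(abscissa_to_position(t, scheme))
    else fixed_upper_interval(abscissa_to_position(t, scheme))
    probability_of_stability(generator_config, iv, trials, seeds[used])
  }
  p_at <- function(t, trials) est_at(t, trials)$probability
  t_min <- min_abscissa(scheme)
  # phase 1: geometric bracket of the 0.5 crossing
  t <- max(t_min, if (scheme == "varied_position") 0.55 else 0.8)
  p <- p_at(t, bracket_trials)
  if (p < 0.5) {
    t_lo <- t
    repeat {
      t <- t * 2
      p <- p_at(t, bracket_trials)
      if (p >= 0.5) { t_hi <- t; break }
      t_lo <- t
      if (t > 1e4) stop_generation("sweep_auto: no stable regime found")
    }
  } else {
    t_hi <- t
    repeat {
      t <- max(t_min, t / 2)
      p <- p_at(t, bracket_trials)
      if (p < 0.5 || t <= t_min) { t_lo <- t; break }
      t_hi <- t
    }
  }
  for (i in 1:4) {   # bisection in log abscissa
    t_mid <- sqrt(t_lo * t_hi)
    if (p_at(t_mid, bracket_trials) >= 0.5) t_hi <- t_mid else t_lo <- t_mid
  }
  t_c <- sqrt(t_lo * t_hi)
  # phase 2: refined grid at full trial count. The varied-position
  # transition is steep (Hill n ~ 13 and rising with N), so a linear grid
  # within +/- 25% of the crossing reaches both tails; the fixed-upper
  # transition is shallow (n ~ 3-4), so covering P ~ 0.05..0.95 needs a
  # geometric grid spanning roughly a factor 4 around the crossing.
  grid <- if (scheme == "varied_position")
    t_c * seq(1 - half_width, 1 + half_width, length.out = n_points)
  else
    t_c * exp(seq(log(1 - half_width), log((1 - half_width)^-1.15),
                  length.out = max(n_points, 9L)))
  grid <- sort(unique(pmax(t_min, grid)))
  ests <- lapply(grid, est_at, trials = n_trials)
  probs <- vapply(ests, function(e) e$probability, numeric(1))
  for (rep in 1:3) {   # extend outward if the transition is not yet covered
    if (min(probs) > 0.35) {
      t_new <- max(t_min, min(grid) * (1 - half_width))
      if (t_new >= min(grid)) break
      e_new <- est_at(t_new, n_trials)
      grid <- c(t_new, grid); ests <- c(list(e_new), ests)
      probs <- c(e_new$probability, probs)
    } else if (max(probs) < 0.65) {
      t_new <- max(grid) * (1 + half_width)
      e_new <- est_at(t_new, n_trials)
      grid <- c(grid, t_new); ests <- c(ests, list(e_new))
      probs <- c(probs, e_new$probability)
    } else break
  }
  # abscissae are negative; increasing t means decreasing abscissa
  stability_curve(if (scheme == "varied_position") -grid else -grid,
                  ests, scheme, generator_config)
}

#' Fit the Hill function to a stability curve
#'
#' Unweighted nonlinear least squares of
#' \eqn{P = |x|^n / (c + |x|^n)} against the curve's absolute abscissa.
#' Initial values come from a linear regression of `logit(P)` on `log |x|`
#' over the interior points (for the Hill function this relation is exactly
#' linear with slope `n`). Asymptotic standard errors use the
#' residual-variance-scaled covariance (the gnuplot convention), and the
#' stabilization parameter `mu = c^(1/n)` carries a first-order error
#' propagated through the full `(c, n)` covariance.
#'
#' @param curve A `stability_curve` whose probabilities span both sides
#'   of 0.5.
#' @return An object of class `hill_fit` with elements `c`, `n`, `c_err`,
#'   `n_err`, `covariance_cn`, `mu`, `mu_err`, `scheme` and the underlying
#'   `nls` fit.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "stability_curve"))
  a <- abs(curve$abscissa)
  P <- curve_probabilities(curve)
  if (!(any(P < 0.5) && any(P > 0.5)))
    stop_fit("fit_hill: curve does not cross P = 0.5; fit would be unreliable",
             class = "netstab_fit_unreliable")
  interior <- P > 0.01 & P < 0.99
  if (sum(interior) >= 2L) {
    lf <- stats::lm(I(log(P[interior] / (1 - P[interior]))) ~ log(a[interior]))
    n0 <- max(0.5, unname(stats::coef(lf)[2L]))
    c0 <- exp(-unname(stats::coef(lf)[1L]))
  } else {
    # degenerate step-like data: locate the crossing by interpolation
    i <- max(which(P < 0.5)); j <- min(which(P > 0.5))
    t_c <- sqrt(a[i] * a[j])
    n0 <- 20
    c0 <- t_c^n0
  }
  d <- data.frame(a = a, P = P)
  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ a^n / (c + a^n), data = d,
                      start = list(c = c0, n = n0),
                      lower = c(c = 1e-12, n = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 1000,
                                                           ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop_fit(paste0("fit_hill: ", conditionMessage(e))))
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  cc <- unname(co["c"]); nn <- unname(co["n"])
  mu <- stabilization_parameter(cc, nn)
  g <- c(mu / (nn * cc), -mu * log(cc) / nn^2)   # d mu / d(c, n)
  mu_var <- drop(t(g) %*% V %*% g)
  structure(list(c = cc, n = nn,
                 c_err = sqrt(V[1L, 1L]), n_err = sqrt(V[2L, 2L]),
                 covariance_cn = V[1L, 2L],
                 mu = mu, mu_err = sqrt(max(0, mu_var)),
                 scheme = curve$scheme, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit (%s): c = %.4g +/- %.2g, n = %.4g +/- %.2g, mu = %.4f +/- %.4f>\n",
              x$scheme, x$c, x$c_err, x$n, x$n_err, x$mu, x$mu_err))
  invisible(x)
}

#' Width of the fitted stability transition
#'
#' Distance in absolute abscissa between the fitted Hill curve's crossings
#' of `p_lo` and `p_hi` (defaults 0.1 and 0.9); a measure of how abrupt the
#' transition to stability is.
#'
#' @param fit A `hill_fit`.
#' @param p_lo,p_hi Probability levels bounding the transition.
#' @return Abscissa width `|x|(p_hi) - |x|(p_lo)`.
#' @export
transition_width <- function(fit, p_lo = 0.1, p_hi = 0.9) {
  stopifnot(inherits(fit, "hill_fit"))
  inv <- function(p) fit$mu * (p / (1 - p))^(1 / fit$n)
  inv(p_hi) - inv(p_lo)
}
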