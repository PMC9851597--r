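test_that("stabilization parameter inverts the Hill function at half saturation", {
  expect_equal(stabilization_parameter(1, 5), 1)
  expect_equal(stabilization_parameter(4, 8), 1.18920712, tolerance = 1e-8)
  expect_equal(hill_function(-stabilization_parameter(4, 8), 4, 8), 0.5,
               tolerance = 1e-12)
  expect_error(stabilization_parameter(-1, 2), class = "netstab_invalid_parameter")
  expect_error(stabilization_parameter(2, 0), class = "netstab_invalid_parameter")
})

test_that("Hill fit recovers exact parameters from noiseless data", {
  x <- -seq(0.6, 2.4, by = 0.2)
  curve <- stability_curve(x, hill_function(x, c = 4, n = 8), "varied_position")
  fit <- fit_hill(curve)
  expect_equal(fit$c, 4, tolerance = 1e-6)
  expect_equal(fit$n, 8, tolerance = 1e-6)
  expect_equal(fit$mu, 4^(1 / 8), tolerance = 1e-6)
  # inverse-consistency: the fitted curve crosses 0.5 exactly at -mu
  expect_equal(hill_function(-fit$mu, fit$c, fit$n), 0.5, tolerance = 1e-12)
})

test_that("Hill fit refuses curves that never cross one half", {
  x <- -seq(2, 3, by = 0.25)
  curve <- stability_curve(x, rep(1, length(x)), "varied_position")
  expect_error(fit_hill(curve), class = "netstab_fit_unreliable")
})

test_that("mu is recovered within three propagated errors under binomial noise", {
  mu_true <- stabilization_parameter(4, 8)
  x <- -mu_true * seq(0.7, 1.3, length.out = 9)
  p_true <- hill_function(x, 4, 8)
  seeds <- derive_seeds(2024, 200)
  hits <- logical(200)
  for (r in 1:200) {
    P <- withr::with_seed(seeds[r], stats::rbinom(9, 1000, p_true) / 1000)
    fit <- fit_hill(stability_curve(x, P, "varied_position", n_trials = 1000L))
    hits[r] <- abs(fit$mu - mu_true) <= 3 * fit$mu_err
  }
  expect_gte(mean(hits), 0.95)
})

test_that("sweep contracts hold on degenerate generators", {
  # single-node system: stable for every negative interval
  solo <- net_config("erdosrenyi", n_nodes = 1, connectance = 0)
  cv <- sweep_varied_position(solo, c(-0.1, -0.6, -1.1), 20, 1)
  expect_equal(curve_probabilities(cv), c(1, 1, 1))
  expect_equal(cv$abscissa, c(-0.1, -0.6, -1.1) - 0.45)

  # all-diagonal generator under the fixed-upper scheme
  diag_only <- net_config("erdosrenyi", n_nodes = 10, connectance = 0)
  cv2 <- sweep_fixed_upper(diag_only, c(-0.5, -1, -2), 20, 2)
  expect_equal(curve_probabilities(cv2), c(1, 1, 1))
  expect_equal(cv2$abscissa, c(-0.5, -1, -2))

  expect_error(sweep_fixed_upper(diag_only, c(-0.4), 10, 1),
               class = "netstab_invalid_parameter")   # interval degenerates
  expect_error(sweep_varied_position(diag_only, c(0.2), 10, 1),
               class = "netstab_invalid_parameter")
  expect_error(stability_curve(c(-1, -1.5, -1.2), c(0, 0.5, 1), "varied_position"),
               class = "netstab_invalid_parameter")   # non-monotone abscissa
})

test_that("the reference first interval is reproduced by the sweep grid", {
  cfg <- net_config("erdosrenyi", n_nodes = 5, connectance = 0)
  cv <- sweep_varied_position(cfg, -0.1, 10, 3)
  expect_equal(cv$abscissa, -0.55)         # mean of [-1.0, -0.1]
  iv <- varied_interval(-0.1)
  expect_equal(c(iv$lower, iv$upper), c(-1.0, -0.1))
})

test_that("transition width follows the fitted Hill steepness", {
  fit <- structure(list(mu = 2, n = 10), class = "hill_fit")
  expect_equal(transition_width(fit), 2 * (9^(1 / 10) - 9^(-1 / 10)),
               tolerance = 1e-12)
})
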