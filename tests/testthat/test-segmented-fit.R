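test_that("a noiseless knot is recovered exactly by SSE selection", {
  x <- seq(0, 100)
  y <- pmin(x, 50)                       # slope 1 below 50, flat above
  fit <- fit_segmented(x, y)
  expect_true(fit$estimable)
  expect_equal(fit$psi, 50, tolerance = 1e-6)
  expect_equal(fit$beta1, 1, tolerance = 1e-6)
  expect_equal(fit$beta2, -1, tolerance = 1e-6)
  expect_equal(fit$beta0, 0, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  # at the knot itself the slope-change estimate is the true -1; the
  # max-|beta2| rule is dominated by inflated edge candidates and is
  # therefore only checked against its own brute-force oracle elsewhere
  expect_equal(fit$profile$beta2[fit$profile$psi == 50], -1,
               tolerance = 1e-6)
})

test_that("the fitted broken line is continuous and matches hand evaluation", {
  fit <- structure(list(beta0 = 0, beta1 = 1, beta2 = -1, psi = 50,
                        estimable = TRUE),
                   class = "segmented_fit")
  expect_equal(predict_segmented(fit, 70), 50)        # hand-evaluated
  expect_equal(predict_segmented(fit, 30), 30)        # below: slope-1 line
  # both branches agree at the knot
  eps <- 1e-9
  expect_equal(predict_segmented(fit, 50 - eps),
               predict_segmented(fit, 50 + eps), tolerance = 1e-6)
  # vectorized evaluation, slope change only above psi
  z <- c(0, 25, 50, 75, 100)
  expect_equal(predict_segmented(fit, z), c(0, 25, 50, 50, 50))
})

test_that("straight-line data yields no slope change", {
  x <- seq(0, 100)
  fit <- fit_segmented(x, 2 * x + 3)
  expect_equal(fit$beta2, 0, tolerance = 1e-8)
  expect_equal(fit$beta1, 2, tolerance = 1e-8)

  # noisy straight lines: the slope-change test should usually not reject
  seeds <- 1:10
  p <- vapply(seeds, function(s) {
    set.seed(s)
    xs <- rnorm(400, 100, 15)
    fit_segmented(xs, 2 * xs + 3 + rnorm(400, 0, 10))$p_beta2
  }, numeric(1))
  expect_gte(sum(p > 0.05), 5)
})

test_that("selection matches the brute-force profile oracle", {
  datasets <- list(
    make_piecewise(n = 200, seed = 1),
    make_piecewise(n = 200, knot_q = 0.4, beta2 = 2, noise_sd = 5,
                   seed = 2),
    make_observed_pair(n = 250, rho = 0.1, seed = 3),
    { set.seed(4); list(x = rnorm(150, 100, 15),
                        y = rnorm(150, 100, 15)) }   # pure noise
  )
  for (d in datasets) {
    fit <- fit_segmented(d$x, d$y)
    oracle <- brute_force_profile(d$x, d$y)
    expect_equal(fit$profile$psi, oracle$psi)
    expect_equal(fit$profile$sse, oracle$sse, tolerance = 1e-8)
    expect_equal(fit$psi, oracle$psi[which.min(oracle$sse)])
    # max-|beta2| selection agrees with its own oracle too
    fit2 <- fit_segmented(d$x, d$y, selection = "beta2")
    expect_equal(fit2$psi, oracle$psi[which.max(abs(oracle$beta2))])
  }
})

test_that("the segmented fit never does worse than a single line", {
  for (s in 1:5) {
    d <- make_observed_pair(n = 200, rho = runif(1), seed = s)
    fit <- fit_segmented(d$x, d$y)
    expect_lte(fit$sse, fit$sse_ols + 1e-8)
    expect_gte(fit$p_beta2, 0)
    expect_lte(fit$p_beta2, 1)
    # psi strictly inside the candidate range
    expect_gte(fit$psi, quantile(d$x, 0.1))
    expect_lte(fit$psi, quantile(d$x, 0.9))
  }
})

test_that("the fit is equivariant under affine rescaling of the predictor", {
  d <- make_piecewise(n = 300, seed = 9)
  fit <- fit_segmented(d$x, d$y)
  a <- -7; b <- 2.5
  fit2 <- fit_segmented(a + b * d$x, d$y)
  expect_equal(fit2$psi, a + b * fit$psi, tolerance = 1e-8)
  expect_equal(fit2$p_beta2, fit$p_beta2, tolerance = 1e-10)
  expect_equal(fit2$sse, fit$sse, tolerance = 1e-6)
  expect_equal(fit2$psi_ci, a + b * fit$psi_ci, tolerance = 1e-8)
})

test_that("degenerate inputs give a 'no breakpoint estimable' result", {
  # too few observations for two segments of five
  fit <- fit_segmented(1:8, rnorm(8))
  expect_false(fit$estimable)
  expect_true(is.na(fit$psi))
  # a constant predictor admits no candidate
  fit2 <- fit_segmented(rep(3, 50), rnorm(50))
  expect_false(fit2$estimable)
  expect_error(predict_segmented(fit2, 1), "estimable")
  expect_error(fit_segmented(1:10, 1:9), "equal length")
})
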