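test_that("configuration rejects invalid generative settings", {
  expect_error(simulation_config(n = 3), "n")
  expect_error(simulation_config(n = 100, rho = 1.2), "rho")
  expect_error(simulation_config(n = 100, rho = -0.1), "rho")
  expect_error(simulation_config(n = 100, rho = "weird"), "rho")
  expect_error(simulation_config(n = 100, true_sd = 0), "true_sd")
  expect_error(simulation_config(n = 100, beta_alpha = 0), "positive")
  expect_error(simulation_config(n = 100, beta_beta = -1), "positive")
  expect_error(simulation_config(n = 100, alpha_level = 1), "alpha_level")
  expect_error(draw_true_scores(100, 100, 15, 1.5), "rho")
  expect_error(draw_true_scores(100, 100, -2, 0.5), "sd")
})

test_that("true scores have the stated marginals and correlation", {
  set.seed(101)
  s <- draw_true_scores(6400, 100, 15, 0.5)
  expect_lt(abs(mean(s$iq) - 100), 1)
  expect_lt(abs(mean(s$creativity) - 100), 1)
  expect_lt(abs(sd(s$iq) - 15), 1)
  expect_lt(abs(sd(s$creativity) - 15), 1)

  # perfect correlation collapses the pair onto one vector
  set.seed(102)
  s1 <- draw_true_scores(500, 100, 15, 1)
  expect_equal(s1$iq, s1$creativity, tolerance = 1e-12)
  expect_equal(cor(s1$iq, s1$creativity), 1, tolerance = 1e-12)

  # independence: sample r within the CLT band around zero
  set.seed(103)
  s0 <- draw_true_scores(1e5, 100, 15, 0)
  expect_lt(abs(cor(s0$iq, s0$creativity)), 3 / sqrt(1e5))

  # intermediate rho recovered within Monte-Carlo tolerance
  set.seed(104)
  for (rho in c(0.2, 0.5, 0.8)) {
    s <- draw_true_scores(5e4, 100, 15, rho)
    expect_lt(abs(cor(s$iq, s$creativity) - rho), 0.02)
  }
})

test_that("disturbance is beta-distributed on [0, 1] with the stated shapes", {
  set.seed(201)
  d <- draw_disturbance(1e5, 9, 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_lt(abs(mean(d) - 0.9), 0.01)       # beta mean alpha/(alpha+beta)
  expect_lt(sample_skewness(d), -1)         # negatively skewed shape

  set.seed(202)
  dsym <- draw_disturbance(1e5, 9, 9)
  expect_lt(abs(sample_skewness(dsym)), 0.05) # approximately symmetric
  expect_lt(abs(mean(dsym) - 0.5), 0.01)

  set.seed(203)
  dpos <- draw_disturbance(1e5, 1, 9)
  expect_gt(sample_skewness(dpos), 1)       # positively skewed shape

  expect_error(draw_disturbance(10, 0, 1), "positive")
})

test_that("disturbance multiplies true scores elementwise", {
  expect_equal(apply_disturbance(c(150, 80), c(0.5, 1.0)), c(75, 80))
  x <- rnorm(50, 100, 15)
  expect_identical(apply_disturbance(x, rep(1, 50)), x)
  expect_identical(apply_disturbance(x, rep(0, 50)), rep(0, 50))
  expect_error(apply_disturbance(1:3, 1:2), "equal length")
})

test_that("generated cohorts satisfy the type invariants", {
  cfg <- simulation_config(n = 500, rho = 0.3, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 500)
  expect_true(all(cohort$disturbance >= 0 & cohort$disturbance <= 1))
  expect_equal(cohort$observed_iq,
               cohort$true_iq * cohort$disturbance, tolerance = 1e-14)
  expect_equal(cohort$observed_creativity,
               cohort$true_creativity * cohort$disturbance,
               tolerance = 1e-14)
  expect_equal(attr(cohort, "rho_population"), 0.3)

  # attenuation direction when all true scores are positive
  if (all(cohort$true_iq > 0))
    expect_lte(mean(cohort$observed_iq), mean(cohort$true_iq))

  # seeded reproducibility
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  # "uniform" rho is resolved per cohort and recorded
  cfg_u <- simulation_config(n = 100, rho = "uniform", seed = 12)
  rho_used <- attr(generate_cohort(cfg_u), "rho_population")
  expect_true(rho_used >= 0 && rho_used <= 1)
})

test_that("disabling disturbance makes observed scores identical to true", {
  cfg <- simulation_config(n = 400, rho = 0.4, disturbance_enabled = FALSE,
                           seed = 21)
  cohort <- generate_cohort(cfg)
  expect_identical(cohort$observed_iq, cohort$true_iq)
  expect_identical(cohort$observed_creativity, cohort$true_creativity)
  expect_true(all(cohort$disturbance == 1))
  # conservation: downstream statistics agree between observed and true
  expect_identical(cor(cohort$observed_iq, cohort$observed_creativity),
                   cor(cohort$true_iq, cohort$true_creativity))
})

test_that("cohorts round-trip through CSV, with column remapping", {
  cohort <- generate_cohort(simulation_config(n = 50, rho = 0.2, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort, tolerance = 1e-12, ignore_attr = TRUE)

  # external headers mapped onto the canonical schema
  ext <- as.data.frame(cohort)
  names(ext) <- c("IQ.true", "Crea.true", "dist", "IQ.obs", "Crea.obs")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ext, path2, row.names = FALSE)
  back2 <- read_cohort(path2, col_map = c(
    IQ.true = "true_iq", Crea.true = "true_creativity",
    dist = "disturbance", IQ.obs = "observed_iq",
    Crea.obs = "observed_creativity"))
  expect_equal(back2, cohort, tolerance = 1e-12, ignore_attr = TRUE)

  # missing disturbance column is reconstructed from the score ratio
  ext3 <- as.data.frame(cohort)[, -3]
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ext3, path3, row.names = FALSE)
  back3 <- read_cohort(path3)
  expect_equal(back3$disturbance, cohort$disturbance, tolerance = 1e-10)

  expect_error(read_cohort(path2), "lacks columns")
})
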