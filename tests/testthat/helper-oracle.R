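# Independent brute-force oracle for the segmented fit: one lm() per
# candidate breakpoint, no shared code with the package's profiling path.
brute_force_profile <- function(x, y, min_seg = 5L,
                                grid_quantiles = c(0.1, 0.9)) {
  qs <- quantile(x, grid_quantiles, names = FALSE)
  cand <- sort(unique(x))
  nb <- vapply(cand, function(cv) sum(x <= cv), numeric(1))
  keep <- cand >= qs[1] & cand <= qs[2] &
    nb >= min_seg & (length(x) - nb) >= min_seg
  cand <- cand[keep]
  sse <- numeric(length(cand))
  beta2 <- numeric(length(cand))
  for (i in seq_along(cand)) {
    u <- pmax(x - cand[i], 0)
    fit <- lm(y ~ x + u)
    sse[i] <- sum(residuals(fit)^2)
    beta2[i] <- coef(fit)[["u"]]
  }
  data.frame(psi = cand, sse = sse, beta2 = beta2)
}

# Noisy broken-line fixture: x ~ N(100, 15), knot at a chosen quantile.
make_piecewise <- function(n = 400, knot_q = 0.6, beta0 = 20, beta1 = 1,
                           beta2 = -1, noise_sd = 10, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 100, 15)
  psi <- qnorm(knot_q, 100, 15)
  y <- beta0 + beta1 * x + beta2 * pmax(x - psi, 0) +
    rnorm(n, 0, noise_sd)
  list(x = x, y = y, psi = psi, beta0 = beta0, beta1 = beta1,
       beta2 = beta2)
}

# Observed-score pair from a small disturbance cohort, for oracle checks
# on realistically shaped data.
make_observed_pair <- function(n = 300, rho = 0.1, alpha = 9, beta = 1,
                               seed = 1) {
  cohort <- generate_cohort(simulation_config(
    n = n, rho = rho, beta_alpha = alpha, beta_beta = beta, seed = seed))
  list(x = cohort$observed_iq, y = cohort$observed_creativity)
}
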