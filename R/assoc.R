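# Correlation inference, correlation comparison, skewness, and the logistic
# summarisation of verification outcomes.

#' Pearson correlation with a two-sided test
#'
#' Thin wrapper around \code{\link[stats]{cor.test}} returning the
#' correlation, the sample size and the two-sided p-value from the
#' t-transform with \code{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 4 observations,
#'   neither constant.
#' @return A list of class \code{"correlation_result"} with \code{r},
#'   \code{n}, \code{p}.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4L)
    stop("correlation inference requires n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = n, p = ct$p.value),
            class = "correlation_result")
}

#' Compare two independent correlations via Fisher's r-to-z transform
#'
#' Tests whether two Pearson correlations from independent groups differ,
#' using \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))}
#' referred to the standard normal; the p-value is two-sided. The statistic
#' is antisymmetric: swapping the groups flips its sign.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Group sizes, at least 4 each.
#' @return A list of class \code{"correlation_comparison"} with
#'   \code{r_below = r1}, \code{n_below = n1}, \code{r_above = r2},
#'   \code{n_above = n2}, \code{z_stat}, \code{p}.
#' @examples
#' fisher_z_compare(0.5, 100, 0, 100)$z_stat # about 3.83
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 < 4L || n2 < 4L)
    stop("both groups need n >= 4", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 makes the r-to-z transform infinite", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r_below = r1, n_below = n1, r_above = r2, n_above = n2,
                 z_stat = z, p = 2 * pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' Sample skewness (population-moment form)
#'
#' The standardized third central moment \code{m3 / m2^(3/2)}, with moments
#' taken over n (no small-sample bias correction), so large beta samples
#' reproduce the distribution's theoretical skewness.
#'
#' @param x Numeric vector, at least 3 non-missing values, not constant.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    stop("skewness requires at least 3 observations", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0)
    stop("skewness undefined for constant input", call. = FALSE)
  mean(d^3) / m2^1.5
}

#' Logistic verification-probability curve for one condition
#'
#' Fits the single-predictor logistic regression
#' \code{logit P(verified) = intercept + slope * rho} over the replicates
#' of one condition and evaluates the predicted verification probability on
#' an even rho grid spanning [0, 1]. When the outcome does not vary (all
#' verified or none), or the fit is degenerate (separation /
#' non-convergence), no coefficients are reported; the summary is flagged
#' \code{degenerate} and carries the empirical verification rate instead,
#' with a flat probability curve at that rate.
#'
#' @param rhos Numeric vector of per-replicate population correlations.
#' @param verified Logical vector of the same length.
#' @param grid_points Number of evenly spaced grid values (default 101).
#' @return A list of class \code{"condition_summary"} with
#'   \code{intercept}, \code{slope} (logit scale; \code{NA} when
#'   degenerate), \code{prob_curve} (data frame \code{rho}, \code{prob}),
#'   \code{n_reps}, \code{rate} (empirical verification rate), and
#'   \code{degenerate}.
#' @export
fit_verification_curve <- function(rhos, verified, grid_points = 101L) {
  if (length(rhos) != length(verified))
    stop("`rhos` and `verified` must have equal length", call. = FALSE)
  verified <- as.logical(verified)
  ok <- is.finite(rhos) & !is.na(verified)
  rhos <- rhos[ok]; verified <- verified[ok]
  n <- length(rhos)
  if (n == 0L) stop("no usable replicates", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_points)
  rate <- mean(verified)

  degenerate_summary <- function() {
    structure(list(intercept = NA_real_, slope = NA_real_,
                   prob_curve = data.frame(rho = grid, prob = rate),
                   n_reps = n, rate = rate, degenerate = TRUE),
              class = "condition_summary")
  }
  if (all(verified) || !any(verified)) return(degenerate_summary())

  fit <- tryCatch(
    withCallingHandlers(
      glm(verified ~ rhos, family = binomial()),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged ||
      any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50))
    return(degenerate_summary())

  cf <- coef(fit)
  prob <- plogis(cf[1] + cf[2] * grid)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 prob_curve = data.frame(rho = grid, prob = unname(prob)),
                 n_reps = n, rate = rate, degenerate = FALSE),
            class = "condition_summary")
}
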