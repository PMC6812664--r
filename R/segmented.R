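# Broken-line (segmented) regression with exhaustive breakpoint profiling.
#
# Model: E[Y] = beta0 + beta1 * z + beta2 * (z - psi) * I(z > psi),
# i.e. a slope beta1 below the breakpoint psi, slope beta1 + beta2 above it,
# with the two lines joined at psi. psi is not pre-specified: every distinct
# observed predictor value inside the admissible range is tried, and the
# candidate optimising the selection criterion is taken.

# Per-candidate least squares via prefix sums on the sorted predictor.
# Centring x and y keeps the 3x3 normal equations well conditioned; the
# returned quantities are on the original scale. O(n log n + #candidates).
segmented_profile <- function(x, y, candidates) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  mx <- mean(xs); my <- mean(ys)
  xc <- xs - mx; yc <- ys - my
  cc <- candidates - mx

  # suffix sums over subjects strictly above each candidate
  rx <- rev(cumsum(rev(xc)))
  rxx <- rev(cumsum(rev(xc * xc)))
  ry <- rev(cumsum(rev(yc)))
  rxy <- rev(cumsum(rev(xc * yc)))
  # index of the first sorted value strictly above each candidate
  first_above <- findInterval(candidates, xs) + 1L
  suffix <- function(s) ifelse(first_above > n, 0, s[pmin(first_above, n)])
  m <- n - first_above + 1L
  m[m < 0L] <- 0L
  Tx <- suffix(rx); Txx <- suffix(rxx)
  Ty <- suffix(ry); Txy <- suffix(rxy)

  Sxx <- sum(xc * xc); Sxy <- sum(xc * yc); Syy <- sum(yc * yc)

  a11 <- n
  a13 <- Tx - cc * m
  a22 <- Sxx
  a23 <- Txx - cc * Tx
  a33 <- Txx - 2 * cc * Tx + cc^2 * m
  r1 <- 0; r2 <- Sxy
  r3 <- Txy - cc * Ty

  # Cramer's rule for the symmetric 3x3 system (a12 = 0 after centring)
  D <- a11 * (a22 * a33 - a23^2) - a13^2 * a22
  D0 <- r1 * (a22 * a33 - a23^2) + a13 * (r2 * a23 - a22 * r3)
  D1 <- a11 * (r2 * a33 - r3 * a23) + a13 * (-r2 * a13)
  D2 <- a11 * (a22 * r3 - a23 * r2) + r1 * (-a22 * a13)
  singular <- !is.finite(D) | abs(D) <= .Machine$double.eps * a11 * a22 *
    pmax(a33, 1)
  b0 <- D0 / D; b1 <- D1 / D; b2 <- D2 / D
  sse <- Syy - (b0 * r1 + b1 * r2 + b2 * r3)
  sse[sse < 0] <- 0
  sse[singular] <- Inf
  b2[singular] <- NA_real_

  # map back to the original scale: slopes unchanged, intercept shifted
  list(candidates = candidates,
       sse = sse,
       beta2 = b2,
       beta1 = b1,
       beta0 = my + b0 - b1 * mx,
       syy = Syy)
}

#' Fit a segmented (broken-line) regression with an empirical breakpoint
#'
#' Fits \code{E[Y] = beta0 + beta1 z + beta2 (z - psi) I(z > psi)} by
#' profiling every admissible candidate breakpoint and selecting the
#' optimum. Candidates are the distinct observed predictor values between
#' the 10th and 90th percentiles (configurable) that leave at least
#' \code{min_seg} observations on each side; this rules out the degenerate
#' one- or two-point segments for which the fit is vacuous. By default the
#' candidate minimising the residual sum of squares is selected
#' (\code{selection = "sse"}, a continuous objective);
#' \code{selection = "beta2"} instead picks the candidate with the largest
#' absolute slope change. On clean piecewise-linear data the two agree.
#' Ties within relative tolerance 1e-10 are broken toward the smallest
#' candidate, so the fit is deterministic.
#'
#' Inference on the slope change is the Wald t-test for \code{beta2} from
#' the ordinary least-squares fit at the selected breakpoint
#' (\code{n - 3} residual df). Because the breakpoint is estimated rather
#' than fixed, this naive p-value does not account for the search and can
#' be anticonservative (the classical unidentified-nuisance-parameter
#' problem); no Davies-type correction is applied. The 95\% interval for
#' \code{psi} is profile-based: all candidates whose SSE satisfies
#' \code{n * log(SSE / SSE_min) <= qchisq(conf_level, 1)} are retained and
#' the interval is their range.
#'
#' @param x Predictor vector.
#' @param y Outcome vector, same length.
#' @param selection \code{"sse"} (default) or \code{"beta2"}.
#' @param min_seg Minimum observations required on each side of a candidate
#'   (default 5).
#' @param grid_quantiles Length-2 vector of predictor quantiles bounding the
#'   candidate range (default \code{c(0.1, 0.9)}).
#' @param conf_level Confidence level for the profile interval on
#'   \code{psi} (default 0.95).
#' @return An object of class \code{"segmented_fit"}: a list with
#'   \code{beta0}, \code{beta1}, \code{beta2}, \code{psi}, \code{se_beta2},
#'   \code{p_beta2}, \code{sse}, \code{sse_ols} (single-line fit),
#'   \code{n}, \code{psi_ci} (length 2), \code{df}, \code{estimable}, and
#'   the full \code{profile} (candidates, SSE, beta2 per candidate). When
#'   no admissible candidate exists, \code{estimable} is \code{FALSE} and
#'   the estimates are \code{NA} — a state distinct from a non-significant
#'   breakpoint.
#' @examples
#' x <- seq(0, 100)
#' y <- pmin(x, 50)
#' fit <- fit_segmented(x, y)
#' fit$psi # 50
#' @export
fit_segmented <- function(x, y, selection = c("sse", "beta2"),
                          min_seg = 5L, grid_quantiles = c(0.1, 0.9),
                          conf_level = 0.95) {
  selection <- match.arg(selection)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)

  not_estimable <- function() {
    structure(list(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                   psi = NA_real_, se_beta2 = NA_real_, p_beta2 = NA_real_,
                   sse = NA_real_, sse_ols = NA_real_, n = n,
                   psi_ci = c(NA_real_, NA_real_), df = NA_integer_,
                   selection = selection, estimable = FALSE,
                   profile = NULL),
              class = "segmented_fit")
  }
  if (n < 2L * min_seg) return(not_estimable())

  qs <- quantile(x, grid_quantiles, names = FALSE)
  cand <- sort(unique(x))
  n_below <- findInterval(cand, sort(x))      # observations with x <= cand
  keep <- cand >= qs[1] & cand <= qs[2] &
    n_below >= min_seg & (n - n_below) >= min_seg
  cand <- cand[keep]
  if (length(cand) == 0L) return(not_estimable())

  prof <- segmented_profile(x, y, cand)
  finite <- is.finite(prof$sse)
  if (!any(finite)) return(not_estimable())

  if (selection == "sse") {
    opt <- min(prof$sse[finite])
    tol <- opt * 1e-10 + .Machine$double.eps * (prof$syy + 1)
    idx <- which(finite & prof$sse <= opt + tol)[1L]
  } else {
    ab2 <- abs(prof$beta2)
    ab2[!finite] <- -Inf
    opt <- max(ab2)
    tol <- abs(opt) * 1e-10
    idx <- which(finite & ab2 >= opt - tol)[1L]
  }
  psi <- prof$candidates[idx]

  # exact OLS refit at the selected breakpoint for the reported estimates
  u <- pmax(x - psi, 0) * (x > psi)
  fit <- lm(y ~ x + u)
  cf <- suppressWarnings(summary(fit)$coefficients)
  sse <- sum(residuals(fit)^2)
  sse_ols <- sum(residuals(lm(y ~ x))^2)

  # profile interval for psi from the SSE profile (chi-square(1) cut)
  sse_min <- min(prof$sse[finite])
  floor_sse <- .Machine$double.eps * (prof$syy + 1)
  ratio <- pmax(prof$sse, floor_sse) / max(sse_min, floor_sse)
  in_ci <- finite & (n * log(ratio) <= qchisq(conf_level, 1))
  psi_ci <- range(prof$candidates[in_ci])

  structure(list(
    beta0 = unname(cf["(Intercept)", "Estimate"]),
    beta1 = unname(cf["x", "Estimate"]),
    beta2 = if ("u" %in% rownames(cf)) unname(cf["u", "Estimate"]) else 0,
    psi = psi,
    se_beta2 = if ("u" %in% rownames(cf)) unname(cf["u", "Std. Error"])
               else NA_real_,
    p_beta2 = if ("u" %in% rownames(cf)) unname(cf["u", "Pr(>|t|)"])
              else NA_real_,
    sse = sse, sse_ols = sse_ols, n = n,
    psi_ci = psi_ci, df = fit$df.residual,
    selection = selection, estimable = TRUE,
    profile = data.frame(psi = prof$candidates, sse = prof$sse,
                         beta2 = prof$beta2)),
    class = "segmented_fit")
}

#' Evaluate the fitted broken-line mean function
#'
#' Returns \code{beta0 + beta1 z + beta2 (z - psi) I(z > psi)}. The two
#' branches agree at \code{z = psi}, i.e. the fitted lines join at the
#' breakpoint.
#'
#' @param fit A \code{"segmented_fit"} object with \code{estimable = TRUE}.
#' @param z Numeric vector of predictor values.
#' @return Numeric vector of expected outcomes.
#' @export
predict_segmented <- function(fit, z) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (!isTRUE(fit$estimable))
    stop("fit has no estimable breakpoint", call. = FALSE)
  fit$beta0 + fit$beta1 * z + fit$beta2 * (z - fit$psi) * (z > fit$psi)
}

#' @export
predict.segmented_fit <- function(object, newdata, ...) {
  predict_segmented(object, newdata)
}

#' @export
print.segmented_fit <- function(x, digits = 4, ...) {
  cat("Segmented (broken-line) regression fit\n")
  if (!isTRUE(x$estimable)) {
    cat("  no estimable breakpoint (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf("  breakpoint psi = %s  [%s, %s] (95%% profile interval)\n",
              format(x$psi, digits = digits),
              format(x$psi_ci[1], digits = digits),
              format(x$psi_ci[2], digits = digits)))
  cat(sprintf("  beta0 = %s, beta1 = %s, beta2 = %s (se %s, p = %s)\n",
              format(x$beta0, digits = digits),
              format(x$beta1, digits = digits),
              format(x$beta2, digits = digits),
              format(x$se_beta2, digits = digits),
              format.pval(x$p_beta2, digits = digits)))
  cat(sprintf("  SSE = %s (single line: %s), n = %d, selection = %s\n",
              format(x$sse, digits = digits),
              format(x$sse_ols, digits = digits), x$n, x$selection))
  invisible(x)
}
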