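#' Simulation configuration
#'
#' Bundles every generative and inferential knob for one virtual cohort:
#' sample size, the mean/SD of the true scores, the population correlation
#' between the two true traits, the beta shape parameters of the disturbance
#' distribution, whether disturbance is applied at all, the significance
#' level used downstream, and the RNG seed.
#'
#' @param n Positive integer, number of virtual subjects (at least 4, the
#'   minimum for any correlation inference).
#' @param true_mean Mean of both true-score distributions, in score units
#'   (IQ-type scale; default 100).
#' @param true_sd Standard deviation of both true-score distributions
#'   (default 15).
#' @param rho Population correlation between the two true scores, in
#'   \code{[0, 1]}, or the token \code{"uniform"} meaning a fresh
#'   \code{rho ~ U(0, 1)} is drawn when the cohort is generated.
#' @param beta_alpha,beta_beta Positive shape parameters of the
#'   beta-distributed disturbance. \code{(9, 1)} is negatively skewed (most
#'   subjects barely disturbed), \code{(1, 9)} positively skewed, and
#'   \code{(9, 9)} approximately symmetric.
#' @param disturbance_enabled If \code{FALSE}, the disturbance vector is all
#'   ones and observed scores are identical to true scores (the null arm).
#' @param alpha_level Significance level used by the verification criteria,
#'   in \code{(0, 1)}; default 0.05.
#' @param seed Integer RNG seed, or \code{NULL} to use the current RNG
#'   state.
#'
#' @return An object of class \code{"simulation_config"} (a named list).
#' @examples
#' cfg <- simulation_config(n = 400, rho = 0.1, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
simulation_config <- function(n,
                              true_mean = 100,
                              true_sd = 15,
                              rho = "uniform",
                              beta_alpha = 9,
                              beta_beta = 1,
                              disturbance_enabled = TRUE,
                              alpha_level = 0.05,
                              seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L)
    stop("`n` must be an integer >= 4", call. = FALSE)
  if (!is.numeric(true_sd) || true_sd <= 0)
    stop("`true_sd` must be positive", call. = FALSE)
  if (is.character(rho)) {
    if (!identical(rho, "uniform"))
      stop("`rho` must be a number in [0, 1] or \"uniform\"", call. = FALSE)
  } else if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
             rho < 0 || rho > 1) {
    stop("`rho` must be a number in [0, 1] or \"uniform\"", call. = FALSE)
  }
  if (!is.numeric(beta_alpha) || beta_alpha <= 0 ||
      !is.numeric(beta_beta) || beta_beta <= 0)
    stop("beta shape parameters must be positive", call. = FALSE)
  if (!is.numeric(alpha_level) || alpha_level <= 0 || alpha_level >= 1)
    stop("`alpha_level` must lie strictly between 0 and 1", call. = FALSE)
  structure(
    list(n = n, true_mean = true_mean, true_sd = true_sd, rho = rho,
         beta_alpha = beta_alpha, beta_beta = beta_beta,
         disturbance_enabled = isTRUE(disturbance_enabled),
         alpha_level = alpha_level,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

#' Draw a pair of correlated true-score vectors
#'
#' Generates two length-\code{n} vectors whose marginals are
#' \code{Normal(mean, sd)} and whose population correlation is \code{rho},
#' using the conditional-normal construction: the second standardized trait
#' is \code{rho * z1 + sqrt(1 - rho^2) * e} with independent standard-normal
#' \code{z1} and \code{e}, then both are rescaled to the requested mean and
#' SD. Scores are left untruncated; negative values under an IQ-type scale
#' (mean 100, SD 15) have probability around 1e-11 and truncating them would
#' distort the stated model.
#'
#' @param n Number of subjects (>= 2).
#' @param mean,sd Marginal mean and standard deviation (score units).
#' @param rho Population correlation, in \code{[0, 1]}.
#' @return A list with numeric vectors \code{iq} and \code{creativity}.
#' @examples
#' set.seed(1)
#' s <- draw_true_scores(1000, 100, 15, 0.5)
#' cor(s$iq, s$creativity)
#' @export
draw_true_scores <- function(n, mean, sd, rho) {
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(iq = mean + sd * z1, creativity = mean + sd * z2)
}

#' Draw the disturbance vector
#'
#' One beta-distributed disturbance value per subject, shared by both traits.
#' Values lie in \code{[0, 1]}; a LOW value means a HIGH degree of
#' disturbance (the subject's observed scores are strongly attenuated).
#'
#' @param n Number of subjects.
#' @param alpha,beta Positive beta shape parameters.
#' @return Numeric vector of length \code{n} with values in \code{[0, 1]}.
#' @export
draw_disturbance <- function(n, alpha, beta) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("beta shape parameters must be positive", call. = FALSE)
  rbeta(n, alpha, beta)
}

#' Attenuate true scores by the disturbance factor
#'
#' Elementwise product of true scores and disturbance. With all-positive
#' true scores the observed score lies between zero and the true score.
#'
#' @param true_scores Numeric vector of true scores.
#' @param disturbance Numeric vector of the same length, values in
#'   \code{[0, 1]}.
#' @return Numeric vector of observed scores.
#' @export
apply_disturbance <- function(true_scores, disturbance) {
  if (length(true_scores) != length(disturbance))
    stop("`true_scores` and `disturbance` must have equal length",
         call. = FALSE)
  true_scores * disturbance
}

#' Generate one virtual cohort
#'
#' Runs the full generative model: correlated true scores, beta-distributed
#' disturbance, multiplicative observed scores. With
#' \code{disturbance_enabled = FALSE} the disturbance vector is all ones and
#' the observed columns are identical to the true columns.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A data frame of class \code{"cohort"} with columns
#'   \code{true_iq}, \code{true_creativity}, \code{disturbance},
#'   \code{observed_iq}, \code{observed_creativity}, and attributes
#'   \code{rho_population} (the correlation actually used, after resolving
#'   \code{"uniform"}) and \code{config}.
#' @examples
#' cohort <- generate_cohort(simulation_config(n = 200, rho = 0.3, seed = 7))
#' attr(cohort, "rho_population")
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rho <- if (identical(config$rho, "uniform")) runif(1) else config$rho
  true <- draw_true_scores(config$n, config$true_mean, config$true_sd, rho)
  dist <- if (config$disturbance_enabled) {
    draw_disturbance(config$n, config$beta_alpha, config$beta_beta)
  } else {
    rep(1, config$n)
  }
  cohort <- data.frame(
    true_iq = true$iq,
    true_creativity = true$creativity,
    disturbance = dist,
    observed_iq = apply_disturbance(true$iq, dist),
    observed_creativity = apply_disturbance(true$creativity, dist)
  )
  class(cohort) <- c("cohort", "data.frame")
  attr(cohort, "rho_population") <- rho
  attr(cohort, "config") <- config
  cohort
}

#' Write / read a cohort as plain CSV
#'
#' The canonical on-disk format is a headered CSV with columns
#' \code{true_iq, true_creativity, disturbance, observed_iq,
#' observed_creativity}. \code{read_cohort()} accepts a named character
#' vector \code{col_map} translating external column names onto the
#' canonical ones (names = external, values = canonical), so datasets
#' deposited elsewhere under different headers can be loaded without
#' editing the file. Missing \code{disturbance} is reconstructed as
#' \code{observed_iq / true_iq} when both score columns are present.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @param col_map Optional named character vector of column renames applied
#'   before validation.
#' @return \code{read_cohort()} returns a \code{"cohort"} data frame;
#'   \code{write_cohort()} returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, col_map = NULL) {
  df <- read.csv(path)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    if (anyNA(idx))
      stop("col_map refers to columns absent from the file: ",
           paste(names(col_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    names(df)[idx] <- unname(col_map)
  }
  needed <- c("true_iq", "true_creativity", "observed_iq",
              "observed_creativity")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("cohort file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"disturbance" %in% names(df))
    df$disturbance <- ifelse(df$true_iq != 0, df$observed_iq / df$true_iq, 1)
  df <- df[c("true_iq", "true_creativity", "disturbance",
             "observed_iq", "observed_creativity")]
  class(df) <- c("cohort", "data.frame")
  df
}
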