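# Study orchestration: condition runners, the no-disturbance null arm,
# condition summaries, residual diagnostics, and CSV output.

# Named disturbance skewness profiles: beta shape pairs.
# "neg"  — negatively skewed, most subjects barely disturbed;
# "norm" — approximately symmetric; "pos" — positively skewed;
# "none" — disturbance disabled (observed == true).
skew_shapes <- function(profile) {
  switch(profile,
         neg = c(alpha = 9, beta = 1),
         norm = c(alpha = 9, beta = 9),
         pos = c(alpha = 1, beta = 9),
         none = c(alpha = NA_real_, beta = NA_real_),
         stop("unknown skew profile: ", profile, call. = FALSE))
}

#' Derive a deterministic stream of replicate seeds
#'
#' One root seed yields a reproducible vector of child seeds, so any single
#' replicate can be re-run in isolation by reusing its recorded seed.
#'
#' @param root_seed Integer root seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length \code{n}, each below 2^31.
#' @export
replicate_seeds <- function(root_seed, n) {
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Plan a full simulation experiment
#'
#' Desk-scale defaults (100 replicates per condition over sample sizes 100,
#' 400 and 1,600, plus a 300-replicate null arm at n = 1,600) keep a full
#' run to minutes on one CPU while preserving the qualitative pattern.
#' \code{paper_scale = TRUE} switches to the full design: sample sizes 100,
#' 400, 1,600 and 6,400, 500 replicates in each of the 12 conditions, and
#' a 1,500-replicate null arm at n = 6,400; expect a long runtime because
#' every replicate profiles thousands of candidate breakpoints.
#'
#' @param sample_sizes Integer vector of cohort sizes.
#' @param skew_profiles Character vector drawn from
#'   \code{c("neg", "norm", "pos")}.
#' @param reps_per_condition Replicates per (size, skew) condition.
#' @param null_arm_reps Replicates in the no-disturbance arm (0 to skip).
#' @param null_arm_n Cohort size of the null arm.
#' @param root_seed Root RNG seed for the whole experiment.
#' @param alpha_level Significance level for verification.
#' @param paper_scale If \code{TRUE}, override the size/replicate arguments
#'   with the full-scale design.
#' @return A list of class \code{"experiment_plan"}.
#' @export
experiment_plan <- function(sample_sizes = c(100, 400, 1600),
                            skew_profiles = c("neg", "norm", "pos"),
                            reps_per_condition = 100L,
                            null_arm_reps = 300L,
                            null_arm_n = 1600L,
                            root_seed = 1L,
                            alpha_level = 0.05,
                            paper_scale = FALSE) {
  if (isTRUE(paper_scale)) {
    sample_sizes <- c(100, 400, 1600, 6400)
    reps_per_condition <- 500L
    null_arm_reps <- 1500L
    null_arm_n <- 6400L
  }
  stopifnot(all(sample_sizes >= 4), reps_per_condition >= 1,
            all(skew_profiles %in% c("neg", "norm", "pos")))
  structure(list(sample_sizes = as.integer(sample_sizes),
                 skew_profiles = skew_profiles,
                 reps_per_condition = as.integer(reps_per_condition),
                 null_arm_reps = as.integer(null_arm_reps),
                 null_arm_n = as.integer(null_arm_n),
                 root_seed = as.integer(root_seed),
                 alpha_level = alpha_level),
            class = "experiment_plan")
}

# One replicate: draw rho (if "uniform"), generate the cohort, verify, and
# flatten everything into a single record row.
run_replicate <- function(condition_id, rep_id, n, profile, rho,
                          alpha_level, seed, true_mean = 100,
                          true_sd = 15) {
  shapes <- skew_shapes(profile)
  cfg <- simulation_config(
    n = n, true_mean = true_mean, true_sd = true_sd, rho = rho,
    beta_alpha = if (is.na(shapes["alpha"])) 9 else shapes[["alpha"]],
    beta_beta = if (is.na(shapes["beta"])) 1 else shapes[["beta"]],
    disturbance_enabled = !identical(profile, "none"),
    alpha_level = alpha_level, seed = seed)
  cohort <- generate_cohort(cfg)
  v <- verify_threshold(cohort, alpha_level = alpha_level)
  fit <- v$fit
  data.frame(
    condition_id = condition_id, rep_id = rep_id, n = n,
    skew_profile = profile,
    rho_population = attr(cohort, "rho_population"),
    rho_sample_true = cor(cohort$true_iq, cohort$true_creativity),
    seed = seed,
    beta0 = fit$beta0, beta1 = fit$beta1, beta2 = fit$beta2,
    psi = fit$psi, se_beta2 = fit$se_beta2, p_beta2 = fit$p_beta2,
    sse = fit$sse, psi_ci_low = fit$psi_ci[1], psi_ci_high = fit$psi_ci[2],
    r_overall = v$r_overall, p_overall = v$p_overall,
    r_below = v$r_below, n_below = v$n_below, p_below = v$p_below,
    r_above = v$r_above, n_above = v$n_above, p_above = v$p_above,
    z_compare = v$z_compare, p_compare = v$p_compare,
    skewness_disturbance = if (identical(profile, "none")) NA_real_
                           else sample_skewness(cohort$disturbance),
    crit1 = v$breakpoint_significant, crit2 = v$below_positive_significant,
    crit3 = v$below_greater_above, verified = v$verified,
    estimable = v$estimable,
    stringsAsFactors = FALSE)
}

#' Run one simulation condition
#'
#' Executes \code{reps} replicates of one (sample size, skewness) cell.
#' Each replicate draws a fresh population correlation (by default
#' \code{rho ~ U(0, 1)}), generates a cohort, runs the three-criterion
#' verification, and records the full fit and test statistics. Replicates
#' whose breakpoint or group correlations cannot be computed are recorded
#' with \code{estimable = FALSE} and count as unverified; nothing is
#' dropped.
#'
#' @param n Cohort size.
#' @param profile Skewness profile: \code{"neg"}, \code{"norm"},
#'   \code{"pos"}, or \code{"none"} (disturbance disabled).
#' @param reps Number of replicates.
#' @param seeds Integer vector of per-replicate seeds (length \code{reps});
#'   derive with \code{\link{replicate_seeds}}.
#' @param rho Per-replicate population correlation: \code{"uniform"}
#'   (default) or a fixed value in [0, 1].
#' @param alpha_level Significance level.
#' @param condition_id Label stored on every record.
#' @param true_mean,true_sd Marginals of the true scores.
#' @param verbose Emit a progress message per condition.
#' @return A data frame with one row per replicate (the replicate-record
#'   schema).
#' @export
run_condition <- function(n, profile, reps, seeds,
                          rho = "uniform", alpha_level = 0.05,
                          condition_id = paste0("n", n, "_", profile),
                          true_mean = 100, true_sd = 15,
                          verbose = FALSE) {
  stopifnot(length(seeds) == reps)
  if (verbose)
    message(sprintf("condition %s: n = %d, %d reps, seeds %d..%d",
                    condition_id, n, reps, seeds[1], seeds[reps]))
  rows <- lapply(seq_len(reps), function(i) {
    run_replicate(condition_id, i, n, profile, rho, alpha_level,
                  seeds[i], true_mean, true_sd)
  })
  do.call(rbind, rows)
}

#' Run the no-disturbance null arm
#'
#' Identical to \code{\link{run_condition}} with disturbance disabled:
#' observed scores equal true scores, so any verification is a false
#' positive. The long-run verification rate of this arm estimates the
#' procedure's type-I error.
#'
#' @inheritParams run_condition
#' @return A replicate-record data frame with \code{skew_profile = "none"}.
#' @export
run_null_arm <- function(n, reps, seeds, rho = "uniform",
                         alpha_level = 0.05, condition_id = "null_arm",
                         verbose = FALSE) {
  run_condition(n, "none", reps, seeds, rho = rho,
                alpha_level = alpha_level, condition_id = condition_id,
                verbose = verbose)
}

#' Run a full planned experiment
#'
#' Executes every (sample size, skewness) condition of the plan plus the
#' null arm, with per-condition seeds derived deterministically from the
#' root seed. The result is a pure function of the plan.
#'
#' @param plan An \code{\link{experiment_plan}}.
#' @param verbose Emit per-condition progress messages.
#' @return A list with \code{records} (one data frame, all replicates),
#'   \code{plan}, and \code{condition_seeds} (named vector; the manifest
#'   needed to replay any condition).
#' @export
run_experiment <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  grid <- expand.grid(n = plan$sample_sizes, profile = plan$skew_profiles,
                      stringsAsFactors = FALSE)
  cond_ids <- paste0("n", grid$n, "_", grid$profile)
  has_null <- plan$null_arm_reps > 0L
  all_ids <- c(cond_ids, if (has_null) "null_arm")
  cond_seeds <- setNames(replicate_seeds(plan$root_seed, length(all_ids)),
                         all_ids)
  pieces <- lapply(seq_len(nrow(grid)), function(i) {
    run_condition(grid$n[i], grid$profile[i], plan$reps_per_condition,
                  replicate_seeds(cond_seeds[[cond_ids[i]]],
                                  plan$reps_per_condition),
                  alpha_level = plan$alpha_level,
                  condition_id = cond_ids[i], verbose = verbose)
  })
  if (has_null) {
    pieces <- c(pieces, list(run_null_arm(
      plan$null_arm_n, plan$null_arm_reps,
      replicate_seeds(cond_seeds[["null_arm"]], plan$null_arm_reps),
      alpha_level = plan$alpha_level, verbose = verbose)))
  }
  list(records = do.call(rbind, pieces), plan = plan,
       condition_seeds = cond_seeds)
}

#' Summarize verification probability per condition
#'
#' Groups replicate records by condition and fits the logistic
#' verification-probability curve (verified ~ population rho) in each via
#' \code{\link{fit_verification_curve}}. Conditions with constant outcomes
#' are flagged degenerate and report the empirical rate, never dropped.
#'
#' @param records A replicate-record data frame.
#' @return A named list of \code{"condition_summary"} objects, one per
#'   condition, each carrying \code{condition_id}, \code{n} and
#'   \code{skew_profile} labels.
#' @export
summarize_conditions <- function(records) {
  stopifnot(all(c("condition_id", "rho_population", "verified") %in%
                  names(records)))
  ids <- unique(records$condition_id)
  out <- lapply(ids, function(id) {
    sub <- records[records$condition_id == id, ]
    s <- fit_verification_curve(sub$rho_population, sub$verified)
    s$condition_id <- id
    s$n <- sub$n[1]
    s$skew_profile <- sub$skew_profile[1]
    s
  })
  setNames(out, ids)
}

#' Flatten condition summaries to a data frame
#'
#' @param summaries The list returned by \code{\link{summarize_conditions}}.
#' @return A data frame with one row per condition: labels, replicate
#'   count, empirical verification rate, degeneracy flag, and the logistic
#'   coefficients.
#' @export
summaries_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition_id = s$condition_id, n = s$n,
               skew_profile = s$skew_profile, n_reps = s$n_reps,
               rate = s$rate, degenerate = s$degenerate,
               intercept = s$intercept, slope = s$slope,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Residual diagnostics for a segmented fit
#'
#' Residuals (observed minus predicted outcome), their mean per
#' predicted-value bin, and the overall mean. For a least-squares fit with
#' intercept the overall mean residual is zero up to rounding; per-bin
#' means near zero across the range of predictions indicate no systematic
#' lack of fit.
#'
#' @param fit A \code{"segmented_fit"}.
#' @param x,y The predictor and outcome the fit was computed on.
#' @param bins Number of equal-width bins over the predicted values.
#' @return A list with \code{residuals}, \code{bin_table} (data frame:
#'   bin midpoint of predictions, count, mean residual), and
#'   \code{mean_residual}.
#' @export
residual_diagnostics <- function(fit, x, y, bins = 10L) {
  pred <- predict_segmented(fit, x)
  resid <- y - pred
  edges <- seq(min(pred), max(pred), length.out = bins + 1L)
  bin <- findInterval(pred, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tab <- data.frame(
    predicted_mid = (edges[-1] + edges[-(bins + 1L)]) / 2,
    n = tabulate(bin, nbins = bins),
    mean_residual = vapply(seq_len(bins), function(b) {
      if (any(bin == b)) mean(resid[bin == b]) else NA_real_
    }, numeric(1)))
  list(residuals = resid, bin_table = tab, mean_residual = mean(resid))
}

#' Write replicate records or summaries to CSV
#'
#' @param x A data frame (replicate records or a summaries table).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
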