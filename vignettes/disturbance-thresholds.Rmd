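---
title: "Disturbance-induced threshold associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disturbance-induced threshold associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disturbsim)
```

## The question

Threshold hypotheses claim that a predictor–outcome association changes
character at some predictor value: for intelligence and creative
potential, a positive association below a threshold (conventionally
IQ 120) and a flat one above it. disturbsim implements a generative
counter-explanation: if two measured traits are both attenuated by the
*same* subject-level disturbance factor (low motivation, illness,
linguistic confusion), the attenuated observations can exhibit exactly
this broken-line signature even when the true traits are unrelated. The
package exists to quantify, by simulation, how often a standard
threshold-detection pipeline "verifies" a threshold under that model.

## The generative model

For each of $n$ virtual subjects:

1. true IQ $\sim N(\mu, \sigma^2)$;
2. true creativity $\sim N(\mu, \sigma^2)$ with population correlation
   $\rho$ to true IQ, induced by the conditional-normal construction
   ($z_2 = \rho z_1 + \sqrt{1-\rho^2}\,e$ on the standardized scale, then
   rescaled). Any construction with the correct joint distribution would
   do; this one is the simplest that makes $\rho$ exact;
3. disturbance $d \sim \mathrm{Beta}(\alpha, \beta)$ on $[0, 1]$, low
   values meaning strong disturbance. One draw per subject, shared by
   both traits;
4. observed score = true score $\times\ d$, for both traits.

Defaults are $\mu = 100$, $\sigma = 15$ (the IQ convention) and the three
canonical disturbance shapes: Beta(9, 1), negatively skewed — most
subjects nearly undisturbed, a few strongly attenuated, which we consider
the realistic shape for motivated volunteers; Beta(9, 9), roughly
symmetric around 0.5; Beta(1, 9), positively skewed. Normal scores are
left untruncated: $P(\text{negative}) \approx 10^{-11}$ at the default
scale, and truncation would distort the stated marginals.

What the generator deliberately does **not** emulate: classical
independent measurement error on each trait (only the shared
multiplicative factor is modelled), several simultaneous disturbance
variables (some shared, some trait-specific), non-beta disturbance
distributions, and discreteness or ceiling effects of real test scores.
Passing simulations therefore show what a *pure shared attenuation*
mechanism can do, not that it is the mechanism operating in any real
dataset.

## Segmented regression

The broken-line model is
$E[Y] = \beta_0 + \beta_1 z + \beta_2 (z - \psi)\, I(z > \psi)$,
continuous at the breakpoint $\psi$. `fit_segmented()` treats $\psi$ as
unknown and profiles it exhaustively:

* **Candidate grid** — every distinct observed predictor value between
  the 10th and 90th percentiles with at least 5 observations on each
  side. The bounds avoid degenerate one- or two-point segments for which
  a slope change is vacuous; both are tunable (`grid_quantiles`,
  `min_seg`).
* **Per-candidate fit** — ordinary least squares of $y$ on
  $(1, z, (z-\psi)^+)$. Implemented with centred prefix-sum normal
  equations solved by Cramer's rule, so a whole profile costs
  $O(n\log n + k)$ rather than $k$ QR factorizations; the estimates
  reported at the selected breakpoint come from an exact `lm()` refit.
  The test suite asserts the entire SSE profile equals a brute-force
  per-candidate `lm()` oracle.
* **Selection** — minimum SSE (default). The alternative rule sometimes
  described for this procedure, "the candidate with the largest
  $|\beta_2|$", is provided (`selection = "beta2"`) but is *not* the
  default for a measured reason: $|\beta_2|$ estimates inflate when one
  segment is short, so on a noiseless kink ($y = \min(z, 50)$,
  $z = 0,\dots,100$) the $|\beta_2|$ profile peaks at the grid edges
  ($|\beta_2| = 2.16$ at $\psi = 10$) rather than at the true knot
  ($|\beta_2| = 1$ at $\psi = 50$). Minimum SSE recovers the knot
  exactly.
* **Tie-break** — candidates within relative tolerance $10^{-10}$ of the
  optimum resolve to the smallest $\psi$; fits are fully deterministic.
* **Inference on $\beta_2$** — the Wald $t$-test from the OLS fit at the
  selected $\psi$ ($n-3$ residual df). Because $\psi$ was searched over,
  this naive p-value is known to be anticonservative (the unidentified-
  nuisance-parameter problem); no Davies-type correction is applied. The
  measured consequence at desk scale is a null verification rate of about
  5.5% rather than 5% (see the acceptance tests), which users should keep
  in mind when interpreting "significant" breakpoints.
* **Interval for $\psi$** — profile-based: all candidates with
  $n \log(\mathrm{SSE}/\mathrm{SSE}_{\min}) \le \chi^2_{1,0.95}$ form the
  95% interval (its construction is otherwise under-determined; this
  likelihood-ratio cut is standard and needs nothing beyond the profile
  already computed). On noisy broken-line data ($n = 400$, knot at the
  60th percentile, unit slope change, noise SD 10) the measured coverage
  over 200 replicates is 90%.
* **Degenerate inputs** — fewer than `2 * min_seg` points, a constant
  predictor, or no admissible candidate yield an `estimable = FALSE`
  result, deliberately distinct from a non-significant breakpoint.

## The verification rule

`verify_threshold()` fits the segmented model of observed creativity on
observed IQ — the threshold is always estimated, never pre-specified —
and declares the threshold hypothesis verified iff all three hold at the
chosen level (default $\alpha = 0.05$):

1. $\beta_2$ significant;
2. below-breakpoint correlation positive and significant;
3. below-breakpoint correlation significantly larger than the
   above-breakpoint one (Fisher r-to-z, two-sided), with
   $r_\text{below} > r_\text{above}$ enforced explicitly so a significant
   difference in the wrong direction never verifies.

A significant correlation *above* the breakpoint is not disqualifying —
demanding non-significance above would perversely reward small samples.
Subjects at exactly $\psi$ belong to the below group (matching the strict
inequality in the model's indicator). Each side must hold at least 4
usable observations — the smallest $n$ for which the correlation tests
exist; cohorts failing this are `estimable = FALSE` and counted as
unverified, since counting them as verified would inflate rates. The
comparison test is reported two-sided; with the direction constraint the
practical difference from a one-sided rule is a factor of two on the
p-value, absorbed into criterion 3's explicit direction check.

## The experiment layer

`run_condition()` runs one (sample size, skewness) cell: each replicate
draws its own $\rho \sim U(0,1)$ — per-replicate rather than
per-condition, because the verification-probability curves are functions
of $\rho$ *within* every cell — generates a cohort, verifies, and records
everything (fit, correlations, comparison, skewness of the realized
disturbance, seed) as one CSV-ready row. `run_null_arm()` is the same
with disturbance disabled; there, every verification is a false positive.
`summarize_conditions()` fits, per condition, the logistic regression of
the verified indicator on the *population* $\rho$ (the controlled
quantity; the realized true-score correlation is also recorded as
`rho_sample_true` for users who prefer it) and evaluates the predicted
probability on an even $\rho$ grid. Conditions with constant outcomes or
separation are flagged degenerate and report the empirical rate instead
of coefficients.

**Seed discipline.** One root seed per experiment; per-condition and
per-replicate child seeds are derived deterministically
(`replicate_seeds()`), and each record stores its seed, so any replicate
can be replayed in isolation. The whole experiment is a pure function of
its plan.

**Problem sizes.** The desk-scale defaults — 100 replicates per condition
over sample sizes 100/400/1,600, and a 300-replicate null arm at
n = 1,600 — were chosen as the smallest design that still shows the
qualitative pattern (verification probability rising with $n$, falling
with $\rho$) with usable Monte-Carlo precision; a full desk-scale run
takes a few minutes on one CPU. `paper_scale = TRUE` restores the full
design (sizes up to 6,400, 500 replicates per condition, 1,500-replicate
null arm).

## Known limitations

* The naive Wald breakpoint test is mildly anticonservative after the
  exhaustive search (above); a Davies-type correction is out of scope.
* Single breakpoint only; no quadratic or other smooth alternatives are
  fitted for model comparison.
* One shared disturbance variable; real settings plausibly mix shared
  and trait-specific attenuators.
* The profile interval for $\psi$ is confined to the candidate grid and
  slightly undercovers at moderate $n$ (90% measured at nominal 95%).
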