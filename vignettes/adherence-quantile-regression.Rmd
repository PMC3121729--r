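---
title: "Modeling medication adherence disparities across the MPR distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling medication adherence disparities across the MPR distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprqr)
```

## The problem

Medication adherence estimated from pharmacy refill data — the medication
possession ratio (MPR) — is bounded in $[0,1]$, quasi-continuous, and heavily
left-skewed: in large diabetes cohorts the median sits near 0.97 while a thin
lower tail of poorly adherent patients stretches toward zero. Mean-based
regression (ordinary least squares, or a linear mixed model with a random
intercept) summarizes a covariate's association with adherence by a single
number, the shift in the conditional mean. When a covariate — race/ethnicity
is the motivating example — affects the lower tail of the adherence
distribution much more strongly than its center, the mean model reports only
the averaged effect and the tail disparity is invisible. Conditional quantile
regression models every part of the distribution and makes such heterogeneous
effects estimable.

`mprqr` implements that whole workflow: MPR construction from refill records,
quantile regression by check-loss minimization with bootstrap inference,
the two mean-model comparators, an end-to-end covariate-adjusted comparison
pipeline, a patient-level resampling study, and a synthetic-cohort generator
in which the conditional quantile structure is user-controlled, so every
claim the package makes can be tested against a planted truth.

## MPR from refill records

For each patient and drug class (insulin HS501 and oral hypoglycemics HS502
by default), consecutive 90-day refill windows are anchored at the first fill
date — 90 days because that is the standard mail-order supply period. The
window sequence runs through the window containing the last fill; the final
window is truncated at the inactivity date (last fill date plus its days
supplied), so days on which the prescription had lapsed contribute no
eligible days, and supply extending beyond the final window's close adds no
eligible days either. Each fill's supply is credited entirely to the window
containing the fill date: there is no carry-over or stockpiling model, since
the cap (below) already absorbs oversupply. Classes are pooled at the
patient level — eligible days and supplied days are summed across classes —
and

$$\mathrm{MPR} = \min\!\left(1,\; \frac{\text{supplied days}}{\text{eligible
days}}\right),$$

with the cap applied to the final pooled ratio, not per window. Per-window
ratios are reported uncapped as diagnostics. Two readings of "average MPR
over follow-up" are possible — the pooled-days ratio or the mean of
per-window ratios; the pooled-days ratio is the implemented definition (it is
the one implied by summing eligible days into a single denominator), and the
per-window ratios remain available for sensitivity checks. Patients with zero
eligible days have no defined MPR and are excluded with a warning rather than
imputed.

## Quantile regression by smoothed check loss

For quantile level $\tau \in (0,1)$ the linear conditional-quantile model is
$Q_y(\tau \mid x) = x^\top \beta_\tau$, and $\hat\beta_\tau$ minimizes the
check-loss sum

$$\sum_{i=1}^n \rho_\tau\!\left(y_i - x_i^\top \beta\right), \qquad
\rho_\tau(r) = r\,(\tau - \mathbf{1}[r < 0]).$$

$\tau = 0.5$ is median ($L_1$) regression. The objective is convex and
piecewise linear, so Newton's method cannot be applied directly. The solver
uses finite smoothing: the kink at $r = 0$ is replaced by a quadratic on
$(-\gamma(1-\tau), \gamma\tau)$, making the objective $C^1$ and piecewise
quadratic, and damped Newton iterations (with ridge regularization whenever
fewer than $p$ residuals fall in the quadratic zone) minimize it at each
smoothing level. The half-width starts at $\gamma_0 = \operatorname{median}|y
- \bar y|$ and shrinks geometrically by a factor of 10 until it falls below
$10^{-8}$, with a final solve at the floor. Because an optimal solution of
the unsmoothed problem interpolates $p$ observations, a polishing step then
solves the exact fit through $p$-subsets of the observations nearest the
fitted hyperplane and keeps whichever solution has the smaller exact
objective.

Quantile solutions can be set-valued (any point between two order statistics
minimizes an intercept-only median problem), so the package's contract — and
all its solver tests — is the optimal *objective*, not a particular
coefficient vector. `exact_small_fit()` provides the independent oracle: on
instances with $n \le 12$, $p \le 3$ it enumerates every $p$-subset basic
solution and returns the global optimum. The solver matches it to $10^{-8}$
on hundreds of random instances, satisfies the subgradient condition
$\#\{r_i < 0\} \le n\tau \le \#\{r_i \le 0\} + p$, is equivariant to response
scaling and covariate shifts, and is unaffected by moving an already-positive
residual's response to $+10^6$ — the estimator is robust to response
outliers, though not to leverage points, which `leverage_flags()` reports
(and never removes) using coordinatewise median/MAD-standardized squared
distances against a $\chi^2_{0.975}$ threshold. The coordinatewise estimator
was chosen over a full minimum-covariance-determinant fit because it is
deterministic, fast, and sufficient for flagging; a heavier estimator can be
substituted upstream by filtering rows before encoding.

Quantile levels within $0.5/n$ of 0 or 1 are clipped with a warning:
clinically interesting cutoffs can sit at extreme percentiles (an MPR cutoff
of 0.40 lands near the 2nd percentile in highly adherent cohorts), where
estimates are fragile and the subgradient condition leaves essentially no
constraint.

### Inference

Rank-inversion confidence intervals are not implemented. Inference is by the
xy-pair bootstrap: whole observations are resampled with replacement, the
model is refitted per replicate, and per-coefficient intervals are the exact
empirical percentiles (order-statistic definition, no interpolation — the
2.5% point of 100 replicates is the 3rd order statistic). The accompanying
p-value is the smallest two-sided level at which the percentile interval
excludes zero, computed as $2\min(\hat F(0), 1 - \hat F(0^-))$ and floored at
$1/B$. Rank-deficient resamples are redrawn and counted. Simulation places
the realized coverage of nominal 95% intervals within a few points of
nominal at $n = 500$ with $B = 300$ replicates (the acceptance suite checks
$0.95 \pm 0.03$ over 500 simulation runs).

## Mean-model comparators

`fit_ols()` is homoscedastic least squares with classical standard errors.
Because bounded skewed outcomes routinely violate its assumptions, every fit
carries a studentized Breusch–Pagan heteroscedasticity test and an
Anderson–Darling residual-normality test — the diagnostics are attached, not
optional. `fit_lmm()` fits the Gaussian random-intercept model $y_{ij} =
x_{ij}^\top\beta + b_i + e_{ij}$ by maximum likelihood (REML optional)
through `lme4`. With one averaged outcome per patient the random intercept is
not identifiable; rather than reproduce an unidentifiable fit, the package
makes the singleton case an explicit, warned fallback to OLS fixed effects
with `sigma2_subject` reported as not estimable. Cross-sectional comparisons
still run — the fixed effects are what the comparison tables report — while
repeated-measure data (which the generator can produce with a known
between-patient variance) estimate both components; at 2,000 subjects with 4
periods the planted components (0.01, 0.02) are recovered within 20%
relative error.

## The analysis pipeline

`encode_design()` treatment-codes race against non-Hispanic White (missing
or unknown race is folded into the Other level), marital status against
married, employment against unemployed, and sex as a 0/1 male indicator
(female reference — retained as printed in the motivating analyses even
though such cohorts are ~97% male, so the lower-quantile sex coefficient is
expected to be fragile). Age is centered (sample mean by default, so the
intercept is the conditional quantile of the reference patient at the
average age) and a quadratic age term is included by default. Column order
is deterministic.

Quantile scenarios can be stated two ways: clinically meaningful MPR cutoffs
(e.g. 0.40/0.60/0.80/0.90) mapped through the right-continuous empirical CDF
with ties counted as $\le$ — so a cutoff equal to a data value includes it —
or direct percentile levels. `cutoff_to_tau()` and `tau_to_cutoff()` are
inverse up to the $1/n$ resolution of the empirical CDF. `fit_all()` fits
quantile regression at every scenario level plus OLS and optionally the LMM
on the identical design, and reports one tidy table; estimates are ×100
(percent scale) by default, matching how adherence differences are
tabulated, with the scale stamped on the output. Non-converged fits are
included and flagged, never silently dropped. `predicted_curves()` evaluates
each fit at reference covariates over an age grid per race level —
mean-model curves are parallel across races by construction; quantile curves
need not be. Quantile crossing, should it occur between fitted levels, is
reported as-is and not rearranged.

## The resampling comparison study

`run_study()` draws patients with replacement from a source cohort —
resampling at the patient level so repeated-measure rows travel with their
patient and the LMM's clustering survives — refits every requested method per
replicate, and aggregates replicate estimates into means, SDs-as-SEs, and
exact 2.5/97.5 empirical percentiles. Each replicate's random stream is
derived from the master seed and the replicate index, so results are
independent of execution order. Failed replicates are recorded and excluded;
more than 10% failures aborts with the first error messages. The full-scale
configuration is 5,000 patients × 10,000 replications (`paper_scale =
TRUE`); the desk default of 2,000 × 200 preserves the qualitative comparison
and is the scale used throughout the test suite, where the study's SD-as-SE
agrees with the Monte-Carlo SD of independent-data refits within 15%.

## The synthetic-cohort generator

Covariates are drawn independently at configurable prevalences; the defaults
emulate a large VA type 2 diabetes cohort (97.3% male, mean age 66 (SD
11.6), hypertension 25.7%, substance use disorder 14.4%, 8.6% missing race,
race split NHW/NHB/Other ≈ 52/30/19 among observed). Outcomes use the
inverse-CDF construction: given per-covariate coefficient curves
$\beta_j(\tau)$ (a `qcf`), a uniform $U$ is drawn per outcome and $Y =
\operatorname{clamp}(x^\top \beta(U), 0, 1)$. This was chosen over an
additive-error model because it makes $\beta(\tau)$ the literal estimand of
quantile regression at every $\tau$ — planted effects have an exact
simulation truth. Validity requires $x^\top\beta(\tau)$ non-decreasing in
$\tau$ on the covariate support; `validate_qcf()` checks this on a $\tau$
grid and rejects violations as configuration errors naming the offending
profile. Well-chosen curves keep the clamp inactive except in the extreme
tails, so recovery tests are unbiased. Repeated-measure mode adds a
patient-level Gaussian shift on the latent scale before clamping, giving the
LMM a known variance-component truth. Missing race is generated completely
at random and folded into Other at encoding time.

The preset `qcf_cohort_preset()` reproduces the left-skewed cohort shape —
median near 0.97 with the clinical cutoffs 0.40/0.60/0.80/0.90 near the
2nd/4th/15th/27th percentiles — and race-effect curves that shrink from the
lower to the upper tail. It is a qualitative emulation for testing, not a
reproduction claim; in particular the generator targets the median/IQR shape
of such cohorts and makes no attempt to match a reported MPR standard
deviation of 0.2 percentage points, which is inconsistent with an IQR of 13
on the same scale and is presumably a standard error. What the generator
deliberately does not emulate: dependence among comorbidities and between
comorbidities and age, coding artifacts of administrative data, informative
missingness of race, and mortality-driven censoring of follow-up. Passing
recovery tests on generated cohorts therefore demonstrates estimator
correctness under the planted model, not robustness to those real-data
features.

`generate_refill_records()` closes the loop with the MPR engine: for a
target MPR and window count $k$ it lays fills at window starts with a
terminal fill ending exactly at the close of window $k$, pinning the
eligible-day denominator at $90k$, so `compute_mpr()` recovers the target to
the nearest representable ratio $s/90k$ (supplied totals $s \in \{k, \dots,
90k\}$; $\{2, \dots, 90\}$ for a single window, which needs two fills unless
the target is 1).

## A worked example

```{r example}
q <- qcf(intercept = function(tau) 0.3 + 0.7 * tau,
         race_nhb = cbind(tau = c(0.1, 0.9), value = c(-0.15, 0)))
coh <- generate_covariates(cohort_config(n_patients = 4000, seed = 1))
coh$race_nhb <- as.numeric(!is.na(coh$race) & coh$race == "NHB")
coh$mpr <- generate_mpr(coh, q, seed = 2)

cmp <- fit_all(coh, mpr_model_spec(taus = c(0.1, 0.5, 0.9)),
               methods = c("qreg", "ols"), boot = 200, seed = 3)
cmp[cmp$term == "race_nhb", c("method", "tau", "estimate", "ci_low", "ci_high", "p")]
```

The planted deficit of −15 MPR percentage points at the 10th percentile,
−7.5 at the median, and 0 at the 90th is visible in the quantile rows, while
the OLS row reports only its average (≈ −7.5): the quantile-varying
disparity is exactly what a mean model cannot see.

## Numerical choices and limitations

* Solver tolerances: Newton gradient/step tolerance $10^{-10}$; smoothing
  floor $10^{-9}$ (one decade below the $10^{-8}$ schedule stop); polish over
  the $p+3$ smallest-residual rows. All solver comparisons are on objectives.
* Problem sizes in the acceptance suite — 200 oracle instances, planted
  recovery at $n = 5{,}000$, coverage over 500 runs of $n = 500$ with $B =
  300$, LMM recovery at 2,000 × 4, resampling calibration at 200 × 2,000 —
  were chosen as the smallest scales at which the Monte-Carlo error of each
  check is comfortably below its tolerance.
* Degenerate inputs: rank-deficient designs error naming the dependent
  columns; $\tau$ outside the resolvable range is clipped with a warning;
  zero-MAD columns are excluded from leverage distances with a warning;
  all-singleton subjects fall back to OLS with a warning.
* Not implemented (out of scope by design): censored/penalized/longitudinal
  quantile regression, quantile-crossing rearrangement, rank-inversion
  intervals, BCa intervals, non-Gaussian mixed models, multiple-testing
  adjustment across quantiles, and any ICD-9 cohort-identification or
  comorbidity-coding logic — comorbidities enter as pre-coded 0/1 flags.
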