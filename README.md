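# mprqr

Quantile-regression analysis of medication adherence disparities measured by
the medication possession ratio (MPR).

## The problem

MPR — days of medication supplied divided by eligible days across refill
windows, capped at 100% — is the standard refill-data measure of adherence in
pharmacoepidemiology. It is bounded, quasi-continuous and strongly
left-skewed (in large diabetes cohorts the median is near 0.97). A covariate
such as race/ethnicity may depress the *lower tail* of the adherence
distribution far more than its center; ordinary least squares and mixed
models, which model only the conditional mean, report a single averaged
effect and can miss the disparity entirely. Conditional quantile regression
models the effect at any quantile level τ and makes such heterogeneous
effects estimable. `mprqr` is for biostatisticians and health-services
researchers who want that analysis end to end, with every component testable
against simulated data with a planted truth.

## What is in the package

* **MPR engine** — `compute_mpr()`, `build_windows()`: per-patient MPR from
  refill records (`patient_id, drug_class, fill_date, days_supplied`), using
  90-day windows anchored at the first fill, an eligible-day denominator
  truncated at prescription inactivity, drug classes pooled per patient, and
  the 100% cap applied to the final ratio.
* **Quantile regression** — `qreg()` (formula interface) / `qreg_fit()`
  (matrix interface) minimize the check-loss objective

  $$\hat\beta_\tau = \arg\min_\beta \sum_i \rho_\tau(y_i - x_i'\beta), \qquad
  \rho_\tau(r) = r\,(\tau - 1[r<0]),$$

  by finite smoothing: the kink is replaced by a quadratic of half-width γ so
  Newton–Raphson applies, γ shrinks geometrically to ~1e-9, and a
  basic-solution polish finishes on an exact vertex. `exact_small_fit()` is
  the independent enumeration oracle for small instances; `qreg_boot_ci()`
  provides xy-pair bootstrap percentile intervals and p-values.
* **Mean-model comparators** — `fit_ols()` (with mandatory heteroscedasticity
  and residual-normality diagnostics) and `fit_lmm()` (random-intercept
  Gaussian mixed model, ML via lme4, with a warned OLS fallback when every
  subject is a singleton).
* **Disparity pipeline** — `encode_design()` (treatment coding against NHW /
  married / unemployed / female references, centered age + age², missing race
  folded into "Other"), `cutoff_to_tau()` / `tau_to_cutoff()` (clinical MPR
  cutoffs ↔ quantile levels through the empirical CDF), `fit_all()` (one tidy
  comparison table across QReg at all scenario levels, OLS and LMM),
  `univariate_screen()`, `leverage_flags()`, `predicted_curves()`.
* **Resampling study** — `run_study()`: patient-level resampling with
  replacement, refitting all methods per replicate, aggregating means,
  SDs-as-SEs and exact 2.5/97.5 percentiles (`summarize_percentiles()`).
* **Synthetic cohorts** — `generate_covariates()` (configurable prevalences
  emulating a VA type 2 diabetes cohort), `qcf()` / `generate_mpr()`
  (inverse-CDF outcome generation, so the planted coefficient curves
  β(τ) are the exact estimand of quantile regression at every τ), and
  `generate_refill_records()` (refill histories that round-trip a target MPR
  through the MPR engine).

## Worked example

Plant a race effect on MPR that shrinks from −0.15 at τ = 0.1 to 0 at
τ = 0.9, then compare quantile regression with OLS:

```r
library(mprqr)

q <- qcf(intercept = function(tau) 0.3 + 0.7 * tau,
         race_nhb = cbind(tau = c(0.1, 0.9), value = c(-0.15, 0)))
coh <- generate_covariates(cohort_config(n_patients = 4000, seed = 1))
coh$race_nhb <- as.numeric(!is.na(coh$race) & coh$race == "NHB")
coh$mpr <- generate_mpr(coh, q, seed = 2)

cmp <- fit_all(coh, mpr_model_spec(taus = c(0.1, 0.5, 0.9)),
               methods = c("qreg", "ols"), boot = 200, seed = 3)
cmp[cmp$term == "race_nhb", c("method", "tau", "estimate", "ci_low", "ci_high", "p")]
#>  method tau estimate ci_low ci_high        p
#>    qreg 0.1 -13.8000 -16.00  -11.90 5.00e-03
#>    qreg 0.5  -6.8200 -10.10   -3.63 5.00e-03
#>    qreg 0.9   0.0451  -1.46    1.02 8.70e-01
#>     ols  NA  -6.4400  -8.10   -4.78 2.65e-14
```

Estimates are on the percent scale. Quantile regression recovers the planted
gradient — a deficit of about 14 MPR percentage points at the 10th
percentile, 7 at the median, none at the 90th — while OLS reports only the
τ-averaged effect (≈ −7.5), exactly the disparity pattern a mean model
cannot resolve.

The MPR engine on a small refill history:

```r
rec <- data.frame(patient_id = "A", drug_class = "HS501",
                  fill_date = c("2001-01-01", "2001-04-01"),
                  days_supplied = c(90L, 45L))
compute_mpr(rec)
#>   patient_id eligible_days supplied_days mpr capped n_windows per_window_ratio
#> 1          A           135           135   1  FALSE         2             1, 1
```

The second window is truncated at the inactivity date (90 + 45 days after the
first fill), so 135 supplied days against 135 eligible days gives MPR 1.

See the methods vignette
(`vignettes/adherence-quantile-regression.Rmd`) for the model, the solver,
the generator's design and its limitations.

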