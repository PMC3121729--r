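# End-to-end disparity analysis: covariate encoding, quantile-scenario
# specification, model fitting across methods, and predicted-curve tables.

default_binary_covariates <- c("male", "cancer", "chd", "chf", "hypertension",
                               "stroke", "poor_hba1c", "bipolar", "gad", "mdd",
                               "ptsd", "psychotic", "substance_use")

#' Model specification for the adherence disparity analysis
#'
#' Defines the outcome, the primary covariate (race/ethnicity with
#' non-Hispanic White as reference), the adjustment set with its reference
#' levels (married, unemployed, female), age centering, and the quantile
#' scenario — either clinically meaningful MPR cutoffs mapped through the
#' empirical CDF ([cutoff_to_tau()]) or quantile levels given directly.
#'
#' @param outcome name of the outcome column (default `"mpr"`).
#' @param cutoffs MPR cutoff values in (0, 1) defining the quantile scenario
#'   (e.g. `c(0.4, 0.6, 0.8, 0.9)`), or `NULL`.
#' @param taus quantile levels in (0, 1), or `NULL`. Exactly one of `cutoffs`
#'   and `taus` must be given for quantile fits.
#' @param binary_covariates names of the 0/1 adjustment covariates expected in
#'   the cohort table (`"male"` encodes sex against a female reference).
#' @param age_center centering constant in years; `NULL` (default) centers at
#'   the sample mean, computed from the data at encoding time.
#' @param include_age_squared add a quadratic age term.
#' @return A list of class `"mpr_model_spec"`.
#' @export
mpr_model_spec <- function(outcome = "mpr", cutoffs = NULL, taus = NULL,
                           binary_covariates = default_binary_covariates,
                           age_center = NULL, include_age_squared = TRUE) {
  if (!is.null(cutoffs)) {
    if (any(cutoffs <= 0 | cutoffs >= 1))
      stop("cutoffs must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(taus)) stop_if_not_scalar_prob(taus, "taus")
  structure(list(outcome = outcome, cutoffs = cutoffs, taus = taus,
                 binary_covariates = binary_covariates,
                 age_center = age_center,
                 include_age_squared = isTRUE(include_age_squared)),
            class = "mpr_model_spec")
}

#' Encode a cohort table into a regression design matrix
#'
#' Treatment coding against the stated references: race against NHW (missing
#' or unknown race is folded into the Other level), marital status against
#' married, employment against unemployed, and sex enters as the 0/1 `male`
#' column (female reference). Age is centered at `spec$age_center` (sample
#' mean if unset) and a quadratic term appended when requested. Column order
#' is deterministic and recorded. The reference patient — NHW, female,
#' married, unemployed, no comorbidities, age at the centering constant —
#' encodes as an all-zero dummy block.
#'
#' @param cohort cohort table (see [generate_covariates()] for the layout).
#' @param spec an [mpr_model_spec()].
#' @param adjusted `TRUE` for the full covariate set; `FALSE` for race terms
#'   only.
#' @return A list of class `"mpr_design"`: `x` (design matrix with intercept),
#'   `y` (outcome vector, or `NULL` when absent from the table),
#'   `age_center`, `columns`, and `subject` (patient ids when present).
#' @export
encode_design <- function(cohort, spec = mpr_model_spec(), adjusted = TRUE) {
  n <- nrow(cohort)
  race <- as.character(cohort$race)
  race[is.na(race)] <- "Other"
  bad <- setdiff(unique(race), c("NHW", "NHB", "Other"))
  if (length(bad))
    stop("unseen race category: ", paste(bad, collapse = ", "), call. = FALSE)
  cols <- list(`(Intercept)` = rep(1, n),
               race_nhb = as.numeric(race == "NHB"),
               race_other = as.numeric(race == "Other"))
  age_center <- spec$age_center
  if (adjusted) {
    marital <- as.character(cohort$marital)
    bad <- setdiff(unique(marital), c("married", "divorced", "never_married"))
    if (length(bad))
      stop("unseen marital category: ", paste(bad, collapse = ", "), call. = FALSE)
    employment <- as.character(cohort$employment)
    bad <- setdiff(unique(employment), c("unemployed", "retired", "employed"))
    if (length(bad))
      stop("unseen employment category: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (is.null(age_center)) age_center <- mean(cohort$age)
    age_c <- cohort$age - age_center
    cols$male <- as.numeric(cohort$male)
    cols$age_c <- age_c
    if (spec$include_age_squared) cols$age_c2 <- age_c^2
    cols$never_married <- as.numeric(marital == "never_married")
    cols$divorced <- as.numeric(marital == "divorced")
    cols$employed <- as.numeric(employment == "employed")
    cols$retired <- as.numeric(employment == "retired")
    flags <- setdiff(spec$binary_covariates, "male")
    miss <- setdiff(flags, names(cohort))
    if (length(miss))
      stop("cohort table lacks adjustment covariates: ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (nm in flags) cols[[nm]] <- as.numeric(cohort[[nm]])
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  y <- if (spec$outcome %in% names(cohort)) as.numeric(cohort[[spec$outcome]])
       else NULL
  structure(list(x = x, y = y, age_center = age_center,
                 columns = colnames(x),
                 subject = cohort$patient_id, spec = spec,
                 adjusted = adjusted),
            class = "mpr_design")
}

#' Map MPR cutoffs to quantile levels through the empirical CDF
#'
#' `cutoff_to_tau()` returns the right-continuous empirical CDF value at each
#' cutoff (`tau = mean(y <= cutoff)`, ties counted as below-or-equal);
#' `tau_to_cutoff()` inverts via the order-statistic quantile (smallest sample
#' value whose CDF reaches `tau`). Both clip results away from 0 and 1 (to
#' `0.5/n` and `1 - 0.5/n`) with a warning, since quantile fits at the exact
#' extremes are undefined.
#'
#' @param y sample of outcome values (e.g. MPR).
#' @param cutoffs outcome cutoff values in (0, 1).
#' @param taus quantile levels in (0, 1).
#' @return Numeric vector of quantile levels (or cutoffs), named by input.
#' @examples
#' cutoff_to_tau(c(0.2, 0.4, 0.6, 0.8, 1.0), 0.4)  # 2 of 5 values <= 0.4
#' @export
cutoff_to_tau <- function(y, cutoffs) {
  if (!length(y)) stop("empty sample", call. = FALSE)
  n <- length(y)
  tau <- vapply(cutoffs, function(cc) mean(y <= cc), numeric(1))
  lo <- 0.5 / n; hi <- 1 - 0.5 / n
  if (any(tau < lo | tau > hi)) {
    warning(sprintf("quantile level(s) clipped into [%g, %g]", lo, hi))
    tau <- pmin(pmax(tau, lo), hi)
  }
  setNames(tau, paste0("cutoff=", cutoffs))
}

#' @rdname cutoff_to_tau
#' @export
tau_to_cutoff <- function(y, taus) {
  if (!length(y)) stop("empty sample", call. = FALSE)
  stop_if_not_scalar_prob(taus, "taus")
  setNames(percentile_exact(y, taus), paste0("tau=", taus))
}

#' Fit all methods for the adherence disparity comparison
#'
#' Fits quantile regression at every level of the scenario plus OLS and (when
#' requested) the random-intercept LMM on the same encoded design, and
#' assembles one tidy comparison table of race and adjustment-covariate
#' coefficients across quantiles versus means. Unadjusted models contain the
#' race terms only; adjusted models the full covariate set. Coefficients are
#' reported on the percent scale (estimates and intervals multiplied by 100)
#' to match how adherence differences are usually tabulated; internal
#' computation stays on the proportion scale.
#'
#' @param cohort cohort table containing the outcome column and covariates;
#'   for the LMM, repeated rows per `patient_id` identify the subjects.
#' @param spec an [mpr_model_spec()] (its `cutoffs` or `taus` define the
#'   quantile levels).
#' @param methods subset of `c("qreg", "ols", "lmm")`.
#' @param adjusted fit the fully adjusted model (default) or race-only.
#' @param boot bootstrap replicates for quantile-regression intervals and
#'   p-values (0 skips them).
#' @param seed integer seed for bootstrap randomness.
#' @param scale `"percent"` (default) or `"proportion"` for reported
#'   estimates.
#' @return A data frame of class `"mpr_comparison"` with columns `term`,
#'   `method`, `tau` (`NA` for mean models), `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `converged`; attributes `scale`, `n`, `age_center`,
#'   `taus`, `fits` (the underlying fit objects) and `design_info`.
#' @export
fit_all <- function(cohort, spec = mpr_model_spec(), methods = c("qreg", "ols", "lmm"),
                    adjusted = TRUE, boot = 0L, seed = NULL,
                    scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  methods <- match.arg(methods, c("qreg", "ols", "lmm"), several.ok = TRUE)
  design <- encode_design(cohort, spec, adjusted = adjusted)
  if (is.null(design$y))
    stop(sprintf("outcome column '%s' not found in cohort", spec$outcome),
         call. = FALSE)
  x <- design$x; y <- design$y
  mult <- if (scale == "percent") 100 else 1
  taus <- numeric()
  if ("qreg" %in% methods) {
    taus <- if (!is.null(spec$taus)) spec$taus
            else if (!is.null(spec$cutoffs)) cutoff_to_tau(y, spec$cutoffs)
            else stop("spec must provide cutoffs or taus for quantile fits",
                      call. = FALSE)
  }
  rows <- list(); fits <- list()
  blank <- function(term, method, tau, est, se, lo, hi, p, conv)
    data.frame(term = term, method = method, tau = tau, estimate = est,
               se = se, ci_low = lo, ci_high = hi, p = p, converged = conv,
               stringsAsFactors = FALSE)
  if ("qreg" %in% methods) {
    bseeds <- derive_seeds(seed, max(1L, length(taus)))
    for (k in seq_along(taus)) {
      tt <- unname(taus[k])
      fit <- qreg_fit(x, y, tt)
      ci <- if (boot > 0) qreg_boot_ci(fit, B = boot, seed = bseeds[k]) else NULL
      fit$ci <- ci
      fits[[paste0("qreg_tau", signif(tt, 6))]] <- fit
      rows[[length(rows) + 1L]] <- blank(
        names(fit$coefficients), "qreg", tt, mult * unname(fit$coefficients),
        NA_real_,
        if (is.null(ci)) NA_real_ else mult * ci$ci_low,
        if (is.null(ci)) NA_real_ else mult * ci$ci_high,
        if (is.null(ci)) NA_real_ else ci$p,
        fit$converged)
    }
  }
  if ("ols" %in% methods) {
    fit <- fit_ols(x, y)
    fits$ols <- fit
    z <- fit$coefficients / fit$se
    rows[[length(rows) + 1L]] <- blank(
      names(fit$coefficients), "ols", NA_real_, mult * unname(fit$coefficients),
      mult * unname(fit$se),
      mult * unname(fit$coefficients - qnorm(0.975) * fit$se),
      mult * unname(fit$coefficients + qnorm(0.975) * fit$se),
      unname(2 * stats::pnorm(-abs(z))), TRUE)
  }
  if ("lmm" %in% methods) {
    subject <- if (!is.null(design$subject)) design$subject else seq_len(nrow(x))
    fit <- fit_lmm(x, y, subject)
    fits$lmm <- fit
    z <- fit$coefficients / fit$se
    rows[[length(rows) + 1L]] <- blank(
      names(fit$coefficients), "lmm", NA_real_, mult * unname(fit$coefficients),
      mult * unname(fit$se),
      mult * unname(fit$coefficients - qnorm(0.975) * fit$se),
      mult * unname(fit$coefficients + qnorm(0.975) * fit$se),
      unname(2 * stats::pnorm(-abs(z))), TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  attr(out, "n_obs") <- nrow(x)
  attr(out, "age_center") <- design$age_center
  attr(out, "taus") <- taus
  attr(out, "fits") <- fits
  attr(out, "design_info") <- list(columns = design$columns,
                                   adjusted = adjusted, spec = spec,
                                   age_range = if (adjusted) range(cohort$age))
  class(out) <- c("mpr_comparison", "data.frame")
  out
}

#' @export
print.mpr_comparison <- function(x, digits = 3, ...) {
  if (is.null(attr(x, "n_obs", exact = TRUE))) {  # subset lost its metadata
    print(as.data.frame(x), row.names = FALSE)
    return(invisible(x))
  }
  cat(sprintf("Adherence model comparison (n = %d, %s scale",
              attr(x, "n_obs"), attr(x, "scale")))
  ac <- attr(x, "age_center")
  if (!is.null(ac)) cat(sprintf(", age centered at %.1f", ac))
  cat(")\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Univariate association screening
#'
#' One single-covariate model per covariate — a median (`tau = 0.5`) quantile
#' regression and an OLS fit of the outcome on that covariate alone — as
#' descriptive pre-model screening. Multi-level covariates (race, marital
#' status, employment) enter as their dummy block and report the OLS F-test
#' p-value of the block; single columns report the slope and its t-test. The
#' screen never gates the adjusted model, which includes all covariates
#' regardless.
#'
#' @param cohort cohort table containing the outcome.
#' @param spec an [mpr_model_spec()].
#' @return A data frame with one row per covariate: `covariate`, `df`,
#'   `qreg_estimate` and `ols_estimate` (first dummy for multi-level
#'   covariates), and `ols_p`.
#' @export
univariate_screen <- function(cohort, spec = mpr_model_spec()) {
  y <- cohort[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found", call. = FALSE)
  groups <- list()
  race <- as.character(cohort$race); race[is.na(race)] <- "Other"
  groups$race <- cbind(race_nhb = as.numeric(race == "NHB"),
                       race_other = as.numeric(race == "Other"))
  if (!is.null(cohort$age)) {
    ac <- if (is.null(spec$age_center)) mean(cohort$age) else spec$age_center
    groups$age <- cbind(age_c = cohort$age - ac)
  }
  if (!is.null(cohort$marital)) {
    m <- as.character(cohort$marital)
    groups$marital <- cbind(never_married = as.numeric(m == "never_married"),
                            divorced = as.numeric(m == "divorced"))
  }
  if (!is.null(cohort$employment)) {
    e <- as.character(cohort$employment)
    groups$employment <- cbind(employed = as.numeric(e == "employed"),
                               retired = as.numeric(e == "retired"))
  }
  for (nm in intersect(spec$binary_covariates, names(cohort)))
    groups[[nm]] <- cbind(as.numeric(cohort[[nm]]))
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (all(apply(g, 2, function(v) length(unique(v)) == 1L)))
      return(data.frame(covariate = nm, df = ncol(g),
                        qreg_estimate = NA_real_, ols_estimate = NA_real_,
                        ols_p = NA_real_, stringsAsFactors = FALSE))
    x <- cbind(`(Intercept)` = 1, g)
    qfit <- qreg_fit(x, y, 0.5)
    lmfit <- lm(y ~ g)
    an <- stats::anova(lmfit)
    data.frame(covariate = nm, df = ncol(g),
               qreg_estimate = unname(coef(qfit)[2L]),
               ols_estimate = unname(coef(lmfit)[2L]),
               ols_p = an[["Pr(>F)"]][1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Predicted outcome curves over an age grid
#'
#' Evaluates each fitted model of a comparison at reference covariates
#' (female, married, unemployed, no comorbidities) for each race level over a
#' grid of ages, producing the long-format table behind predicted-MPR-by-age
#' figures. Mean-model curves for two races are parallel (they differ by the
#' race coefficient at every age); quantile curves can fan out or converge.
#'
#' @param comparison an `"mpr_comparison"` from [fit_all()] (adjusted, so age
#'   is in the model).
#' @param age_grid ages (years) at which to evaluate.
#' @param races subset of `c("NHW", "NHB", "Other")`.
#' @param clamp clamp predictions into `[0, 1]` (clamp count kept in the
#'   `"clamped"` attribute).
#' @return A data frame with columns `method`, `tau`, `race`, `age`,
#'   `predicted` (on the proportion scale).
#' @export
predicted_curves <- function(comparison, age_grid,
                             races = c("NHW", "NHB", "Other"), clamp = TRUE) {
  info <- attr(comparison, "design_info")
  fits <- attr(comparison, "fits")
  if (is.null(info) || !info$adjusted)
    stop("predicted_curves requires an adjusted comparison", call. = FALSE)
  races <- match.arg(races, c("NHW", "NHB", "Other"), several.ok = TRUE)
  if (!is.null(info$age_range) &&
      any(age_grid < info$age_range[1] | age_grid > info$age_range[2]))
    warning("age grid extends beyond the observed age range [",
            round(info$age_range[1], 1), ", ", round(info$age_range[2], 1),
            "]; predictions are extrapolations")
  cols <- info$columns
  center <- attr(comparison, "age_center")
  newx <- function(race, age) {
    v <- setNames(numeric(length(cols)), cols)
    v["(Intercept)"] <- 1
    if (race == "NHB") v["race_nhb"] <- 1
    if (race == "Other") v["race_other"] <- 1
    v["age_c"] <- age - center
    if ("age_c2" %in% cols) v["age_c2"] <- (age - center)^2
    v
  }
  total_clamped <- 0L
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    method <- if (inherits(fit, "qreg")) "qreg" else fit$method
    tau <- if (inherits(fit, "qreg")) fit$tau else NA_real_
    for (race in races) {
      xm <- t(vapply(age_grid, function(a) newx(race, a),
                     numeric(length(cols))))
      pred <- as.numeric(xm %*% coef(fit))
      if (clamp) {
        total_clamped <- total_clamped + sum(pred < 0 | pred > 1)
        pred <- pmin(1, pmax(0, pred))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, tau = tau, race = race, age = age_grid,
                   predicted = pred, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "clamped") <- total_clamped
  out
}
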