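# Synthetic-cohort generator.
#
# Emulates the covariate mix of a VA type-2-diabetes cohort (prevalence
# defaults follow the published sample characteristics of such a cohort:
# ~97% male, mean age 66, hypertension ~26%, substance use ~14%, 8.6% missing
# race) together with an MPR outcome whose conditional quantile structure is
# user-controlled, and refill-record histories consistent with a target MPR.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the covariate prevalences of a large VA type 2 diabetes
#' cohort. Race probabilities are conditional on race being observed; a
#' missing-race indicator is drawn separately (missing completely at random)
#' and folded into the "Other (including unknown and missing)" level at
#' design-encoding time.
#'
#' @param n_patients number of patients (>= 1).
#' @param race_probs named probabilities over `NHW`, `NHB`, `Other` summing
#'   to 1 (within 1e-12).
#' @param covariate_prevalences named vector of binary-covariate
#'   probabilities in `[0, 1]`.
#' @param marital_probs,employment_probs named probabilities over the
#'   three-level categorical covariates, each summing to 1.
#' @param age_mean,age_sd age distribution (years); ages are truncated below
#'   at 19.
#' @param missing_race_rate probability that race is missing.
#' @param periods_per_patient repeated-measure periods (>= 1) for mixed-model
#'   data.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients,
                          race_probs = c(NHW = 5307, NHB = 3061, Other = 1930) / 10298,
                          covariate_prevalences = c(
                            male = 0.973, cancer = 0.050, chd = 0.139,
                            chf = 0.080, hypertension = 0.257, stroke = 0.030,
                            poor_hba1c = 0.116, bipolar = 0.019, gad = 0.022,
                            mdd = 0.078, ptsd = 0.051, psychotic = 0.024,
                            substance_use = 0.144),
                          marital_probs = c(married = 0.652, divorced = 0.286,
                                            never_married = 0.062),
                          employment_probs = c(unemployed = 0.482,
                                               retired = 0.308,
                                               employed = 0.210),
                          age_mean = 66, age_sd = 11.6,
                          missing_race_rate = 0.086,
                          periods_per_patient = 1L,
                          seed = NULL) {
  check_probs <- function(p, nm) {
    if (any(p < 0) || any(p > 1))
      stop(sprintf("%s must be probabilities in [0, 1]", nm), call. = FALSE)
  }
  check_simplex <- function(p, nm) {
    check_probs(p, nm)
    if (abs(sum(p) - 1) > 1e-12)
      stop(sprintf("%s must sum to 1 (got %.15g)", nm, sum(p)), call. = FALSE)
  }
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (periods_per_patient < 1) stop("periods_per_patient must be >= 1", call. = FALSE)
  if (!setequal(names(race_probs), c("NHW", "NHB", "Other")))
    stop("race_probs must be named NHW, NHB, Other", call. = FALSE)
  check_simplex(race_probs, "race_probs")
  check_simplex(marital_probs, "marital_probs")
  check_simplex(employment_probs, "employment_probs")
  check_probs(covariate_prevalences, "covariate_prevalences")
  check_probs(missing_race_rate, "missing_race_rate")
  if (age_sd <= 0) stop("age_sd must be positive", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 race_probs = race_probs[c("NHW", "NHB", "Other")],
                 covariate_prevalences = covariate_prevalences,
                 marital_probs = marital_probs,
                 employment_probs = employment_probs,
                 age_mean = age_mean, age_sd = age_sd,
                 missing_race_rate = missing_race_rate,
                 periods_per_patient = as.integer(periods_per_patient),
                 seed = seed),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML or JSON
#'
#' Parses a config file whose keys match the arguments of [cohort_config()]
#' (unknown keys are rejected) and validates it. Probability maps may be given
#' as named mappings.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(file)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required to read JSON configs", call. = FALSE)
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop("config file must be .yaml, .yml or .json", call. = FALSE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in c("race_probs", "covariate_prevalences", "marital_probs",
               "employment_probs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(cohort_config, raw)
}

#' Generate a synthetic cohort covariate table
#'
#' Draws race (possibly missing), sex, age, marital status, employment and
#' binary comorbidity flags per patient, independently across covariates,
#' with the probabilities in the [cohort_config()]. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return A data frame with one row per patient: `patient_id`, `race`
#'   (factor `NHW`/`NHB`/`Other`, `NA` when missing), `age`, `marital`,
#'   `employment`, and one 0/1 integer column per binary covariate (including
#'   `male`).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    race[runif(n) < config$missing_race_rate] <- NA
    out <- data.frame(
      patient_id = seq_len(n),
      race = factor(race, levels = c("NHW", "NHB", "Other")),
      age = pmax(19, rnorm(n, config$age_mean, config$age_sd)),
      marital = factor(sample(names(config$marital_probs), n, replace = TRUE,
                              prob = config$marital_probs),
                       levels = names(config$marital_probs)),
      employment = factor(sample(names(config$employment_probs), n,
                                 replace = TRUE,
                                 prob = config$employment_probs),
                          levels = names(config$employment_probs)),
      stringsAsFactors = FALSE)
    for (nm in names(config$covariate_prevalences))
      out[[nm]] <- rbinom(n, 1L, config$covariate_prevalences[[nm]])
    # the resolved config (including the seed) travels with the table
    attr(out, "config") <- config
    out
  })
}

#' Generate MPR outcomes with a planted conditional quantile structure
#'
#' Inverse-CDF construction: per outcome a latent uniform `U` is drawn and the
#' outcome is `clamp(x' beta(U), 0, 1)`, where the coefficient curves
#' `beta(tau)` come from a [qcf()]. This makes `beta(tau)` the exact estimand
#' of quantile regression at every `tau` (up to clamping, which well-chosen
#' curves keep inactive except in the extreme tails). With
#' `periods_per_patient > 1` a patient-level Gaussian shift of standard
#' deviation `subject_sd` is added on the latent scale before clamping, so a
#' random-intercept mixed model has a known variance-component truth.
#'
#' @param cohort cohort table; any numeric/logical column named by a qcf term
#'   is used as that covariate (the intercept is implicit).
#' @param q a [qcf()]; its monotonicity on the cohort's covariate support is
#'   validated first (violation is a configuration error).
#' @param seed integer seed.
#' @param periods number of repeated measures per patient (default 1).
#' @param subject_sd standard deviation of the patient-level latent shift
#'   used when `periods > 1`.
#' @return For `periods = 1`, a numeric vector of MPR values in `[0, 1]`
#'   aligned with the cohort rows. Otherwise a data frame with columns
#'   `patient_id`, `period`, `mpr`.
#' @export
generate_mpr <- function(cohort, q, seed = NULL, periods = 1L,
                         subject_sd = 0) {
  stopifnot(inherits(q, "qcf"), periods >= 1, subject_sd >= 0)
  x <- qcf_design(q, cohort)
  validate_qcf(q, x)
  n <- nrow(x)
  with_seed(seed, {
    shift <- if (periods > 1L) rnorm(n, 0, subject_sd) else numeric(n)
    draw_once <- function() {
      u <- runif(n)
      b <- qcf_eval(q, u)                       # n x p
      rowSums(x * b)
    }
    if (periods == 1L) {
      pmin(1, pmax(0, draw_once()))
    } else {
      per <- lapply(seq_len(periods), function(k)
        data.frame(patient_id = if (!is.null(cohort$patient_id))
                     cohort$patient_id else seq_len(n),
                   period = k,
                   mpr = pmin(1, pmax(0, draw_once() + shift))))
      out <- do.call(rbind, per)
      out[order(out$patient_id, out$period), , drop = FALSE]
    }
  })
}

#' Generate refill records that reproduce a target MPR
#'
#' Round-trip fixture generator for the MPR engine: per patient it lays out
#' fills across `n_windows` consecutive windows such that [compute_mpr()]
#' recovers the target to the nearest representable day-count ratio with
#' denominator `n_windows * window_len`. Fills are placed at window starts,
#' except that the final fill is positioned to end exactly at the close of the
#' last window, which pins the eligible-day denominator (under the inactivity
#' rule a trailing short fill would otherwise shorten the final window). With
#' a single window and a target below 1 this requires two fills, so supplied
#' totals below 2 days are not representable; for `k` windows the
#' representable totals are `{k, ..., 90k}` days (`{2, ..., 90}` when
#' `k = 1`).
#'
#' @param patient_ids vector of patient identifiers.
#' @param target_mpr numeric vector (recycled) of targets in `[0, 1]`.
#' @param n_windows number of refill windows (>= 1).
#' @param window_len window length in days.
#' @param start_date first fill date (ISO-8601 string or `Date`).
#' @param drug_class drug class code for the records.
#' @return A refill-record data frame accepted by [compute_mpr()].
#' @export
generate_refill_records <- function(patient_ids, target_mpr, n_windows,
                                    window_len = 90L,
                                    start_date = "2001-01-01",
                                    drug_class = "HS501") {
  if (any(target_mpr < 0 | target_mpr > 1))
    stop("target_mpr must lie in [0, 1]", call. = FALSE)
  if (n_windows < 1) stop("n_windows must be >= 1", call. = FALSE)
  k <- as.integer(n_windows); L <- as.integer(window_len)
  start_date <- as.Date(start_date)
  target_mpr <- rep_len(target_mpr, length(patient_ids))
  rows <- lapply(seq_along(patient_ids), function(i) {
    total <- L * k
    s <- round(target_mpr[i] * total)
    lo <- if (k == 1L) 2L else k
    s <- min(max(s, lo), total)
    if (s == total) {
      off <- (seq_len(k) - 1L) * L
      d <- rep(L, k)
    } else if (k == 1L) {
      off <- c(0L, L - 1L)
      d <- c(s - 1L, 1L)
    } else {
      base <- s %/% k; rem <- s %% k
      d <- base + (seq_len(k) <= rem)
      off <- c((seq_len(k - 1L) - 1L) * L, k * L - d[k])
    }
    data.frame(patient_id = patient_ids[i], drug_class = drug_class,
               fill_date = start_date + off, days_supplied = as.integer(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a cohort table as delimited text
#'
#' UTF-8, comma-delimited with a header row; factor columns are written as
#' their labels and missing race as an empty field.
#'
#' @param cohort a cohort table from [generate_covariates()].
#' @param file output path.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, na = "")
  invisible(file)
}
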