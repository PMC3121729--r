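# Resampling comparison of the estimators: repeated sampling with replacement
# from a source cohort, refitting every requested method per replicate, and
# aggregating replicate estimates into means, SDs-as-SEs and exact empirical
# percentiles.

#' Configuration for the resampling comparison study
#'
#' The full-scale study uses 5,000 patients per replicate and 10,000
#' replications; the desk default is 200 replications of 2,000 patients,
#' which preserves the qualitative comparison at a fraction of the cost.
#'
#' @param n_per_replicate patients drawn (with replacement) per replicate.
#' @param replications number of replicates (>= 2).
#' @param seed master seed; each replicate's random stream is derived
#'   deterministically from (seed, replicate index), so results do not depend
#'   on execution order.
#' @param methods methods refitted per replicate.
#' @param adjusted fit the adjusted model.
#' @param paper_scale convenience switch to 10,000 replications of 5,000
#'   patients.
#' @return A list of class `"resample_config"`.
#' @export
resample_config <- function(n_per_replicate = 2000L, replications = 200L,
                            seed = NULL, methods = c("qreg", "ols"),
                            adjusted = TRUE, paper_scale = FALSE) {
  if (paper_scale) {
    n_per_replicate <- 5000L
    replications <- 10000L
  }
  if (replications < 2) stop("replications must be >= 2", call. = FALSE)
  structure(list(n_per_replicate = as.integer(n_per_replicate),
                 replications = as.integer(replications),
                 seed = seed, methods = methods, adjusted = adjusted),
            class = "resample_config")
}

#' Run the resampling comparison study
#'
#' Each replicate draws `n_per_replicate` patients with replacement from the
#' source cohort — resampling is at the patient level, so repeated-measure
#' rows travel with their patient and any within-patient clustering survives —
#' refits all requested models, and the replicate coefficient estimates are
#' aggregated per (method, tau, term) into the mean estimate, the SD of the
#' replicate estimates (reported as the bootstrap SE), and exact empirical
#' 2.5/97.5 percentiles. Replicates whose fit fails are recorded and excluded
#' from aggregation; more than 10% failures aborts with diagnostics.
#'
#' @param cohort source cohort table including the outcome column.
#' @param spec an [mpr_model_spec()]; its scenario fixes the quantile levels
#'   (cutoffs are mapped through the empirical CDF of the source cohort once,
#'   so every replicate fits the same levels).
#' @param config a [resample_config()].
#' @param keep_replicates keep the replicate-level estimates for audit.
#' @return A data frame of class `"bootstrap_summary"` with columns `method`,
#'   `tau`, `term`, `mean`, `sd_as_se`, `p2.5`, `p97.5`; attributes
#'   `replications`, `failures`, `n_per_replicate` and (optionally)
#'   `replicates`.
#' @export
run_study <- function(cohort, spec = mpr_model_spec(), config = resample_config(),
                      keep_replicates = FALSE) {
  stopifnot(inherits(config, "resample_config"))
  if (nrow(cohort) < 1) stop("empty cohort", call. = FALSE)
  y_all <- cohort[[spec$outcome]]
  if (is.null(y_all)) stop("outcome column not found in cohort", call. = FALSE)
  taus <- if (!is.null(spec$taus)) spec$taus
          else if (!is.null(spec$cutoffs)) unname(cutoff_to_tau(y_all, spec$cutoffs))
          else if ("qreg" %in% config$methods)
            stop("spec must provide cutoffs or taus", call. = FALSE)
          else numeric()
  spec_fixed <- spec
  spec_fixed$taus <- taus
  spec_fixed$cutoffs <- NULL

  ids <- unique(cohort$patient_id)
  if (is.null(ids)) stop("cohort must have a patient_id column", call. = FALSE)
  rows_by_id <- split(seq_len(nrow(cohort)), cohort$patient_id)
  seeds <- derive_seeds(config$seed, config$replications)

  one_replicate <- function(b) {
    with_seed(seeds[b], {
      draw <- sample(ids, config$n_per_replicate, replace = TRUE)
      idx <- unlist(rows_by_id[as.character(draw)], use.names = FALSE)
      rep_cohort <- cohort[idx, , drop = FALSE]
      # resampled patients must stay distinct subjects for the LMM
      rep_cohort$patient_id <- rep(seq_along(draw),
                                   lengths(rows_by_id[as.character(draw)]))
      fit_all(rep_cohort, spec_fixed, methods = config$methods,
              adjusted = config$adjusted, boot = 0L, scale = "proportion")
    })
  }

  estimates <- vector("list", config$replications)
  failures <- 0L
  fail_msgs <- character()
  for (b in seq_len(config$replications)) {
    res <- tryCatch(suppressWarnings(one_replicate(b)), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      fail_msgs <- c(fail_msgs, conditionMessage(res))
    } else {
      estimates[[b]] <- data.frame(replicate = b,
                                   method = res$method, tau = res$tau,
                                   term = res$term, estimate = res$estimate,
                                   stringsAsFactors = FALSE)
    }
  }
  if (failures > 0.10 * config$replications)
    stop(sprintf("%d of %d replicates failed (> 10%%); first errors: %s",
                 failures, config$replications,
                 paste(head(unique(fail_msgs), 3), collapse = " | ")),
         call. = FALSE)
  est <- do.call(rbind, estimates)
  key <- interaction(est$method, ifelse(is.na(est$tau), -1, est$tau), est$term,
                     drop = TRUE, lex.order = TRUE)
  cells <- split(est, key)
  out <- do.call(rbind, c(lapply(cells, function(cell) {
    pct <- summarize_percentiles(cell$estimate)
    data.frame(method = cell$method[1L], tau = cell$tau[1L],
               term = cell$term[1L],
               mean = mean(cell$estimate), sd_as_se = sd(cell$estimate),
               p2.5 = pct[["2.5%"]], p97.5 = pct[["97.5%"]],
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  ord <- order(out$method, ifelse(is.na(out$tau), Inf, out$tau),
               match(out$term, unique(est$term)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replications") <- config$replications
  attr(out, "failures") <- failures
  attr(out, "n_per_replicate") <- config$n_per_replicate
  attr(out, "taus") <- taus
  if (keep_replicates) attr(out, "replicates") <- est
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

#' Exact empirical percentiles of replicate estimates
#'
#' Order-statistic percentiles without interpolation: the lower percentile is
#' the smallest value whose empirical CDF reaches the probability.
#'
#' @param estimates numeric vector of replicate estimates (>= 2).
#' @param probs probabilities (default the 2.5 and 97.5 percent points).
#' @return Named numeric vector of percentiles.
#' @examples
#' summarize_percentiles(1:100)  # c(`2.5%` = 3, `97.5%` = 98)
#' @export
summarize_percentiles <- function(estimates, probs = c(0.025, 0.975)) {
  if (length(estimates) < 2) stop("need at least 2 estimates", call. = FALSE)
  setNames(percentile_exact(estimates, probs),
           paste0(format(100 * probs, trim = TRUE), "%"))
}

#' @export
print.bootstrap_summary <- function(x, digits = 4, ...) {
  if (is.null(attr(x, "replications"))) {
    print(as.data.frame(x), row.names = FALSE)
    return(invisible(x))
  }
  cat(sprintf("Resampling study: %d replications of n = %d (%d failed)\n",
              attr(x, "replications"), attr(x, "n_per_replicate"),
              attr(x, "failures")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
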