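# Medication possession ratio (MPR) from pharmacy refill records.
#
# MPR = days of medication supplied / eligible days, computed over
# consecutive fixed-length refill windows (default 90 days, the usual VA
# mail-order supply period) anchored at a patient's first fill for a drug
# class. Eligible days stop accruing at the class's inactivity date (last
# fill date + its days supplied): prescriptions that have become inactive do
# not contribute to the denominator, so a partial final window counts only
# its actual calendar days. Classes are pooled at the patient level and the
# final ratio is capped at 100%.

default_drug_classes <- c("HS501", "HS502")

#' Read refill records from a delimited text file
#'
#' Expects a comma-delimited file with header
#' `patient_id,drug_class,fill_date,days_supplied` and ISO-8601 dates.
#'
#' @param file path to the file.
#' @return A validated data frame of refill records.
#' @export
read_refill_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_refill_records(df)
}

validate_refill_records <- function(records,
                                    allow_any_class = FALSE,
                                    drug_classes = default_drug_classes) {
  need <- c("patient_id", "drug_class", "fill_date", "days_supplied")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("refill records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$fill_date <- as.Date(records$fill_date)
  if (anyNA(records$fill_date))
    stop("unparseable fill_date values", call. = FALSE)
  ds <- records$days_supplied
  if (anyNA(ds) || any(ds < 1) || any(ds != round(ds)))
    stop("days_supplied must be positive whole-day counts", call. = FALSE)
  records$days_supplied <- as.integer(ds)
  if (!allow_any_class) {
    bad <- setdiff(unique(records$drug_class), drug_classes)
    if (length(bad))
      stop("unknown drug_class values: ", paste(bad, collapse = ", "),
           "; set allow_any_class = TRUE to accept them", call. = FALSE)
  }
  records
}

#' Refill windows for one patient-class record set
#'
#' Consecutive half-open windows of `window_len` days anchored at the first
#' fill date, running through the window containing the last fill. The final
#' window is truncated at the class's inactivity date (last fill date + its
#' days supplied) when the prescription runs out inside it, so a partial
#' final window contributes only its actual day count to the eligible-day
#' denominator; supply extending past the final window's close does not add
#' eligible days (that oversupply is handled by the MPR cap).
#'
#' @param fill_dates `Date` vector of fill dates for one patient and class.
#' @param days_supplied integer vector of supplied days per fill.
#' @param window_len window length in days (default 90).
#' @return A data frame with columns `start`, `end` (half-open, `end`
#'   exclusive) and `eligible_days`; zero rows when no fills are given.
#' @export
build_windows <- function(fill_dates, days_supplied, window_len = 90L) {
  stopifnot(window_len >= 1)
  if (length(fill_dates) == 0L)
    return(data.frame(start = as.Date(character()), end = as.Date(character()),
                      eligible_days = integer()))
  fill_dates <- as.Date(fill_dates)
  anchor <- min(fill_dates)
  offsets <- as.numeric(fill_dates - anchor)
  inactive <- max(offsets + days_supplied)
  n_win <- floor(max(offsets) / window_len) + 1L
  start_off <- (seq_len(n_win) - 1L) * window_len
  # middle windows are always full; only the final one can be cut short
  end_off <- pmin(start_off + window_len, inactive)
  data.frame(start = anchor + start_off, end = anchor + end_off,
             eligible_days = as.integer(end_off - start_off))
}

mpr_one_class <- function(fill_dates, days_supplied, window_len) {
  win <- build_windows(fill_dates, days_supplied, window_len)
  if (nrow(win) == 0L)
    return(list(eligible = 0L, supplied = 0L, per_window = numeric()))
  anchor <- win$start[1L]
  off <- as.numeric(as.Date(fill_dates) - anchor)
  idx <- pmin(floor(off / window_len) + 1L, nrow(win))
  supplied_by_win <- vapply(seq_len(nrow(win)), function(w)
    sum(days_supplied[idx == w]), numeric(1))
  list(eligible = sum(win$eligible_days),
       supplied = sum(days_supplied),
       per_window = supplied_by_win / win$eligible_days)
}

#' Compute per-patient medication possession ratio
#'
#' Supplied days are summed within refill windows per drug class (a fill is
#' credited entirely to the window containing its fill date; there is no
#' carry-over between windows), classes are pooled into a single
#' eligible/supplied day pair per patient, and the ratio is capped at 1. The
#' per-window ratios are reported uncapped for diagnostics.
#'
#' @param records refill-record data frame with columns `patient_id`,
#'   `drug_class`, `fill_date`, `days_supplied` (see [read_refill_records()]).
#' @param window_len refill window length in days (default 90).
#' @param allow_any_class accept drug classes other than HS501/HS502.
#' @param per_class if `TRUE`, return one row per patient-class instead of
#'   pooling classes (sensitivity analysis).
#' @return A data frame of class `"mpr_result"` with columns `patient_id`,
#'   `eligible_days`, `supplied_days`, `mpr`, `capped`, `n_windows`, plus a
#'   list column `per_window_ratio`. Patients with zero eligible days are
#'   excluded with a warning.
#' @examples
#' rec <- data.frame(patient_id = 1, drug_class = "HS501",
#'                   fill_date = c("2001-01-01", "2001-04-01"),
#'                   days_supplied = c(90L, 45L))
#' compute_mpr(rec)
#' @export
compute_mpr <- function(records, window_len = 90L, allow_any_class = FALSE,
                        per_class = FALSE) {
  records <- validate_refill_records(records, allow_any_class = allow_any_class)
  key <- if (per_class) interaction(records$patient_id, records$drug_class,
                                    drop = TRUE, sep = "/")
         else factor(records$patient_id, levels = unique(records$patient_id))
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    parts <- lapply(split(g, g$drug_class, drop = TRUE), function(cg)
      mpr_one_class(cg$fill_date, cg$days_supplied, window_len))
    eligible <- sum(vapply(parts, `[[`, numeric(1), "eligible"))
    supplied <- sum(vapply(parts, `[[`, numeric(1), "supplied"))
    per_window <- unlist(lapply(parts, `[[`, "per_window"), use.names = FALSE)
    data.frame(patient_id = g$patient_id[1L],
               eligible_days = as.integer(eligible),
               supplied_days = as.integer(supplied),
               mpr = if (eligible > 0) min(1, supplied / eligible) else NA_real_,
               capped = supplied > eligible,
               n_windows = length(per_window),
               per_window_ratio = I(list(per_window)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bad <- is.na(out$mpr)
  if (any(bad)) {
    warning(sprintf("%d patient(s) with zero eligible days excluded: %s",
                    sum(bad), paste(out$patient_id[bad], collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  class(out) <- c("mpr_result", "data.frame")
  out
}

#' Write an MPR table to a delimited text file
#'
#' @param x an `"mpr_result"` data frame from [compute_mpr()].
#' @param file output path; comma-delimited with header
#'   `patient_id,eligible_days,supplied_days,mpr,capped,n_windows`.
#' @export
write_mpr <- function(x, file) {
  cols <- c("patient_id", "eligible_days", "supplied_days", "mpr", "capped",
            "n_windows")
  utils::write.csv(as.data.frame(x)[cols], file, row.names = FALSE)
  invisible(file)
}
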