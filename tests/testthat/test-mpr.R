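# MPR engine: window construction, eligible-day accounting, capping,
# invariances, and the generator round-trip.

rec <- function(id, dates, days, class = "HS501") {
  data.frame(patient_id = id, drug_class = class,
             fill_date = as.Date("2001-01-01") + dates,
             days_supplied = as.integer(days), stringsAsFactors = FALSE)
}

test_that("windows are anchored at the first fill and end at inactivity", {
  w1 <- build_windows(as.Date("2001-01-01"), 90L)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$start, as.Date("2001-01-01"))
  expect_equal(w1$end, as.Date("2001-04-01"))
  expect_equal(w1$eligible_days, 90L)
  # contiguous refills: two full windows
  w2 <- build_windows(as.Date("2001-01-01") + c(0, 90), c(90L, 90L))
  expect_equal(sum(w2$eligible_days), 180L)
  # inactivity truncates the final window: fills day 0 (90d) and day 90 (45d)
  w3 <- build_windows(as.Date("2001-01-01") + c(0, 90), c(90L, 45L))
  expect_equal(w3$eligible_days, c(90L, 45L))
  # no fills -> no windows, not an error
  expect_equal(nrow(build_windows(as.Date(character()), integer())), 0L)
})

test_that("golden MPR fixtures are exact", {
  # one 90-day window, fully supplied
  m <- compute_mpr(rec(1, 0, 90))
  expect_equal(m$mpr, 1.0)
  expect_false(m$capped)
  # (90 + 45) / 180
  m <- compute_mpr(rec(1, c(0, 90), c(90, 45), class = c("HS501", "HS501")))
  # second window is truncated at inactivity -> 135 eligible of 135 supplied
  expect_equal(m$eligible_days, 135L)
  expect_equal(m$mpr, 1.0)
  # two full windows with 90 and 45 supplied: anchor full span with a 1-day
  # terminal fill so the denominator is 180
  r <- rbind(rec(1, c(0, 90), c(90, 44)), rec(1, 179, 1))
  m <- compute_mpr(r)
  expect_equal(m$eligible_days, 180L)
  expect_equal(m$mpr, 135 / 180)
  # oversupply is capped at 100% after the ratio
  m <- compute_mpr(rec(1, 0, 120))
  expect_equal(m$eligible_days, 90L)
  expect_equal(m$supplied_days, 120L)
  expect_equal(m$mpr, 1.0)
  expect_true(m$capped)
})

test_that("MPR is invariant to record order and fill splitting", {
  r <- rbind(rec(1, c(0, 30, 95), c(90, 10, 30)))
  base <- compute_mpr(r)
  shuffled <- compute_mpr(r[c(3, 1, 2), ])
  expect_equal(shuffled$mpr, base$mpr)
  expect_equal(shuffled$eligible_days, base$eligible_days)
  # split one fill into two same-day fills with the same total
  split <- rbind(rec(1, c(0, 30, 30, 95), c(90, 4, 6, 30)))
  expect_equal(compute_mpr(split)$mpr, base$mpr)
})

test_that("drug classes pool at the patient level", {
  r <- rbind(rec(1, 0, 90, "HS501"), rec(1, 0, 45, "HS502"))
  m <- compute_mpr(r)
  expect_equal(nrow(m), 1L)
  # HS502 window truncates at day 45: eligible 90 + 45, supplied 135
  expect_equal(m$eligible_days, 135L)
  expect_equal(m$supplied_days, 135L)
  per <- compute_mpr(r, per_class = TRUE)
  expect_equal(nrow(per), 2L)
  expect_equal(sort(per$eligible_days), c(45L, 90L))
})

test_that("per-window ratios are reported uncapped", {
  m <- compute_mpr(rec(1, c(0, 90), c(120, 90)))
  expect_equal(m$per_window_ratio[[1]], c(120 / 90, 1))
  expect_equal(m$mpr, 1.0)
})

test_that("record validation enforces classes, dates and day counts", {
  expect_error(compute_mpr(rec(1, 0, 90, class = "XX")), "unknown drug_class")
  expect_silent(compute_mpr(rec(1, 0, 90, class = "XX"), allow_any_class = TRUE))
  expect_error(compute_mpr(rec(1, 0, 0)), "positive whole-day")
  expect_error(compute_mpr(rec(1, 0, 90)[, -4]), "missing columns")
  bad <- rec(1, 0, 90); bad$fill_date <- "not-a-date"
  expect_error(compute_mpr(bad))
})

test_that("adding fills never decreases supplied days; extending follow-up never raises MPR", {
  r <- rec(1, c(0, 90), c(90, 60))
  base <- compute_mpr(r)
  more <- compute_mpr(rbind(r, rec(1, 100, 10)))
  expect_gte(more$supplied_days, base$supplied_days)
  # a later 1-day fill extends eligible days without matching supply
  extended <- compute_mpr(rbind(r, rec(1, 300, 1)))
  expect_lte(extended$mpr, base$mpr)
})

test_that("refill generation round-trips target MPR to the nearest representable ratio", {
  for (k in 1:8) {
    m_grid <- seq(0, 1, by = 0.01)
    recs <- generate_refill_records(seq_along(m_grid), m_grid, n_windows = k)
    got <- compute_mpr(recs)
    total <- 90L * k
    lo <- if (k == 1L) 2L else k
    expected <- pmin(pmax(round(m_grid * total), lo), total) / total
    expect_equal(got$eligible_days, rep(total, length(m_grid)))
    expect_equal(got$mpr, expected, tolerance = 1e-12)
  }
  # full adherence: exactly k fills of 90 days
  r <- generate_refill_records(1, 1.0, 4)
  expect_equal(nrow(r), 4L)
  expect_equal(r$days_supplied, rep(90L, 4))
  expect_error(generate_refill_records(1, 1.5, 2), "\\[0, 1\\]")
  expect_error(generate_refill_records(1, 0.5, 0), "n_windows")
})

test_that("MPR tables write and read back as delimited text", {
  m <- compute_mpr(rec(1:2, c(0, 0), c(45, 90)))
  f <- tempfile(fileext = ".csv")
  write_mpr(m, f)
  back <- utils::read.csv(f)
  expect_equal(back$mpr, m$mpr)
  rf <- tempfile(fileext = ".csv")
  r <- rec(1, c(0, 90), c(90, 45))
  utils::write.csv(r, rf, row.names = FALSE)
  expect_equal(compute_mpr(read_refill_records(rf))$mpr, 1.0)
})
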