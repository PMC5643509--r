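test_that("local solar time applies the longitudinal offset", {
  t <- utc("2015-06-21 12:00:00")
  expect_identical(local_solar_time(t, 0), t)
  ## Barrow, Alaska: -156.65 deg -> -10.4433 h -> 01:33:24 local
  expect_equal(format(local_solar_time(t, -156.65), "%H:%M:%S"), "01:33:24")
  ## Chukotka: +177.67 deg -> +11.8447 h -> 11:50:41 local
  t2 <- utc("2015-06-21 00:00:00")
  expect_equal(as.numeric(local_solar_time(t2, 177.67) - t2, units = "secs"),
               177.67 * 24 / 360 * 3600, tolerance = 1)
  expect_equal(format(round(local_solar_time(t2, 177.67)), "%H:%M:%S"),
               "11:50:41")
  expect_error(local_solar_time(t, 200), "longitude")
})

test_that("constant-separation traces classify trivially", {
  t0 <- utc("2015-06-01 00:00:00")
  tr <- data.table(nest_id = "T1", timestamp_utc = t0 + (0:99) * 60,
                   nest_temp_c = 35, surface_temp_c = 5)
  st <- classify_incubation(tr, extraction_params(margin_c = 3))
  expect_true(all(st$incubated))
  tr2 <- copy(tr)[, nest_temp_c := surface_temp_c]
  expect_false(any(classify_incubation(tr2)$incubated))
  expect_error(classify_incubation(copy(tr)[, nest_temp_c := NA_real_]),
               "unusable")
})

test_that("margin-only mode equals the brute-force per-reading oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 500
    tr <- data.table(nest_id = "T1",
                     timestamp_utc = utc("2015-06-01") + (1:n) * 60,
                     nest_temp_c = runif(n, 0, 40),
                     surface_temp_c = runif(n, 0, 20))
    p <- extraction_params(margin_c = 3, surface_window_min = 10,
                           steep_slope_c_min = Inf)
    got <- classify_incubation(tr, p)$incubated
    k <- 11L  # 10 min at 60 s, rounded up to odd
    base <- stats::runmed(tr$surface_temp_c, k)
    expect_identical(got, tr$nest_temp_c - base >= 3)
  }
})

test_that("classification is idempotent and finds square-wave transitions", {
  sq <- make_square_trace(n_cycles = 4, on_min = 120, off_min = 60)
  p <- extraction_params(smooth_window_min = 5)
  st <- classify_incubation(sq$trace, p)
  ## idempotence: same input, same output
  expect_identical(st, classify_incubation(sq$trace, p))
  truth <- sq$truth$incubated
  flips_got <- which(diff(st$incubated) != 0)
  flips_true <- which(diff(truth) != 0)
  expect_equal(length(flips_got), length(flips_true))
  ## every detected transition within one smooth window (5 min = 5 readings)
  expect_true(all(abs(flips_got - flips_true) <= 5))
})

test_that("bout segmentation follows the merge and labelling rules", {
  t0 <- utc("2015-06-01 00:00:00")
  dt_s <- 60
  mk_states <- function(inc, att) data.table(
    nest_id = "T1", timestamp_utc = t0 + (seq_along(inc) - 1) * dt_s,
    timestamp_local = t0 + (seq_along(inc) - 1) * dt_s,
    incubated = inc, attending = att)

  ## clean F->M switch at 12 h with no gap -> two 12-h bouts
  n <- 24 * 60
  att <- c(rep("F", n / 2), rep("M", n / 2))
  b <- segment_bouts(mk_states(rep(TRUE, n), att))
  expect_equal(nrow(b), 2L)
  expect_equal(b$attending, c("F", "M"))
  expect_equal(b$length_h, c(12, 12))
  expect_equal(b$start, c(t0, t0 + 12 * 3600))

  ## continuous incubation, no RFID -> single unknown bout
  b2 <- segment_bouts(mk_states(rep(TRUE, n), rep("unknown", n)))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$attending, "unknown")

  ## two blocks split by a 30-min gap, tolerance 60 -> one merged bout
  inc <- c(rep(TRUE, 120), rep(FALSE, 30), rep(TRUE, 120))
  att <- ifelse(inc, "F", "none")
  b3 <- segment_bouts(mk_states(inc, att),
                      params = extraction_params(recess_tolerance_min = 60))
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$length_h, 270 / 60)
  ## same data, tolerance 15 -> two bouts
  b4 <- segment_bouts(mk_states(inc, att),
                      params = extraction_params(recess_tolerance_min = 15))
  expect_equal(nrow(b4), 2L)
})

test_that("bouts are non-overlapping and within the trace span", {
  sim <- sim_noisefree(n_nests = 3, seed = 101)
  ds <- sim$dataset
  st <- incubation_states(ds$temperature, ds$rfid, ds$tags, ds$metadata,
                          exact_params())
  b <- segment_bouts(st, params = exact_params())
  for (nid in unique(b$nest_id)) {
    bb <- b[nest_id == nid][order(start)]
    expect_true(all(bb$start[-1] >= bb$end[-nrow(bb)]))
    span <- range(ds$temperature[nest_id == nid, timestamp_utc])
    expect_true(sum(bb$length_h) <=
                  as.numeric(span[2] - span[1], units = "hours") + 1)
  }
})

test_that("noise-free extraction reproduces the truth ledger exactly", {
  sim <- sim_noisefree(n_nests = 3, seed = 7)
  ds <- sim$dataset
  st <- incubation_states(ds$temperature, ds$rfid, ds$tags, ds$metadata,
                          exact_params())
  b <- segment_bouts(st, params = exact_params())
  tb <- copy(sim$truth$bouts)
  setorder(b, nest_id, start); setorder(tb, nest_id, start)
  expect_equal(nrow(b), nrow(tb))
  expect_equal(b$start, tb$start)
  expect_equal(b$end, tb$end)
  expect_equal(b$attending, tb$sex)
})

test_that("population median bout follows the midpoint convention", {
  expect_equal(population_median_bout(c(10, 12, 14)), 12)
  expect_equal(population_median_bout(c(10, 12)), 11)
  set.seed(8)
  x <- rlnorm(1001, log(11), 0.4)
  sorted <- sort(x)                      # brute-force oracle
  expect_equal(population_median_bout(x), sorted[501])
  expect_error(population_median_bout(numeric(0)), "no bouts")
})

test_that("incubation start estimation respects the precedence ladder", {
  ref <- list(typical_incubation_period_days = 21)
  ## (1) direct observation wins
  m <- make_meta("T1", incubation_start = utc("2015-05-20 06:00:00"),
                 first_egg_date = as.Date("2015-05-01"))
  est <- estimate_incubation_start(m, ref)
  expect_equal(est, utc("2015-05-20 06:00:00"), ignore_attr = TRUE)
  expect_equal(attr(est, "method"), "observed")
  ## (2) laying rule: first egg May 1, clutch 4 -> May 4
  m2 <- make_meta("T2", incubation_start = utc(NA),
                  first_egg_date = as.Date("2015-05-01"))
  expect_equal(as.Date(estimate_incubation_start(m2, ref)),
               as.Date("2015-05-04"), ignore_attr = TRUE)
  ## (3) hatch June 1 minus 21 d -> May 11
  m3 <- make_meta("T3", incubation_start = utc(NA),
                  hatch_start = utc("2015-06-01 00:00:00"))
  expect_equal(as.Date(estimate_incubation_start(m3, ref)),
               as.Date("2015-05-11"), ignore_attr = TRUE)
  ## (4) flotation lookup
  m4 <- make_meta("T4", incubation_start = utc(NA),
                  flotation_date = as.Date("2015-05-20"),
                  flotation_stage = "S3")
  expect_equal(as.Date(estimate_incubation_start(
    m4, ref, flotation_lookup = c(S3 = 8))), as.Date("2015-05-12"),
    ignore_attr = TRUE)
  ## (5) population median fallback, else an error naming the nest
  m5 <- make_meta("T5", incubation_start = utc(NA))
  est5 <- estimate_incubation_start(m5, ref,
    population_starts = utc(c("2015-05-10", "2015-05-12", "2015-05-20")))
  expect_equal(as.Date(est5), as.Date("2015-05-12"), ignore_attr = TRUE)
  expect_error(estimate_incubation_start(m5, ref), "T5")
})
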