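t0 <- utc("2015-06-01 00:00:00")

## build an explicit state series for one nest over whole local days
mk_states <- function(inc, att, dt_s = 60, nest_id = "T1") {
  n <- length(inc)
  data.table(nest_id = nest_id, timestamp_utc = t0 + (seq_len(n) - 1) * dt_s,
             timestamp_local = t0 + (seq_len(n) - 1) * dt_s,
             incubated = inc, attending = att)
}

test_that("incubation fraction is elapsed time over the typical period", {
  expect_equal(incubation_fraction(t0, t0, 21), 0)
  expect_equal(incubation_fraction(t0 + 10.5 * 86400, t0, 21), 50)
  expect_equal(incubation_fraction(t0 + 23 * 86400, t0, 21), 100 * 23 / 21)
  expect_gt(incubation_fraction(t0 + 23 * 86400, t0, 21), 100)
})

test_that("circadian regressors map hours onto the unit circle", {
  expect_equal(unlist(circadian_regressors(0)), c(sine = 0, cosine = 1))
  expect_equal(unlist(circadian_regressors(6)), c(sine = 1, cosine = 0),
               tolerance = 1e-12)
  r18 <- circadian_regressors(18)
  expect_equal(r18$sine, -1, tolerance = 1e-12)
  expect_equal(r18$cosine, 0, tolerance = 1e-12)
  expect_error(circadian_regressors(24), "0, 24")
  expect_error(circadian_regressors(-1), "0, 24")
  h <- runif(50, 0, 24)
  rr <- circadian_regressors(h)
  expect_equal(rr$sine^2 + rr$cosine^2, rep(1, 50), tolerance = 1e-12)
})

test_that("the 80/20 day yields one biparental record computed on the 80%", {
  n <- 1440                                   # one local day at 60 s
  inc <- rep(TRUE, n)
  att <- c(rep("F", n * 0.8 / 2), rep("M", n * 0.8 / 2), rep("M", n * 0.2))
  st <- mk_states(inc, att)
  ## phase covers the last 20% of the day
  ph <- data.table(nest_id = "T1", sex = "M",
                   start = t0 + 0.8 * 86400, end = t0 + 86400,
                   duration_days = 0.2, cause = "natural/unknown",
                   censored = FALSE)
  rec <- attendance_records(st, ph, make_meta("T1"), make_refs(),
                            granularity = "daily")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$inc_type, "biparental")
  expect_equal(rec$n_type, as.integer(n * 0.8))
  expect_equal(rec$purity, 80)
  expect_equal(rec$attendance, 100)

  ## a 50/50 day emits nothing
  ph5 <- copy(ph)[, start := t0 + 0.5 * 86400]
  rec5 <- attendance_records(st, ph5, make_meta("T1"), make_refs(),
                             granularity = "daily")
  expect_equal(nrow(rec5), 0L)

  ## attendance is computed on the pure portion only
  inc2 <- c(rep(TRUE, n * 0.8), rep(FALSE, n * 0.2))   # uniparental part bare
  rec2 <- attendance_records(mk_states(inc2, att), ph, make_meta("T1"),
                             make_refs(), granularity = "daily")
  expect_equal(rec2$attendance, 100)   # the 20% of zeros is outside the type
})

test_that("the 75% purity boundary is inclusive at hourly granularity", {
  n <- 60                                      # one hour at 60 s
  att <- c(rep("F", 45), rep("M", 15))
  st <- mk_states(rep(TRUE, n), att)
  ph <- data.table(nest_id = "T1", sex = "M", start = t0 + 45 * 60,
                   end = t0 + 3600, duration_days = 1 / 96,
                   cause = "natural/unknown", censored = FALSE)
  rec <- attendance_records(st, ph, make_meta("T1"), make_refs(),
                            granularity = "hourly", min_purity = 75)
  rec <- rec[local_hour == 0]
  expect_equal(nrow(rec), 1L)                  # exactly 75% -> emitted
  expect_equal(rec$purity, 75)
  expect_equal(rec$inc_type, "biparental")
  ## 30 of 60 minutes incubated, pure type -> 50%
  st2 <- mk_states(rep(c(TRUE, FALSE), each = 30), rep("F", 60))
  rec2 <- attendance_records(st2, NULL, make_meta("T1"), make_refs(),
                             granularity = "hourly")
  expect_equal(rec2[local_hour == 0, attendance], 50)
})

test_that("attendance equals the brute-force counting oracle on random windows", {
  set.seed(123)
  for (gran in c("daily", "hourly")) {
    n <- 3 * 1440
    st <- mk_states(runif(n) < 0.8,
                    sample(c("F", "M", "none"), n, TRUE))
    ph <- data.table(nest_id = "T1", sex = "M",
                     start = t0 + 86400, end = t0 + 2 * 86400,
                     duration_days = 1, cause = "natural/unknown",
                     censored = FALSE)
    rec <- attendance_records(st, ph, make_meta("T1"), make_refs(),
                              granularity = gran)
    ## rebuild the per-reading typing exactly as documented, then count
    stt <- copy(st)
    stt[, inc_type := fifelse(timestamp_utc >= ph$start &
                                timestamp_utc < ph$end,
                              "uniparental-biparental-species", "biparental")]
    stt[, local_date := as.Date(timestamp_local)]
    stt[, local_hour := as.integer(format(timestamp_local, "%H"))]
    orc <- oracle_attendance(stt, gran)
    expect_equal(nrow(rec), nrow(orc))
    ordcols <- intersect(c("local_date", "local_hour", "inc_type"), names(rec))
    setorderv(rec, ordcols)
    orc <- orc[order(orc$key, orc$inc_type), ]
    expect_equal(rec$attendance, orc$attendance)
    expect_equal(rec$purity, orc$purity)
    expect_equal(rec$n_type, orc$n_type)
    expect_true(all(rec$purity >= 75))
    ## per-window type counts never exceed the window total
    expect_true(all(rec$n_type <= rec$n_total))
  }
})

test_that("nest-level exclusions are honoured", {
  n <- 2 * 1440
  st <- mk_states(rep(TRUE, n), rep("F", n))
  ## single-egg nests are excluded
  rec <- attendance_records(st, NULL, make_meta("T1", eggs_remaining = 1L),
                            make_refs(), granularity = "daily")
  expect_equal(nrow(rec), 0L)
  ## hatch trim removes the readings before hatch_start
  md <- make_meta("T1", hatch_start = t0 + 86400)
  rec2 <- attendance_records(st, NULL, md, make_refs(), granularity = "daily")
  expect_true(all(rec2$local_date < as.Date("2015-06-02")))
  ## dislocated-probe spans are dropped
  ex <- data.table(nest_id = "T1", start = t0, end = t0 + 86400)
  rec3 <- attendance_records(st, NULL, make_meta("T1"), make_refs(),
                             granularity = "daily", exclude_spans = ex)
  expect_false(as.Date("2015-06-01") %in% rec3$local_date)
})

test_that("uniparental-species nests are typed by the reference flag", {
  n <- 1440
  st <- mk_states(rep(TRUE, n), rep("M", n))
  rec <- attendance_records(st, NULL, make_meta("T1", species = "RNPH"),
                            make_refs(species = "RNPH",
                                      flag = "uniparental-male"),
                            granularity = "daily")
  expect_equal(unique(rec$inc_type), "uniparental-uniparental-species")
})
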