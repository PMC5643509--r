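t0 <- utc("2015-06-01 00:00:00")

test_that("the 2x-median rule is applied after removing the first regular bout", {
  ## median 10 h, solo span 40 h -> 30-h phase starting 10 h after onset
  b <- make_bouts("T1", data.frame(
    start_h = c(0, 10.1, 20.2), end_h = c(10, 20.1, 60.2),
    sex = c("F", "M", "F")))
  ## last F run spans 20.2..60.2 h = 40 h
  ph <- detect_uniparental_phases(b, 10)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$sex, "F")
  expect_equal(ph$onset, t0 + 20.2 * 3600)
  expect_equal(ph$start, t0 + 30.2 * 3600)
  expect_equal(as.numeric(ph$end - ph$start, units = "hours"), 30)
  expect_equal(ph$duration_days, 30 / 24)

  ## solo span 25 h -> remainder 15 < 20 -> no phase
  b2 <- make_bouts("T1", data.frame(
    start_h = c(0, 10.1, 20.2), end_h = c(10, 20.1, 45.2),
    sex = c("F", "M", "F")))
  expect_equal(nrow(detect_uniparental_phases(b2, 10)), 0L)

  ## regular alternation to hatching -> no phases at all
  alt <- make_bouts("T1", data.frame(
    start_h = seq(0, 110, by = 11), end_h = seq(11, 121, by = 11),
    sex = rep(c("F", "M"), length.out = 11)))
  expect_equal(nrow(detect_uniparental_phases(alt, 11)), 0L)

  expect_error(detect_uniparental_phases(b, 0), "positive")
})

test_that("hatching exclusion windows trim phases", {
  ## 60-h F solo span starting at 20 h; hatch at 70 h -> trim to 64 h
  b <- make_bouts("T1", data.frame(
    start_h = c(0, 10, 20), end_h = c(10, 20, 80), sex = c("M", "F", "F")))
  ## note: runs are M then F (the F bout at 10 h is the solo run's start)
  md <- make_meta("T1", hatch_start = t0 + 70 * 3600)
  ph <- detect_uniparental_phases(b, 10, metadata = md)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$end, t0 + 64 * 3600)
  ## no phase may overlap the trimmed window
  expect_lte(as.numeric(ph$end), as.numeric(t0 + 70 * 3600 - 6 * 3600))
  ## chicks_found trims 24 h
  md2 <- make_meta("T1", chicks_found = t0 + 80 * 3600)
  ph2 <- detect_uniparental_phases(b, 10, metadata = md2)
  expect_equal(ph2$end, t0 + 56 * 3600)
})

test_that("phase metrics convert to start fraction and days", {
  ph <- data.table(nest_id = "T1", sex = "F",
                   onset = t0, start = t0 + 14.2 * 86400,
                   end = t0 + 17.2 * 86400, duration_days = 3,
                   cause = "natural/unknown", censored = FALSE)
  m <- phase_metrics(ph, setNames(t0, "T1"),
                     list(typical_incubation_period_days = 20, species = "SESA"))
  expect_equal(m$start_fraction, 100 * 14.2 / 20)  # 71%
  ## starts after the typical period are allowed (>100%)
  ph2 <- copy(ph)[, start := t0 + 22 * 86400]
  m2 <- phase_metrics(ph2, setNames(t0, "T1"),
                      list(typical_incubation_period_days = 20))
  expect_equal(m2$start_fraction, 110)
  ## 72-h phase -> 3 days; negative fractions flagged as anomalies
  expect_equal(m$duration_days, 3)
  ph3 <- copy(ph)[, start := t0 - 86400]
  expect_warning(m3 <- phase_metrics(ph3, setNames(t0, "T1"),
                                     list(typical_incubation_period_days = 20)),
                 "before")
  expect_true(m3$anomaly)
})

test_that("cause classification follows removal > capture > temporal > unknown", {
  ph <- data.table(nest_id = "T1", sex = "F", onset = t0 + 8 * 86400,
                   start = t0 + 8 * 86400 + 10 * 3600,
                   end = t0 + 11 * 86400)
  ev_rm <- data.table(nest_id = "T1", timestamp_utc = t0 + 8 * 86400,
                      kind = "removal")
  expect_equal(classify_cause(ph, ev_rm), "experimental-removal")
  ev_cap <- data.table(nest_id = "T1",
                       timestamp_utc = t0 + 8 * 86400 - 6 * 3600,
                       kind = "capture")
  expect_equal(classify_cause(ph, ev_cap), "post-capture")
  ## capture outside the 24-h window does not count
  ev_old <- data.table(nest_id = "T1",
                       timestamp_utc = t0 + 8 * 86400 - 30 * 3600,
                       kind = "capture")
  expect_equal(classify_cause(ph, ev_old), "natural/unknown")
  ## renewed alternation after the phase -> temporal
  b <- make_bouts("T1", data.frame(start_h = 12 * 24, end_h = 12 * 24 + 10,
                                   sex = "M"))
  expect_equal(classify_cause(ph, NULL, b), "temporal")
})

test_that("temporal desertion yields two phases on one nest", {
  ## F solo span, then biparental again, then permanent F solo
  b <- make_bouts("T1", data.frame(
    start_h = c(0, 10, 20, 60, 70, 80, 90, 130),
    end_h   = c(10, 20, 55, 70, 80, 90, 125, 160),
    sex = c("F", "M", "F", "M", "F", "M", "F", "F")))
  ## runs: F(0-10), M(10-20), F(20-55: 35h), M..., F(90-160: 70h)
  ph <- detect_uniparental_phases(b, 10)
  expect_equal(nrow(ph), 2L)
  expect_equal(ph$cause, c("temporal", "natural/unknown"))
  ## phases of one nest never overlap
  expect_true(all(ph$start[-1] >= ph$end[-nrow(ph)]))
})

test_that("injected desertions are recovered with accurate phase starts", {
  sim <- sim_noisefree(n_nests = 8, seed = 31,
                       desertion_day_range = c(6, 12))
  ds <- sim$dataset
  st <- incubation_states(ds$temperature, ds$rfid, ds$tags, ds$metadata,
                          exact_params())
  b <- segment_bouts(st, params = exact_params())
  rec_end <- setNames(sim$truth$nests$recording_end, sim$truth$nests$nest_id)
  ph <- detect_uniparental_phases(b, 11, ds$metadata, ds$events,
                                  recording_end = rec_end)
  qualifying <- sim$truth$nests[deserted == TRUE]
  ## every deserting nest whose solo span is long enough must be found
  for (nid in qualifying$nest_id) {
    span_h <- as.numeric(qualifying[nest_id == nid, solo_end - solo_onset],
                         units = "hours")
    if (span_h >= 3 * 11) {
      hit <- ph[nest_id == nid]
      expect_gte(nrow(hit), 1L)
      ## detected start within one median bout of truth onset + one bout
      truth_start <- qualifying[nest_id == nid, solo_onset] + 11 * 3600
      expect_lte(abs(as.numeric(hit$start[1] - truth_start, units = "hours")),
                 11)
    }
  }
  ## no-desertion noise-free nests yield zero phases
  sim0 <- sim_noisefree(n_nests = 4, seed = 32, desertion_prob = 0)
  st0 <- incubation_states(sim0$dataset$temperature, sim0$dataset$rfid,
                           sim0$dataset$tags, sim0$dataset$metadata,
                           exact_params())
  b0 <- segment_bouts(st0, params = exact_params())
  ph0 <- detect_uniparental_phases(b0, 11, sim0$dataset$metadata)
  expect_equal(nrow(ph0), 0L)
})

test_that("censoring is flagged when recording ends mid-phase", {
  ## recording stops at 60 h during an F solo span
  b <- make_bouts("T1", data.frame(
    start_h = c(0, 10.1, 20.2), end_h = c(10, 20.1, 60), sex = c("F", "M", "F")))
  ph <- detect_uniparental_phases(b, 10,
                                  recording_end = c(T1 = t0 + 60 * 3600))
  expect_true(ph$censored)
  ## with recording extending past the span end, not censored
  ph2 <- detect_uniparental_phases(b, 10,
                                   recording_end = c(T1 = t0 + 100 * 3600))
  expect_false(ph2$censored)
})
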