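## Fixtures are built in code; nothing binary ships with the tests.
library(data.table)

utc <- function(x) as.POSIXct(x, tz = "UTC")

## a minimal valid metadata row
make_meta <- function(nest_id = "T1", species = "SESA", population = "barrow",
                      longitude = 0, latitude = 70, ...) {
  dots <- list(...)
  base <- data.table(nest_id = nest_id, species = species,
                     population = population, latitude = latitude,
                     longitude = longitude, clutch_size = 4L,
                     first_egg_date = as.Date(NA),
                     hatch_start = utc(NA), chicks_found = utc(NA),
                     flotation_date = as.Date(NA),
                     flotation_stage = NA_character_,
                     incubation_start = utc("2015-06-01 00:00:00"),
                     outcome = "unknown", eggs_remaining = 4L)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

make_refs <- function(species = "SESA", population = "barrow",
                      period = 20, median_bout = 11,
                      flag = "biparental") {
  data.table(species = species, population = population,
             typical_incubation_period_days = period,
             median_bout_h = median_bout, uniparental_flag = flag)
}

## square-wave trace: alternating attended (temp_hi) and bare
## (exponential decay toward ambient) blocks, noise-free
make_square_trace <- function(nest_id = "T1", n_cycles = 4,
                              on_min = 120, off_min = 60, dt_s = 60,
                              temp_hi = 35, ambient = 5, tau_min = 20,
                              t0 = utc("2015-06-01 00:00:00")) {
  on_n <- on_min * 60 / dt_s; off_n <- off_min * 60 / dt_s
  inc <- rep(rep(c(TRUE, FALSE), n_cycles), times = rep(c(on_n, off_n), n_cycles))
  n <- length(inc)
  times <- t0 + (seq_len(n) - 1) * dt_s
  temp <- numeric(n); cur <- ambient
  for (i in seq_len(n)) {
    temp[i] <- cur
    target <- if (inc[i]) temp_hi else ambient
    tau <- if (inc[i]) 5 else tau_min
    cur <- target + (cur - target) * exp(-dt_s / 60 / tau)
  }
  list(trace = data.table(nest_id = nest_id, timestamp_utc = times,
                          nest_temp_c = temp, surface_temp_c = ambient),
       truth = data.table(timestamp_utc = times, incubated = inc))
}

## hand-built bout table for phase-rule tests (hours from origin)
make_bouts <- function(nest_id, spec, t0 = utc("2015-06-01 00:00:00")) {
  ## spec: data.frame(start_h, end_h, sex)
  data.table(nest_id = nest_id,
             start = t0 + spec$start_h * 3600,
             end = t0 + spec$end_h * 3600,
             attending = spec$sex,
             length_h = spec$end_h - spec$start_h,
             n_readings = as.integer((spec$end_h - spec$start_h) * 60))
}

## brute-force attendance oracle: plain loops over readings
oracle_attendance <- function(st, granularity, min_purity = 75) {
  st <- as.data.frame(st)
  key <- if (granularity == "daily")
    paste(st$nest_id, st$local_date)
  else paste(st$nest_id, st$local_date, sprintf("%02d", st$local_hour))
  out <- list()
  for (k in unique(key)) {
    rows <- st[key == k, ]
    for (ty in unique(rows$inc_type)) {
      sub <- rows[rows$inc_type == ty, ]
      purity <- 100 * nrow(sub) / nrow(rows)
      if (purity >= min_purity) {
        out[[length(out) + 1]] <- data.frame(
          key = k, inc_type = ty,
          attendance = 100 * sum(sub$incubated) / nrow(sub),
          purity = purity, n_type = nrow(sub), n_total = nrow(rows))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## small noise-free deserting population used by several files
sim_noisefree <- function(n_nests = 3, seed = 42, desertion_prob = 1,
                          dt_s = 120, ...) {
  cfg <- sim_config(n_nests = n_nests, sampling_interval_s = dt_s,
                    desertion_prob = desertion_prob,
                    ambient_noise_sd = 0, incubated_noise_sd = 0,
                    detection_prob = 1, seed = seed, ...)
  generate_dataset(cfg)
}

exact_params <- function() extraction_params(smooth_window_min = 0,
                                             recess_tolerance_min = 0.5)
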