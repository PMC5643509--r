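## Synthetic nest-monitoring data with a ground-truth ledger.
##
## The generator emulates the phenomenology of continuous shorebird
## incubation records: two parents alternating log-normal incubation
## bouts around the population median; a diel ambient temperature cycle;
## nest temperature held near incubation temperature while a parent
## sits and relaxing exponentially toward ambient when the nest is bare;
## RFID detections only while the tagged parent attends; desertion of
## one parent followed by a solo phase in which the remaining bird keeps
## a uniparental-like rhythm (continuous attendance in the cold night
## hours, recesses concentrated in the warm part of the day).

#' Simulation configuration
#'
#' Defaults describe an arctic biparental sandpiper population: a 20-day
#' incubation period, 11-h median bouts, 5-s sampling, a 5/7 degC diel
#' ambient cycle, 35 degC incubated nest temperature, 20-min cooling
#' time constant and a mostly-female desertion process (females desert
#' in 80% of cases) with a median 3-day solo phase.
#'
#' @param n_nests number of nests to simulate
#' @param species,population species and population codes
#' @param latitude,longitude nest site (degrees); default Barrow, Alaska
#' @param typical_incubation_period_days species incubation period
#' @param median_bout_h population median incubation bout (hours)
#' @param bout_log_sd log-sd of log-normal bout lengths
#' @param exchange_gap_min off-nest gap at a change-over (minutes)
#' @param base_off_frac,day_recess_rate solo rhythm: off-fraction of an
#'   hour is `base_off_frac + day_recess_rate * warmth(hour)` with
#'   warmth 0 at the coldest hour and 1 twelve hours later
#' @param desertion_prob probability a nest loses one parent
#' @param desertion_day_range uniform range (days since incubation
#'   start) for the targeted desertion day
#' @param desert_female_prob probability the deserting parent is female
#' @param desertion_cause one of `"natural"`, `"capture"`, `"removal"`;
#'   capture/removal inject the corresponding metadata event
#' @param solo_days_median,solo_days_log_sd log-normal solo-phase length
#' @param ambient_mean,ambient_amplitude,ambient_noise_sd,coldest_hour
#'   diel ambient temperature model (degC; coldest local hour)
#' @param incubated_temp,incubated_noise_sd nest temperature while
#'   attended (degC)
#' @param cooling_tau_min,warming_tau_min exponential relaxation time
#'   constants (minutes) toward ambient / incubated temperature
#' @param sampling_interval_s logger cadence (seconds; nominal 5)
#' @param detection_prob per-reading RFID detection probability while
#'   the tagged parent attends
#' @param clutch_size eggs per clutch (usually 4, rarely 3)
#' @param post_desertion_days extra recording after full desertion
#' @param uniparental_species simulate an obligate uniparental species
#'   (single parent, solo rhythm from day one)
#' @param uniparental_sex attending sex for a uniparental species
#' @param start_time incubation start of the first nest (POSIXct UTC)
#' @param start_jitter_days uniform stagger of nest start dates
#' @param seed master RNG seed
#' @return a list of class `unicub_sim_config`
#' @export
sim_config <- function(n_nests = 8L,
                       species = "SESA", population = "barrow",
                       latitude = 71.32, longitude = -156.65,
                       typical_incubation_period_days = 20,
                       median_bout_h = 11, bout_log_sd = 0.25,
                       exchange_gap_min = 5,
                       base_off_frac = 0.02, day_recess_rate = 0.4,
                       desertion_prob = 0.5,
                       desertion_day_range = c(5, 15),
                       desert_female_prob = 0.8,
                       desertion_cause = "natural",
                       solo_days_median = 3, solo_days_log_sd = 0.7,
                       ambient_mean = 5, ambient_amplitude = 7,
                       ambient_noise_sd = 1.5, coldest_hour = 2,
                       incubated_temp = 35, incubated_noise_sd = 0.8,
                       cooling_tau_min = 20, warming_tau_min = 5,
                       sampling_interval_s = 5,
                       detection_prob = 0.9,
                       clutch_size = 4L,
                       post_desertion_days = 1,
                       uniparental_species = FALSE,
                       uniparental_sex = "M",
                       start_time = as.POSIXct("2015-06-01 00:00:00", tz = "UTC"),
                       start_jitter_days = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_nests < 1) stop("n_nests must be positive")
  stopifnot(cfg$typical_incubation_period_days > 0, cfg$median_bout_h > 0,
            cfg$sampling_interval_s > 0,
            cfg$desertion_prob >= 0, cfg$desertion_prob <= 1,
            cfg$desert_female_prob >= 0, cfg$desert_female_prob <= 1,
            cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            cfg$desertion_cause %in% c("natural", "capture", "removal"))
  class(cfg) <- "unicub_sim_config"
  cfg
}

#' Diel ambient temperature
#'
#' A 24-h sinusoid: `mean - amplitude * cos(2*pi*(h - coldest_hour)/24)`
#' plus optional Gaussian noise; minimum at `coldest_hour`, maximum 12 h
#' later.
#'
#' @param local_hour hour of local solar day, possibly fractional
#' @param mean,amplitude,coldest_hour sinusoid parameters (degC, hours)
#' @param noise_sd Gaussian noise sd (0 = deterministic)
#' @return numeric degC, same length as `local_hour`
#' @export
ambient_temperature <- function(local_hour, mean = 5, amplitude = 7,
                                coldest_hour = 2, noise_sd = 0) {
  stopifnot(is.finite(mean), is.finite(amplitude), amplitude >= 0)
  base <- mean - amplitude * cos(2 * pi * (local_hour - coldest_hour) / 24)
  if (noise_sd > 0) base <- base + rnorm(length(base), 0, noise_sd)
  base
}

## Hour-by-hour solo attendance: returns data.table(start, end) of
## attended intervals within [onset, solo_end], boundaries on the grid.
.solo_attended_intervals <- function(onset, solo_end, cfg, origin) {
  dt_s <- cfg$sampling_interval_s
  if (solo_end <= onset) return(data.table(start = as.POSIXct(character(), tz = "UTC"),
                                           end = as.POSIXct(character(), tz = "UTC")))
  hour0 <- as.numeric(onset, units = "secs") %/% 3600 * 3600
  hours <- seq(hour0, as.numeric(solo_end, units = "secs"), by = 3600)
  off <- vector("list", length(hours))
  for (k in seq_along(hours)) {
    hstart <- as.POSIXct(hours[k], origin = "1970-01-01", tz = "UTC")
    lh <- (as.numeric(local_solar_time(hstart, cfg$longitude), units = "secs") / 3600) %% 24
    warmth <- (1 - cos(2 * pi * (lh - cfg$coldest_hour) / 24)) / 2
    f <- min(0.95, max(0, cfg$base_off_frac + cfg$day_recess_rate * warmth))
    len <- round(f * 3600 / dt_s) * dt_s
    if (len <= 0) next
    pos <- floor(runif(1) * (3600 - len) / dt_s) * dt_s
    off[[k]] <- c(hours[k] + pos, hours[k] + pos + len)
  }
  off <- off[!vapply(off, is.null, TRUE)]
  offm <- if (length(off)) do.call(rbind, off) else matrix(numeric(0), ncol = 2)
  ## complement within [onset, solo_end]
  lo <- as.numeric(onset, units = "secs"); hi <- as.numeric(solo_end, units = "secs")
  starts <- c(lo, pmin(pmax(offm[, 2], lo), hi))
  ends <- c(pmin(pmax(offm[, 1], lo), hi), hi)
  keep <- ends > starts
  out <- data.table(start = starts[keep], end = ends[keep])
  setorder(out, start)
  out[, `:=`(start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
             end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC"))]
  out
}

#' Simulate one nest
#'
#' Single-nest version of [generate_dataset()]: builds the attendance
#' schedule (biparental alternation, optional desertion with a solo
#' phase, or an obligate-uniparental rhythm), derives nest/surface
#' temperatures by exponential relaxation between the incubated
#' temperature and the diel ambient curve, and emits RFID detections
#' while the tagged parent attends.
#'
#' @param cfg a [sim_config()]
#' @param nest_id nest identifier
#' @param seed RNG seed for this nest
#' @return list with elements `temperature`, `rfid`, `metadata`,
#'   `events`, `tags` (interchange tables) and `truth` (list:
#'   `attending` per reading, `bouts`, `nest` ledger row)
#' @export
simulate_nest <- function(cfg, nest_id = "N001", seed = cfg$seed) {
  stopifnot(inherits(cfg, "unicub_sim_config"))
  set.seed(seed)
  dt_s <- cfg$sampling_interval_s
  t0 <- snap_to_grid(cfg$start_time +
                       runif(1, 0, cfg$start_jitter_days) * 86400,
                     cfg$start_time, dt_s)
  hatch_time <- t0 + cfg$typical_incubation_period_days * 86400

  deserts <- !cfg$uniparental_species && runif(1) < cfg$desertion_prob
  desert_sex <- if (runif(1) < cfg$desert_female_prob) "F" else "M"
  desert_target <- t0 + runif(1, cfg$desertion_day_range[1],
                              cfg$desertion_day_range[2]) * 86400

  gap_s <- round(cfg$exchange_gap_min * 60 / dt_s) * dt_s
  bouts <- list()          # true attendance intervals (start, end, sex)
  desertion_time <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  solo_onset <- desertion_time
  outcome <- "hatched"

  if (cfg$uniparental_species) {
    solo_sex <- cfg$uniparental_sex
    solo_onset <- t0
    solo_end <- hatch_time
    sol <- .solo_attended_intervals(t0, solo_end, cfg, t0)
    if (nrow(sol)) bouts <- c(bouts, split(sol, seq_len(nrow(sol))))
    sexes_present <- solo_sex
    rec_end <- hatch_time
  } else {
    cur_sex <- sample(c("F", "M"), 1)
    t <- t0
    repeat {
      len <- round(rlnorm(1, log(cfg$median_bout_h), cfg$bout_log_sd) *
                     3600 / dt_s) * dt_s
      len <- max(len, dt_s)
      b_end <- t + len
      if (deserts && cur_sex == desert_sex && b_end >= desert_target) {
        ## deserting parent's final bout; partner takes over afterwards
        b_end <- min(b_end, hatch_time)
        bouts[[length(bouts) + 1]] <- data.table(start = t, end = b_end, sex = cur_sex)
        desertion_time <- b_end
        break
      }
      if (b_end >= hatch_time) {
        bouts[[length(bouts) + 1]] <- data.table(start = t, end = hatch_time, sex = cur_sex)
        break
      }
      bouts[[length(bouts) + 1]] <- data.table(start = t, end = b_end, sex = cur_sex)
      t <- b_end + gap_s
      cur_sex <- if (cur_sex == "F") "M" else "F"
    }
    sexes_present <- c("F", "M")
    rec_end <- hatch_time
    solo_sex <- if (desert_sex == "F") "M" else "F"
    if (deserts && !is.na(desertion_time) && desertion_time < hatch_time) {
      solo_onset <- desertion_time + gap_s
      solo_days <- rlnorm(1, log(cfg$solo_days_median), cfg$solo_days_log_sd)
      solo_end <- solo_onset + round(solo_days * 86400 / dt_s) * dt_s
      if (solo_end >= hatch_time) {
        solo_end <- hatch_time
        outcome <- "hatched"
        rec_end <- hatch_time
      } else {
        outcome <- "deserted"
        rec_end <- solo_end + cfg$post_desertion_days * 86400
      }
      sol <- .solo_attended_intervals(solo_onset, solo_end, cfg, t0)
      if (nrow(sol)) {
        sol[, sex := solo_sex]
        bouts <- c(bouts, split(sol, seq_len(nrow(sol))))
      }
    }
  }
  ivl <- rbindlist(bouts, use.names = TRUE, fill = TRUE)
  if (!"sex" %in% names(ivl)) ivl[, sex := cfg$uniparental_sex]
  ivl[is.na(sex), sex := solo_sex]
  setorder(ivl, start)
  ivl[, `:=`(start = snap_to_grid(start, t0, dt_s),
             end = snap_to_grid(end, t0, dt_s))]
  ivl <- ivl[end > start]

  ## reading grid
  times <- seq(t0, rec_end, by = dt_s)
  n <- length(times)
  attending <- rep("none", n)
  idx0 <- as.numeric(times[1], units = "secs")
  for (i in seq_len(nrow(ivl))) {
    a <- floor((as.numeric(ivl$start[i], units = "secs") - idx0) / dt_s) + 1
    b <- ceiling((as.numeric(ivl$end[i], units = "secs") - idx0) / dt_s)
    a <- max(1L, a); b <- min(n, b)
    if (b >= a) attending[a:b] <- ivl$sex[i]
  }

  ## temperatures: analytic relaxation within constant-state runs
  lh <- (as.numeric(local_solar_time(times, cfg$longitude), units = "secs") / 3600) %% 24
  amb <- ambient_temperature(lh, cfg$ambient_mean, cfg$ambient_amplitude,
                             cfg$coldest_hour, 0)
  on <- attending != "none"
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  temp <- numeric(n)
  t_cur <- amb[1]
  for (k in seq_along(r$lengths)) {
    s <- starts[k]; e <- ends[k]
    el <- (seq(s, e) - s) * dt_s / 60   # minutes
    if (r$values[k]) {
      temp[s:e] <- cfg$incubated_temp +
        (t_cur - cfg$incubated_temp) * exp(-el / cfg$warming_tau_min)
      t_cur <- cfg$incubated_temp + (t_cur - cfg$incubated_temp) *
        exp(-(e - s + 1) * dt_s / 60 / cfg$warming_tau_min)
    } else {
      d0 <- t_cur - amb[s]
      temp[s:e] <- amb[s:e] + d0 * exp(-el / cfg$cooling_tau_min)
      t_cur <- amb[min(e + 1, n)] + d0 *
        exp(-(e - s + 1) * dt_s / 60 / cfg$cooling_tau_min)
    }
  }
  nest_noise <- ifelse(on, cfg$incubated_noise_sd, cfg$ambient_noise_sd)
  if (any(nest_noise > 0)) temp <- temp + rnorm(n, 0, nest_noise)
  surface <- amb + if (cfg$ambient_noise_sd > 0)
    rnorm(n, 0, cfg$ambient_noise_sd) else 0

  temperature <- data.table(nest_id = nest_id, timestamp_utc = times,
                            nest_temp_c = temp, surface_temp_c = surface)

  tagF <- paste0(nest_id, "_F"); tagM <- paste0(nest_id, "_M")
  det <- on & (runif(n) < cfg$detection_prob)
  rfid <- data.table(nest_id = nest_id, timestamp_utc = times[det],
                     tag_id = ifelse(attending[det] == "F", tagF, tagM))
  tags <- data.table(nest_id = nest_id, tag_id = c(tagF, tagM),
                     sex = c("F", "M"))
  if (length(sexes_present) == 1)
    tags <- tags[sex %in% sexes_present]

  hatched <- outcome == "hatched"
  metadata <- data.table(
    nest_id = nest_id, species = cfg$species, population = cfg$population,
    latitude = cfg$latitude, longitude = cfg$longitude,
    clutch_size = as.integer(cfg$clutch_size),
    first_egg_date = as.Date(t0) - (cfg$clutch_size - 1L),
    hatch_start = if (hatched) hatch_time else as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
    chicks_found = if (hatched) hatch_time + 12 * 3600 else as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
    flotation_date = as.Date(NA), flotation_stage = NA_character_,
    incubation_start = t0, outcome = outcome,
    eggs_remaining = as.integer(cfg$clutch_size))

  events <- data.table(nest_id = character(), timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                       kind = character())
  if (deserts && !is.na(desertion_time)) {
    if (cfg$desertion_cause == "capture")
      events <- data.table(nest_id = nest_id,
                           timestamp_utc = desertion_time - 6 * 3600,
                           kind = "capture")
    if (cfg$desertion_cause == "removal")
      events <- data.table(nest_id = nest_id, timestamp_utc = desertion_time,
                           kind = "removal")
  }

  truth_bouts <- copy(ivl)[, nest_id := nest_id]
  setcolorder(truth_bouts, c("nest_id", "start", "end", "sex"))
  truth_nest <- data.table(
    nest_id = nest_id,
    deserted = deserts && !is.na(desertion_time),
    desertion_time = desertion_time,
    deserting_sex = if (deserts) desert_sex else NA_character_,
    solo_sex = if (deserts || cfg$uniparental_species) solo_sex else NA_character_,
    solo_onset = solo_onset,
    solo_end = if (deserts || cfg$uniparental_species) solo_end else as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
    hatch_time = if (hatched) hatch_time else as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
    outcome = outcome, recording_end = rec_end)

  list(temperature = temperature, rfid = rfid, metadata = metadata,
       events = events, tags = tags,
       truth = list(
         attending = data.table(nest_id = nest_id, timestamp_utc = times,
                                attending = attending),
         bouts = truth_bouts, nest = truth_nest))
}

#' Generate a multi-nest dataset with ground truth
#'
#' Runs [simulate_nest()] for `cfg$n_nests` nests with per-nest seeds
#' derived deterministically from `cfg$seed`, and assembles a
#' [unicub_dataset()] plus a truth ledger.
#'
#' @param cfg a [sim_config()]
#' @param nest_prefix prefix for generated nest ids
#' @return list with `dataset` (a `unicub_dataset`) and `truth`
#'   (list of data.tables `attending`, `bouts`, `nests`)
#' @export
generate_dataset <- function(cfg, nest_prefix = "N") {
  stopifnot(inherits(cfg, "unicub_sim_config"))
  sims <- vector("list", cfg$n_nests)
  for (i in seq_len(cfg$n_nests)) {
    nid <- sprintf("%s%03d", nest_prefix, i)
    sims[[i]] <- simulate_nest(cfg, nest_id = nid,
                               seed = derive_seed(cfg$seed, i))
  }
  cat_tab <- function(nm) rbindlist(lapply(sims, `[[`, nm), use.names = TRUE)
  references <- data.table(
    species = cfg$species, population = cfg$population,
    typical_incubation_period_days = cfg$typical_incubation_period_days,
    median_bout_h = cfg$median_bout_h,
    uniparental_flag = if (cfg$uniparental_species)
      paste0("uniparental-", if (cfg$uniparental_sex == "M") "male" else "female")
    else "biparental")
  ds <- unicub_dataset(temperature = cat_tab("temperature"),
                       rfid = cat_tab("rfid"), metadata = cat_tab("metadata"),
                       events = cat_tab("events"), tags = cat_tab("tags"),
                       references = references, validate = FALSE)
  truth <- list(
    attending = rbindlist(lapply(sims, function(s) s$truth$attending)),
    bouts = rbindlist(lapply(sims, function(s) s$truth$bouts)),
    nests = rbindlist(lapply(sims, function(s) s$truth$nest)))
  list(dataset = ds, truth = truth)
}
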