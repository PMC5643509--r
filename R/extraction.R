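## Extraction of incubation behaviour from raw traces.
##
## Incubation is read off the thermal signature: constant nest
## temperatures above the surrounding surface temperature mean a sitting
## parent; steep temperature rises/drops mark arrivals/departures.
## All downstream daily statistics use local solar time,
## UTC + longitude * 24/360 hours.

#' Default extraction parameters
#'
#' @param margin_c nest must exceed the surface baseline by at least
#'   this much (degC) to count as incubated
#' @param surface_window_min rolling-median window (minutes) for the
#'   surface baseline
#' @param smooth_window_min rolling-mean window (minutes) applied to the
#'   nest temperature before slopes are computed; 0 disables smoothing
#' @param steep_slope_c_min onset/offset slope threshold (degC/min);
#'   `Inf` disables the slope rules (margin-only mode, a pure
#'   per-reading threshold)
#' @param recess_tolerance_min off-gaps shorter than this do not split a
#'   bout (minutes)
#' @param rfid_window_min a reading takes the sex of the nearest RFID
#'   detection within this window (minutes)
#' @return list of class `unicub_extraction_params`
#' @export
extraction_params <- function(margin_c = 3, surface_window_min = 10,
                              smooth_window_min = 5,
                              steep_slope_c_min = 0.5,
                              recess_tolerance_min = 60,
                              rfid_window_min = 2) {
  p <- as.list(environment())
  stopifnot(p$margin_c > 0, p$surface_window_min >= 0,
            p$smooth_window_min >= 0, p$steep_slope_c_min > 0,
            p$recess_tolerance_min >= 0, p$rfid_window_min >= 0)
  class(p) <- "unicub_extraction_params"
  p
}

#' Local solar time
#'
#' Shifts UTC by `longitude * 24/360` hours (240 s per degree east).
#' The result is a POSIXct whose clock value reads local solar time
#' (kept in the UTC timezone for arithmetic convenience).
#'
#' @param timestamp_utc POSIXct (UTC)
#' @param longitude decimal degrees in \[-180, 180\]
#' @return POSIXct shifted by the longitudinal offset
#' @export
local_solar_time <- function(timestamp_utc, longitude) {
  if (any(!is.finite(longitude)) || any(longitude < -180 | longitude > 180))
    stop("longitude must lie in [-180, 180]")
  timestamp_utc + longitude * 240
}

## centered rolling mean over k readings (k odd), edges fall back to raw
.roll_mean <- function(x, k) {
  if (k <= 1) return(x)
  s <- frollmean(x, n = k, align = "center", na.rm = TRUE)
  s[is.na(s)] <- x[is.na(s)]
  s
}

.odd_window <- function(minutes, dt_s) {
  k <- max(1L, round(minutes * 60 / dt_s))
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

#' Classify each reading as incubated or not
#'
#' Baseline rule: a reading is incubated when nest temperature exceeds a
#' rolling-median surface baseline by at least `margin_c`. With
#' `steep_slope_c_min` finite a hysteresis refinement is applied so the
#' exponential cooling tail after a departure (which can stay above the
#' margin for tens of minutes) is not classified as incubation: the
#' state switches off on a steep negative smoothed slope or a margin
#' failure, and switches on on a steep positive slope (an arrival warms
#' the nest quickly) or on margin with a non-negative slope. With
#' `steep_slope_c_min = Inf` the classification is exactly the
#' per-reading margin threshold. Classification is idempotent: it
#' depends only on the trace and parameters.
#'
#' @param trace temperature table (`nest_id`, `timestamp_utc`,
#'   `nest_temp_c`, `surface_temp_c`) for one or more nests
#' @param params an [extraction_params()]
#' @return data.table: `nest_id`, `timestamp_utc`, `incubated` (logical)
#' @export
classify_incubation <- function(trace, params = extraction_params()) {
  trace <- as.data.table(trace)
  if (!nrow(trace)) stop("empty trace")
  if (all(is.na(trace$nest_temp_c))) stop("unusable trace: all nest temperatures missing")
  out <- trace[, {
    tt <- as.numeric(timestamp_utc)
    dt_s <- if (length(tt) > 1) median(diff(tt)) else 5
    kS <- .odd_window(params$surface_window_min, dt_s)
    surf <- surface_temp_c
    surf[is.na(surf)] <- median(surf, na.rm = TRUE)
    base <- if (kS > 1 && length(surf) > kS) runmed(surf, kS) else surf
    margin_ok <- !is.na(nest_temp_c) & (nest_temp_c - base >= params$margin_c)
    if (is.infinite(params$steep_slope_c_min)) {
      inc <- margin_ok
    } else {
      kN <- .odd_window(params$smooth_window_min, dt_s)
      sm <- .roll_mean(nest_temp_c, kN)
      n <- length(sm)
      slope <- c(diff(sm), NA) / (dt_s / 60)   # degC per minute, forward
      slope[n] <- slope[max(1, n - 1)]
      slope[is.na(slope)] <- 0
      on_trig <- slope >= params$steep_slope_c_min |
        (margin_ok & slope >= 0)
      off_trig <- (slope <= -params$steep_slope_c_min | !margin_ok) & !on_trig
      ev <- integer(n)
      ev[off_trig] <- -1L
      ev[on_trig] <- 1L
      idx <- which(ev != 0L)
      if (!length(idx)) {
        inc <- rep(margin_ok[1], n)
      } else {
        pos <- findInterval(seq_len(n), idx)
        state <- c(ifelse(margin_ok[1], 1L, -1L), ev[idx])[pos + 1L]
        inc <- state == 1L
      }
    }
    list(timestamp_utc = timestamp_utc, incubated = inc)
  }, by = nest_id]
  out[]
}

## per-reading sex from RFID: nearest detection within the window
.assign_reading_sex <- function(states, rfid, tags, window_min) {
  states <- copy(states)
  states[, sex := NA_character_]
  if (!nrow(rfid)) return(states)
  rf <- as.data.table(rfid)
  if (nrow(tags)) {
    rf <- merge(rf, as.data.table(tags)[, .(nest_id, tag_id, sex)],
                by = c("nest_id", "tag_id"), all.x = TRUE)
  } else rf[, sex := NA_character_]
  rf <- rf[!is.na(sex)][, .(nest_id, tag_time = timestamp_utc, sex)]
  if (!nrow(rf)) return(states)
  setkey(rf, nest_id, tag_time)
  qry <- states[, .(nest_id, tag_time = timestamp_utc)]
  setkey(qry, nest_id, tag_time)
  ## two-sided roll join: index of last detection <= t and first >= t
  fwd2 <- rf[qry, roll = Inf, which = TRUE]
  bwd2 <- rf[qry, roll = -Inf, which = TRUE]
  tq <- as.numeric(qry$tag_time)
  dF <- ifelse(is.na(fwd2), Inf, tq - as.numeric(rf$tag_time[fwd2]))
  dB <- ifelse(is.na(bwd2), Inf, as.numeric(rf$tag_time[bwd2]) - tq)
  use_f <- dF <= dB
  best_idx <- ifelse(use_f, fwd2, bwd2)
  best_d <- pmin(dF, dB)
  sexv <- rep(NA_character_, nrow(qry))
  ok <- is.finite(best_d) & best_d <= window_min * 60
  sexv[ok] <- rf$sex[best_idx[ok]]
  ## map back to states order (qry was re-keyed/sorted)
  res <- qry[, .(nest_id, timestamp_utc = tag_time)]
  res[, sex := sexv]
  out <- merge(states[, -"sex"], res, by = c("nest_id", "timestamp_utc"),
               sort = FALSE)
  out
}

#' Full incubation state series with attendance labels
#'
#' Combines [classify_incubation()] with RFID-based parent attribution:
#' an incubated reading takes the sex of the nearest detection within
#' `rfid_window_min`, `"unknown"` when none is near; readings not
#' incubated are `"none"`. Adds local solar timestamps when nest
#' longitudes are supplied.
#'
#' @param trace temperature table
#' @param rfid RFID table (may be empty)
#' @param tags tag-to-sex table (`nest_id`, `tag_id`, `sex`)
#' @param metadata nest metadata (for longitude); optional
#' @param params an [extraction_params()]
#' @return data.table: `nest_id`, `timestamp_utc`, `timestamp_local`,
#'   `incubated`, `attending` in F/M/unknown/none
#' @export
incubation_states <- function(trace, rfid = NULL, tags = NULL,
                              metadata = NULL,
                              params = extraction_params()) {
  st <- classify_incubation(trace, params)
  rfid <- if (is.null(rfid)) data.table() else as.data.table(rfid)
  tags <- if (is.null(tags)) data.table() else as.data.table(tags)
  st <- .assign_reading_sex(st, rfid, tags, params$rfid_window_min)
  st[, attending := fifelse(!incubated, "none",
                            fifelse(is.na(sex), "unknown", sex))]
  st[, sex := NULL]
  if (!is.null(metadata) && nrow(metadata)) {
    md <- as.data.table(metadata)[, .(nest_id, longitude)]
    st <- merge(st, md, by = "nest_id", sort = FALSE)
    st[, timestamp_local := local_solar_time(timestamp_utc, longitude)]
    st[, longitude := NULL]
  } else st[, timestamp_local := timestamp_utc]
  setcolorder(st, c("nest_id", "timestamp_utc", "timestamp_local",
                    "incubated", "attending"))
  st[]
}

#' Segment classified states into parent-labelled bouts
#'
#' Maximal incubated intervals become bouts; internal off-gaps shorter
#' than `recess_tolerance_min` are merged when the attending parent on
#' both sides is compatible. A change of RFID-attributed parent always
#' splits a bout (a clean F-to-M change-over yields two bouts even with
#' no off-gap). The bout's attending parent is the tag with the majority
#' of detections inside it; ties go to the earlier-detected tag; bouts
#' without detections are `"unknown"`. A bout's `end` is the time of its
#' last reading plus one sampling interval, so `length_h = end - start`.
#'
#' @param states output of [incubation_states()] (or of
#'   [classify_incubation()] plus an RFID join)
#' @param rfid RFID detections (used for majority labelling)
#' @param tags tag-to-sex table
#' @param params an [extraction_params()]
#' @return data.table: `nest_id`, `start`, `end`, `attending`,
#'   `length_h`, `n_readings`
#' @export
segment_bouts <- function(states, rfid = NULL, tags = NULL,
                          params = extraction_params()) {
  states <- as.data.table(states)
  if (!"attending" %in% names(states)) {
    states <- .assign_reading_sex(states,
                                  if (is.null(rfid)) data.table() else rfid,
                                  if (is.null(tags)) data.table() else tags,
                                  params$rfid_window_min)
    states[, attending := fifelse(!incubated, "none",
                                  fifelse(is.na(sex), "unknown", sex))]
  }
  out <- states[, {
    tt <- as.numeric(timestamp_utc)
    n <- length(tt)
    dt_s <- if (n > 1) median(diff(tt)) else 5
    inc <- incubated
    ## merge sub-tolerance off-gaps
    r <- rle(inc)
    if (length(r$lengths) > 2) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (!r$values[k] && k > 1 && k < length(r$lengths) &&
            r$lengths[k] * dt_s < params$recess_tolerance_min * 60) {
          sl <- attending[ends[k - 1]]; sr <- attending[starts[k + 1]]
          if (sl == sr || sl == "unknown" || sr == "unknown")
            inc[starts[k]:ends[k]] <- TRUE
        }
      }
    }
    ## carry parent label through merged gaps / unknown readings;
    ## non-incubated readings act as barriers (their label is NA, so a
    ## gap resets the carried label)
    sexv <- fifelse(attending %in% c("F", "M"), attending, NA_character_)
    pos <- seq_len(n)
    known <- !is.na(sexv) | !inc
    lastk <- cummax(fifelse(known, pos, 0L))
    filled <- fifelse(lastk > 0L, sexv[pmax(lastk, 1L)], NA_character_)
    ## backward pass for leading unlabelled readings of a bout
    lastk_rev <- cummax(fifelse(rev(known), pos, 0L))  # reversed coords
    nextk <- fifelse(rev(lastk_rev) > 0L, n + 1L - rev(lastk_rev), 0L)
    bwd <- fifelse(nextk > 0L, sexv[pmax(nextk, 1L)], NA_character_)
    filled <- fifelse(is.na(filled), bwd, filled)
    seg <- paste0(inc, ".", fifelse(is.na(filled), "u", filled))
    sid <- rleid(seg)
    list(timestamp_utc = timestamp_utc, state_id = sid, inc = inc,
         sex = sexv, dt_s = dt_s)
  }, by = nest_id]

  bouts <- out[inc == TRUE,
               .(start = min(timestamp_utc),
                 end = max(timestamp_utc) + dt_s[1],
                 n_readings = .N,
                 nF = sum(sex == "F", na.rm = TRUE),
                 nM = sum(sex == "M", na.rm = TRUE),
                 first_sex = { s <- sex[!is.na(sex)]
                               if (length(s)) s[1] else NA_character_ }),
               by = .(nest_id, state_id)]
  if (!nrow(bouts)) {
    return(data.table(nest_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      attending = character(), length_h = numeric(),
                      n_readings = integer()))
  }
  setorder(bouts, nest_id, start)
  ## majority labelling from RFID-attributed readings; ties go to the
  ## earlier-detected tag
  bouts[, attending := fifelse(nF + nM == 0L, "unknown",
                        fifelse(nF > nM, "F",
                         fifelse(nM > nF, "M", first_sex)))]
  bouts[, length_h := as.numeric(end - start, units = "hours")]
  bouts[, c("state_id", "nF", "nM", "first_sex") := NULL]
  setcolorder(bouts, c("nest_id", "start", "end", "attending",
                       "length_h", "n_readings"))
  bouts[]
}

#' Population median incubation bout
#'
#' Sample median of bout lengths in hours (even counts give the
#' midpoint of the central pair).
#'
#' @param bouts a bout table from [segment_bouts()] or numeric hours
#' @return numeric hours
#' @export
population_median_bout <- function(bouts) {
  x <- if (is.numeric(bouts)) bouts else as.data.table(bouts)$length_h
  if (!length(x)) stop("no bouts: cannot compute a median bout length")
  median(x)
}

#' Estimate the start of incubation for a nest
#'
#' Pathways, in order of precedence:
#' 1. a directly observed `incubation_start` in the metadata;
#' 2. laying rule: `first_egg_date + (clutch_size - 1)` days (one egg
#'    per day, incubation from clutch completion), taken at local
#'    midnight UTC;
#' 3. `hatch_start` minus the species' typical incubation period;
#' 4. egg flotation: observation date minus a configurable
#'    stage-to-elapsed-days lookup;
#' 5. the median incubation start of other nests of the same
#'    population (supplied by the caller).
#'
#' @param meta one-row nest metadata (list or data.table row)
#' @param ref one-row species reference (needs
#'   `typical_incubation_period_days`)
#' @param flotation_lookup named numeric: stage code to elapsed days
#' @param population_starts POSIXct vector of other nests' starts for
#'   the fallback pathway
#' @return POSIXct (UTC) plus attribute `method`
#' @export
estimate_incubation_start <- function(meta, ref = NULL,
                                      flotation_lookup = NULL,
                                      population_starts = NULL) {
  meta <- as.list(as.data.table(as.list(meta))[1])
  done <- function(x, how) { attr(x, "method") <- how; x }
  if (!is.null(meta$incubation_start) && !is.na(meta$incubation_start))
    return(done(parse_utc(meta$incubation_start), "observed"))
  if (!is.null(meta$first_egg_date) && !is.na(meta$first_egg_date) &&
      !is.null(meta$clutch_size) && !is.na(meta$clutch_size)) {
    d <- as.Date(meta$first_egg_date) + (as.integer(meta$clutch_size) - 1L)
    return(done(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"), "laying"))
  }
  if (!is.null(meta$hatch_start) && !is.na(meta$hatch_start) &&
      !is.null(ref) && !is.na(ref$typical_incubation_period_days)) {
    return(done(parse_utc(meta$hatch_start) -
                  ref$typical_incubation_period_days * 86400, "hatch"))
  }
  if (!is.null(meta$flotation_stage) && !is.na(meta$flotation_stage) &&
      !is.null(meta$flotation_date) && !is.na(meta$flotation_date) &&
      !is.null(flotation_lookup) &&
      meta$flotation_stage %in% names(flotation_lookup)) {
    d <- as.Date(meta$flotation_date) -
      flotation_lookup[[meta$flotation_stage]]
    return(done(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"), "flotation"))
  }
  if (!is.null(population_starts) && length(population_starts)) {
    ps <- sort(as.numeric(parse_utc(population_starts)))
    return(done(as.POSIXct(median(ps), origin = "1970-01-01", tz = "UTC"),
                "population-median"))
  }
  stop("no incubation-start pathway available for nest ",
       meta$nest_id %||% "<unknown>")
}
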