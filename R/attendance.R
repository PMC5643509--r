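## Hourly and daily nest attendance with the 75% type-purity filter.
##
## Each reading carries an incubation type: biparental, uniparental in a
## biparental species (inside a detected phase), or uniparental in an
## obligate uniparental species. A window (local-solar calendar day or
## hour) contributes one record per type only when that type covers at
## least 75% of the window's readings; attendance is then the
## percentage of that type's readings classified as incubated.
## Denominators count readings, not wall-clock time, so sensor gaps
## shrink numerator and denominator symmetrically.

.type_levels <- c("biparental", "uniparental-biparental-species",
                  "uniparental-uniparental-species")

#' Fraction of the typical incubation period elapsed
#'
#' @param t instant(s)
#' @param incubation_start incubation start instant
#' @param period_days species' typical incubation period (days)
#' @return percentage (values above 100 permitted)
#' @export
incubation_fraction <- function(t, incubation_start, period_days) {
  stopifnot(period_days > 0)
  100 * as.numeric(parse_utc(t) - parse_utc(incubation_start),
                   units = "days") / period_days
}

#' Circadian sine and cosine regressors
#'
#' Time of day is mapped to radians (`2*pi*hour/24`) and returned as
#' its sine and cosine, the pair of regressors used to linearise the
#' circular time-of-day covariate.
#'
#' @param local_hour hour of local day in \[0, 24)
#' @return data.table with columns `sine`, `cosine`
#' @export
circadian_regressors <- function(local_hour) {
  if (any(!is.finite(local_hour)) || any(local_hour < 0 | local_hour >= 24))
    stop("local_hour must lie in [0, 24)")
  rad <- 2 * pi * local_hour / 24
  data.table(sine = sin(rad), cosine = cos(rad))
}

## label each reading with an incubation type
.label_types <- function(states, phases, metadata, references) {
  st <- copy(as.data.table(states))
  md <- as.data.table(metadata)
  rf <- as.data.table(references)
  uni_sp <- rf[uniparental_flag != "biparental", species]
  st <- merge(st, md[, .(nest_id, species)], by = "nest_id", sort = FALSE)
  st[, inc_type := .type_levels[1]]
  st[species %in% uni_sp, inc_type := .type_levels[3]]
  ph <- as.data.table(phases)
  if (!is.null(ph) && nrow(ph)) {
    for (i in seq_len(nrow(ph))) {
      st[nest_id == ph$nest_id[i] & timestamp_utc >= ph$start[i] &
           timestamp_utc < ph$end[i] & inc_type == .type_levels[1],
         inc_type := .type_levels[2]]
    }
  }
  st
}

## apply nest-level and hatch-window exclusions
.apply_exclusions <- function(st, metadata, exclude_spans,
                              hatch_trim_h = 6, chicks_trim_h = 24) {
  md <- as.data.table(metadata)
  if ("eggs_remaining" %in% names(md)) {
    single <- md[!is.na(eggs_remaining) & eggs_remaining == 1, nest_id]
    st <- st[!nest_id %in% single]
  }
  if ("hatch_start" %in% names(md)) {
    hb <- md[!is.na(hatch_start), .(nest_id, bound = hatch_start - hatch_trim_h * 3600)]
    if (nrow(hb)) {
      st <- merge(st, hb, by = "nest_id", all.x = TRUE, sort = FALSE)
      st <- st[is.na(bound) | timestamp_utc < bound][, bound := NULL]
    }
  }
  if ("chicks_found" %in% names(md)) {
    cb <- md[!is.na(chicks_found), .(nest_id, bound = chicks_found - chicks_trim_h * 3600)]
    if (nrow(cb)) {
      st <- merge(st, cb, by = "nest_id", all.x = TRUE, sort = FALSE)
      st <- st[is.na(bound) | timestamp_utc < bound][, bound := NULL]
    }
  }
  if (!is.null(exclude_spans) && nrow(as.data.table(exclude_spans))) {
    ex <- as.data.table(exclude_spans)
    for (i in seq_len(nrow(ex)))
      st <- st[!(nest_id == ex$nest_id[i] & timestamp_utc >= ex$start[i] &
                   timestamp_utc < ex$end[i])]
  }
  st
}

#' Attendance records at daily or hourly granularity
#'
#' @param states incubation state series from [incubation_states()]
#'   (needs `timestamp_local`)
#' @param phases detected uniparental phases (may be empty)
#' @param metadata nest metadata (species, hatching fields,
#'   `eggs_remaining`; single-egg nests are excluded, as are readings
#'   inside the hatching trims)
#' @param references species reference table (for the uniparental
#'   species flag and the incubation period)
#' @param incubation_starts named POSIXct keyed by nest_id (for the
#'   day-in-period covariate); defaults to metadata `incubation_start`
#' @param granularity `"daily"` or `"hourly"`
#' @param min_purity emit a record only when one type covers at least
#'   this percentage of the window's readings (inclusive; default 75)
#' @param exclude_spans optional table (`nest_id`, `start`, `end`) of
#'   dislocated-probe spans to drop
#' @return data.table: `nest_id`, `local_date` (+ `local_hour` for
#'   hourly), `inc_type`, `attendance` (%), `purity` (%), `n_type`,
#'   `n_total`, `day_fraction` (%), `sine`, `cosine`
#' @export
attendance_records <- function(states, phases, metadata, references,
                               incubation_starts = NULL,
                               granularity = c("daily", "hourly"),
                               min_purity = 75, exclude_spans = NULL) {
  granularity <- match.arg(granularity)
  st <- .label_types(states, phases, metadata, references)
  st <- .apply_exclusions(st, metadata, exclude_spans)
  if (!nrow(st)) return(data.table())
  md <- as.data.table(metadata)
  rf <- as.data.table(references)
  if (is.null(incubation_starts)) {
    incubation_starts <- setNames(md$incubation_start, md$nest_id)
  }
  st[, local_date := as.Date(timestamp_local)]
  st[, local_hour := as.integer(format(timestamp_local, "%H"))]
  grp <- if (granularity == "daily") c("nest_id", "species", "local_date")
         else c("nest_id", "species", "local_date", "local_hour")
  tot <- st[, .(n_total = .N), by = grp]
  per <- st[, .(n_type = .N, attendance = 100 * sum(incubated) / .N),
            by = c(grp, "inc_type")]
  per <- merge(per, tot, by = grp)
  per[, purity := 100 * n_type / n_total]
  rec <- per[purity >= min_purity]
  if (!nrow(rec)) return(rec)
  ## one record per window at most (purity >= 75 admits a single type,
  ## except exactly 50/50 at min_purity <= 50 which we keep as-is)
  per_map <- setNames(rf$typical_incubation_period_days, rf$species)
  rec[, window_mid := if (granularity == "daily")
        as.POSIXct(paste(local_date, "12:00:00"), tz = "UTC")
      else as.POSIXct(paste(local_date, sprintf("%02d:30:00", local_hour)), tz = "UTC")]
  rec[, day_fraction := {
    i0 <- parse_utc(incubation_starts[nest_id])
    ## window_mid is in local solar time; compare on the local scale by
    ## shifting the start the same way
    lon <- setNames(md$longitude, md$nest_id)[nest_id]
    100 * as.numeric(window_mid - local_solar_time(i0, lon), units = "days") /
      per_map[species]
  }]
  hmid <- if (granularity == "daily") rep(12, nrow(rec)) else rec$local_hour + 0.5
  cr <- circadian_regressors(hmid)
  rec[, `:=`(sine = cr$sine, cosine = cr$cosine)]
  rec[, window_mid := NULL]
  setorderv(rec, grp)
  rec[]
}

#' @rdname attendance_records
#' @param ... passed to [attendance_records()]
#' @export
daily_attendance <- function(...) attendance_records(..., granularity = "daily")

#' @rdname attendance_records
#' @export
hourly_attendance <- function(...) attendance_records(..., granularity = "hourly")
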