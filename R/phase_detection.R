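## Qualified uniparental incubation phases.
##
## A solo span starts when one parent's partner fails to return (its
## final departure / the last change-over) and contains only that
## parent's incubation. The first population-median bout after the
## onset is treated as the remaining parent's "regular" bout and is
## excluded; the remainder qualifies as uniparental incubation only if
## it is at least `qualify_multiple` (default 2) median bouts long, so
## the whole solo span is at least three median bouts. Windows
## confounded by hatching are trimmed: 6 h before the start of
## hatching, 24 h before chicks were found.

#' Phase-detection parameters
#' @param qualify_multiple the post-exclusion remainder must be at
#'   least this many median bouts long (default 2)
#' @param capture_window_h a capture this many hours before the solo
#'   onset attributes the phase to `post-capture` (default 24)
#' @param hatch_trim_h trim this many hours before `hatch_start`
#' @param chicks_trim_h trim this many hours before `chicks_found`
#' @return list of class `unicub_phase_params`
#' @export
phase_params <- function(qualify_multiple = 2, capture_window_h = 24,
                         hatch_trim_h = 6, chicks_trim_h = 24) {
  p <- as.list(environment())
  stopifnot(p$qualify_multiple > 0, p$capture_window_h >= 0)
  class(p) <- "unicub_phase_params"
  p
}

## maximal same-sex runs of bouts for one nest (unknown-sex bouts are
## absorbed into the current run; a leading unknown run stands alone)
.solo_runs <- function(b) {
  n <- nrow(b)
  sex_ctx <- character(n)
  cur <- NA_character_
  run <- integer(n)
  rid <- 0L
  for (i in seq_len(n)) {
    s <- b$attending[i]
    if (s %in% c("F", "M")) {
      if (is.na(cur) || s != cur) { rid <- rid + 1L; cur <- s }
    } else if (is.na(cur)) {
      if (i == 1L || run[i - 1L] == 0L) { rid <- rid + 1L }
    }
    run[i] <- rid
    sex_ctx[i] <- if (is.na(cur)) "unknown" else cur
  }
  data.table(run_id = run, sex = sex_ctx)
}

#' Detect qualified uniparental incubation phases
#'
#' @param bouts sex-labelled bout table from [segment_bouts()] (one or
#'   more nests)
#' @param median_bout_h population median bout length (hours); a named
#'   vector keyed by nest_id is accepted for multi-population input
#' @param metadata nest metadata (hatching fields, events are taken
#'   from `events`)
#' @param events event table (`nest_id`, `timestamp_utc`,
#'   `kind` in capture/removal); optional
#' @param recording_end named POSIXct of per-nest recording ends (for
#'   the censoring flag); defaults to each nest's last bout end
#' @param params a [phase_params()]
#' @return data.table: `nest_id`, `sex`, `onset` (partner's final
#'   departure / solo-span start), `start`, `end`, `duration_days`,
#'   `cause`, `censored`
#' @export
detect_uniparental_phases <- function(bouts, median_bout_h, metadata = NULL,
                                      events = NULL, recording_end = NULL,
                                      params = phase_params()) {
  bouts <- as.data.table(bouts)
  if (any(median_bout_h <= 0)) stop("median_bout_h must be positive")
  md <- if (is.null(metadata)) data.table(nest_id = character()) else
    as.data.table(metadata)
  ev <- if (is.null(events)) data.table(nest_id = character(),
                                        timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                                        kind = character()) else as.data.table(events)
  empty <- data.table(nest_id = character(), sex = character(),
                      onset = as.POSIXct(character(), tz = "UTC"),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_days = numeric(), cause = character(),
                      censored = logical())
  if (!nrow(bouts)) return(empty)
  setorder(bouts, nest_id, start)
  res <- list()
  for (nid in unique(bouts$nest_id)) {
    b <- bouts[nest_id == nid]
    mb <- if (length(median_bout_h) > 1) median_bout_h[[nid]] else median_bout_h
    mb_s <- mb * 3600
    runs <- .solo_runs(b)
    b <- cbind(b, runs[, .(run_id, sex_ctx = sex)])
    m <- if (nrow(md)) md[nest_id == nid] else md
    hatch_bound <- as.POSIXct(Inf, origin = "1970-01-01", tz = "UTC")
    if (nrow(m)) {
      if (!is.null(m$hatch_start) && !is.na(m$hatch_start[1]))
        hatch_bound <- min(hatch_bound, m$hatch_start[1] - params$hatch_trim_h * 3600)
      if (!is.null(m$chicks_found) && !is.na(m$chicks_found[1]))
        hatch_bound <- min(hatch_bound, m$chicks_found[1] - params$chicks_trim_h * 3600)
    }
    rec_end <- if (!is.null(recording_end) && nid %in% names(recording_end))
      parse_utc(recording_end[[nid]]) else max(b$end)
    ## span boundaries come from sex-known bouts: stray unknown-sex
    ## fragments (e.g. noise blips after full desertion) must not
    ## stretch a solo span
    spans <- b[, {
      known <- attending %in% c("F", "M")
      if (any(known))
        list(span_start = min(start[known]), span_end = max(end[known]),
             sex = sex_ctx[1])
      else
        list(span_start = min(start), span_end = max(end), sex = sex_ctx[1])
    }, by = run_id]
    last_run <- spans$run_id[which.max(spans$span_end)]
    for (k in seq_len(nrow(spans))) {
      sp <- spans[k]
      p_start <- sp$span_start + mb_s       # skip the first regular bout
      p_end <- min(sp$span_end, hatch_bound)
      if (as.numeric(p_end - p_start, units = "secs") <
          params$qualify_multiple * mb_s) next
      nb <- ev[nest_id == nid]
      cause <- "natural/unknown"
      if (nrow(nb[kind == "removal" & timestamp_utc <= sp$span_start]))
        cause <- "experimental-removal"
      else if (nrow(nb[kind == "capture" &
                       timestamp_utc <= sp$span_start &
                       timestamp_utc >= sp$span_start - params$capture_window_h * 3600]))
        cause <- "post-capture"
      else {
        later <- spans[span_start > sp$span_end & sex != sp$sex & sex != "unknown"]
        if (sp$sex != "unknown" && nrow(later)) cause <- "temporal"
      }
      censored <- sp$run_id == last_run && p_end >= rec_end - 1 &&
        p_end < hatch_bound
      res[[length(res) + 1]] <- data.table(
        nest_id = nid, sex = sp$sex, onset = sp$span_start,
        start = p_start, end = p_end,
        duration_days = as.numeric(p_end - p_start, units = "days"),
        cause = cause, censored = censored)
    }
  }
  if (!length(res)) return(empty)
  out <- rbindlist(res)
  setorder(out, nest_id, start)
  out[]
}

#' Phase metrics: start fraction and duration
#'
#' `start_fraction` is the percentage of the species' typical
#' incubation period already elapsed when the phase begins; values
#' above 100 mark phases starting after the expected hatch date and are
#' legitimate. Negative fractions (phase before the estimated
#' incubation start) are flagged as data anomalies.
#'
#' @param phases table from [detect_uniparental_phases()]
#' @param incubation_starts named POSIXct keyed by nest_id (or a single
#'   value)
#' @param ref species reference (needs
#'   `typical_incubation_period_days`); a single row or a table keyed
#'   by species together with `metadata`
#' @param metadata optional metadata to map nest to species when `ref`
#'   has several rows
#' @return input table with `start_fraction` (%) and `anomaly` columns
#' @export
phase_metrics <- function(phases, incubation_starts, ref, metadata = NULL) {
  ph <- copy(as.data.table(phases))
  if (!nrow(ph)) { ph[, `:=`(start_fraction = numeric(), anomaly = logical())]; return(ph) }
  period <- function(nid) {
    rr <- as.data.table(ref)
    if (nrow(rr) == 1 || is.null(metadata)) return(rr$typical_incubation_period_days[1])
    sp <- as.data.table(metadata)[nest_id == nid, species][1]
    rr[species == sp, typical_incubation_period_days][1]
  }
  inc0 <- function(nid) {
    if (length(incubation_starts) > 1 || !is.null(names(incubation_starts)))
      parse_utc(incubation_starts[[nid]]) else parse_utc(incubation_starts)
  }
  ph[, start_fraction := vapply(seq_len(.N), function(i) {
    100 * as.numeric(start[i] - inc0(nest_id[i]), units = "days") /
      period(nest_id[i])
  }, numeric(1))]
  ph[, anomaly := start_fraction < 0]
  if (any(ph$anomaly))
    warning("phase(s) starting before the estimated incubation start: ",
            paste(unique(ph[anomaly == TRUE, nest_id]), collapse = ", "))
  ph[]
}

#' Classify the cause of a uniparental phase
#'
#' Standalone version of the attribution applied inside
#' [detect_uniparental_phases()]: experimental removal before the
#' onset beats a capture within `capture_window_h` before the onset,
#' which beats a later return to biparental incubation (`temporal`);
#' everything else is `natural/unknown`.
#'
#' @param phase one-row phase (needs `onset`, `end`, `sex`, `nest_id`)
#' @param events event table for the nest
#' @param bouts bout table for the nest (to see partner return)
#' @param params a [phase_params()]
#' @return character cause
#' @export
classify_cause <- function(phase, events = NULL, bouts = NULL,
                           params = phase_params()) {
  phase <- as.data.table(as.list(as.data.table(phase)[1]))
  ev <- if (is.null(events)) data.table(kind = character(),
                                        timestamp_utc = as.POSIXct(character(), tz = "UTC"))
        else as.data.table(events)
  if (nrow(ev[kind == "removal" & timestamp_utc <= phase$onset]))
    return("experimental-removal")
  if (nrow(ev[kind == "capture" & timestamp_utc <= phase$onset &
              timestamp_utc >= phase$onset - params$capture_window_h * 3600]))
    return("post-capture")
  if (!is.null(bouts)) {
    b <- as.data.table(bouts)
    other <- setdiff(c("F", "M"), phase$sex)
    if (length(other) == 1 &&
        nrow(b[attending == other & start > phase$end]))
      return("temporal")
  }
  "natural/unknown"
}
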