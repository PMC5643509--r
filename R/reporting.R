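## Summary surfaces: species/population tables, case-level descriptive
## statistics, the published-count fixture, and actogram rendering.

#' Published summary counts of the multi-species field study
#'
#' A small packaged fixture transcribing the body-text counts of the
#' published multi-population field study of uniparental incubation in
#' biparentally incubating shorebirds (398 monitored nests; 70
#' uniparental cases from 68 nests, 14 by females; 55 nests with known
#' outcome of which 15 hatched, 4 were depredated and 36 were deserted;
#' 69 cases with a known start of which 7 began after the typical
#' incubation period). Gives the summary operations a fixed test
#' surface without the original raw data.
#'
#' @return named numeric vector of counts
#' @export
study_counts <- function() {
  p <- system.file("extdata", "study_counts.csv", package = "unicub")
  dt <- fread(p)
  setNames(dt$value, dt$quantity)
}

#' Contingency statistics from summary counts
#'
#' Derives the headline percentages from a count vector shaped like
#' [study_counts()]:
#' * `t1` % of known-outcome uniparental nests that hatched
#' * `t2` % deserted, `t3` % depredated (same denominator)
#' * `t4` % of uniparental cases with the male as remaining incubator
#' * `t5` % of all monitored nests with at least one uniparental case
#' * `t6` % of cases starting after the typical incubation period
#'
#' @param counts named numeric vector (defaults to [study_counts()])
#' @return named numeric vector `t1`..`t6`, in percent
#' @export
contingency_stats <- function(counts = study_counts()) {
  c(t1 = 100 * counts[["hatched_nests"]] / counts[["known_outcome_nests"]],
    t2 = 100 * counts[["deserted_nests"]] / counts[["known_outcome_nests"]],
    t3 = 100 * counts[["depredated_nests"]] / counts[["known_outcome_nests"]],
    t4 = 100 * (counts[["uniparental_cases"]] - counts[["female_cases"]]) /
      counts[["uniparental_cases"]],
    t5 = 100 * counts[["uniparental_nests"]] / counts[["total_monitored_nests"]],
    t6 = 100 * counts[["cases_start_after_period"]] /
      counts[["cases_with_known_start"]])
}

#' Species/population summary table
#'
#' One row per species x population: monitored nests, nests with at
#' least one uniparental phase (count and %), male-only uniparental
#' nests (count and % of uniparental), nests with known outcome and
#' successful nests (count and % of known outcome); ordered by %
#' uniparental (descending), then total nests, with a pooled `ALL` row.
#' Percentages are stored at full precision; every percentage column is
#' recomputable from the counts on the same row.
#'
#' @param dataset a `unicub_dataset` (metadata supplies species,
#'   population, outcome)
#' @param phases detected phases (possibly with metrics)
#' @return data.table summary
#' @export
species_summary_table <- function(dataset, phases) {
  md <- as.data.table(dataset$metadata)
  ph <- as.data.table(phases)
  if (!nrow(md)) return(data.table())
  per_nest <- md[, .(nest_id, species, population, outcome)]
  has_phase <- if (nrow(ph)) unique(ph$nest_id) else character(0)
  male_only_nests <- if (nrow(ph))
    ph[, .(mo = all(sex == "M")), by = nest_id][mo == TRUE, nest_id]
  else character(0)
  per_nest[, `:=`(uni = nest_id %in% has_phase,
                  mo = nest_id %in% male_only_nests)]
  summ <- function(d) d[, .(
    total_nests = .N,
    uniparental_nests = sum(uni),
    pct_uniparental = 100 * sum(uni) / .N,
    male_only = sum(uni & mo),
    pct_male_only = if (sum(uni) > 0) 100 * sum(uni & mo) / sum(uni) else NA_real_,
    known_outcome = sum(uni & outcome != "unknown" & !is.na(outcome)),
    successful = sum(uni & outcome == "hatched"),
    pct_successful = {
      ko <- sum(uni & outcome != "unknown" & !is.na(outcome))
      if (ko > 0) 100 * sum(uni & outcome == "hatched") / ko else NA_real_
    })]
  tab <- per_nest[, summ(.SD), by = .(species, population)]
  setorder(tab, -pct_uniparental, -total_nests)
  all_row <- summ(per_nest)[, `:=`(species = "ALL", population = "ALL")]
  setcolorder(all_row, names(tab))
  out <- rbind(tab, all_row)
  .audit_percentages(out)
  out[]
}

## self-consistency audit: every % column equals 100 * num / den
.audit_percentages <- function(tab) {
  chk <- function(pct, num, den) {
    ok <- is.na(pct) | den == 0 |
      abs(pct - 100 * num / den) < 1e-8
    if (!all(ok)) stop("percentage column inconsistent with its counts")
  }
  chk(tab$pct_uniparental, tab$uniparental_nests, tab$total_nests)
  chk(tab$pct_male_only, tab$male_only, tab$uniparental_nests)
  chk(tab$pct_successful, tab$successful, tab$known_outcome)
  invisible(TRUE)
}

#' Descriptive statistics of uniparental cases
#'
#' Medians, ranges and Ns of phase duration (days) and start fraction
#' (% of the typical incubation period), plus the filtered variant that
#' drops cases starting after the typical period (start fraction >
#' 100%) and the share of cases removed by that filter.
#'
#' @param phases phase table with `duration_days` and `start_fraction`
#' @return data.table with one row per statistic, or an empty-stats
#'   marker (zero rows) for an empty phase list
#' @export
case_summary_stats <- function(phases) {
  ph <- as.data.table(phases)
  if (!nrow(ph)) return(data.table(statistic = character(), value = numeric(),
                                   n = integer()))
  row <- function(stat, value, n) data.table(statistic = stat, value = value,
                                             n = as.integer(n))
  out <- rbind(
    row("median_duration_days", median(ph$duration_days), nrow(ph)),
    row("min_duration_days", min(ph$duration_days), nrow(ph)),
    row("max_duration_days", max(ph$duration_days), nrow(ph)))
  if ("start_fraction" %in% names(ph) && any(!is.na(ph$start_fraction))) {
    sf <- ph[!is.na(start_fraction)]
    kept <- sf[start_fraction <= 100]
    out <- rbind(out,
      row("median_start_fraction", median(sf$start_fraction), nrow(sf)),
      row("min_start_fraction", min(sf$start_fraction), nrow(sf)),
      row("max_start_fraction", max(sf$start_fraction), nrow(sf)),
      row("median_start_fraction_filtered",
          if (nrow(kept)) median(kept$start_fraction) else NA_real_, nrow(kept)),
      row("pct_cases_start_after_period",
          100 * (nrow(sf) - nrow(kept)) / nrow(sf), nrow(sf)))
  }
  out[]
}

#' Render an actogram
#'
#' One row per local-solar day; within each row the 24-h time axis is
#' colour-coded: no incubation (pink), female on the nest (yellow),
#' male on the nest (dark blue), unknown attending parent (grey), with
#' the surface temperature overlaid as a line scaled into the row and
#' days inside a uniparental phase marked along the left edge. Output
#' is deterministic for fixed input.
#'
#' @param trace one nest's temperature table
#' @param states the matching incubation state series (with
#'   `timestamp_local` and `attending`)
#' @param phases detected phases for the nest (may be empty)
#' @param file output file; the device is chosen by extension
#'   (`.png` or `.svg`)
#' @param width,height device size in pixels (png) or inches (svg)
#' @return invisible `file`
#' @export
render_actogram <- function(trace, states, phases = NULL, file,
                            width = 900, height = 600) {
  st <- as.data.table(states)
  if (!nrow(st)) stop("empty trace: nothing to render")
  tr <- as.data.table(trace)
  st <- merge(st, tr[, .(nest_id, timestamp_utc, surface_temp_c)],
              by = c("nest_id", "timestamp_utc"), sort = FALSE)
  st[, local_date := as.Date(timestamp_local)]
  st[, hour := as.numeric(timestamp_local -
                            as.POSIXct(paste(local_date, "00:00:00"), tz = "UTC"),
                          units = "hours")]
  days <- sort(unique(st$local_date))
  ph <- if (is.null(phases)) data.table() else as.data.table(phases)
  if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = width / 100, height = height / 100)
  } else {
    grDevices::png(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 6, 2, 1))
  graphics::plot(NULL, xlim = c(0, 24), ylim = c(length(days), 0),
                 xlab = "hour of local solar day", ylab = "",
                 yaxt = "n", xaxs = "i",
                 main = unique(st$nest_id)[1])
  graphics::axis(2, at = seq_along(days) - 0.5, labels = format(days),
                 las = 1, cex.axis = 0.7)
  cols <- c(none = "#f8b8c8", F = "#f2c200", M = "#2a4d7a",
            unknown = "#9b9b9b")
  srange <- range(st$surface_temp_c, na.rm = TRUE)
  if (diff(srange) == 0) srange <- srange + c(-1, 1)
  for (d in seq_along(days)) {
    dd <- st[local_date == days[d]]
    setorder(dd, hour)
    r <- rle(dd$attending)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    graphics::rect(dd$hour[starts], d - 0.08, dd$hour[ends], d - 0.92,
                   col = cols[r$values], border = NA)
    ## surface temperature overlay scaled into the row band
    ys <- d - 0.08 - 0.84 * (dd$surface_temp_c - srange[1]) / diff(srange)
    graphics::lines(dd$hour, ys, col = "#57c4e5", lwd = 0.6)
    if (nrow(ph)) {
      mid <- as.POSIXct(paste(days[d], "12:00:00"), tz = "UTC")
      in_phase <- any(ph$start <= mid & ph$end >= mid)
      graphics::rect(-0.45, d - 0.05, -0.05, d - 0.95, xpd = TRUE,
                     col = if (in_phase) "#8496ad" else "#69b578",
                     border = NA)
    }
  }
  invisible(file)
}
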