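## Data model and interchange IO.
##
## The pipeline's interchange dialect is plain CSV with ISO-8601 UTC
## timestamps. A dataset bundles six tables keyed by nest_id:
##   temperature: nest_id, timestamp_utc, nest_temp_c, surface_temp_c
##   rfid:        nest_id, timestamp_utc, tag_id
##   metadata:    one row per nest (see below)
##   events:      nest_id, timestamp_utc, kind in {capture, removal}
##   tags:        nest_id, tag_id, sex in {F, M}
##   references:  species, population, typical_incubation_period_days,
##                median_bout_h, uniparental_flag
## Missing sensor samples are kept as explicit gaps; interpolation policy
## belongs to extraction, not to loading.

.metadata_cols <- c("nest_id", "species", "population", "latitude",
                    "longitude", "clutch_size", "first_egg_date",
                    "hatch_start", "chicks_found", "flotation_date",
                    "flotation_stage", "incubation_start", "outcome",
                    "eggs_remaining")

#' Construct a nest-monitoring dataset
#'
#' Low-level constructor; [load_dataset()] is the file-based entry point.
#' All tables are coerced to data.table and validated.
#'
#' @param temperature,rfid,metadata,events,tags,references data.frames in
#'   the documented column layouts; `events` and `tags` may be omitted.
#' @param validate run [validate_dataset()] and stop on violations?
#' @return an object of class `unicub_dataset`
#' @export
unicub_dataset <- function(temperature, rfid = NULL, metadata = NULL,
                           events = NULL, tags = NULL, references = NULL,
                           validate = TRUE) {
  empt <- function(cols) setnames(data.table(matrix(nrow = 0, ncol = length(cols))), cols)
  temperature <- as.data.table(temperature)
  rfid <- if (is.null(rfid)) empt(c("nest_id", "timestamp_utc", "tag_id")) else as.data.table(rfid)
  metadata <- if (is.null(metadata)) empt(.metadata_cols) else as.data.table(metadata)
  events <- if (is.null(events)) empt(c("nest_id", "timestamp_utc", "kind")) else as.data.table(events)
  tags <- if (is.null(tags)) empt(c("nest_id", "tag_id", "sex")) else as.data.table(tags)
  references <- if (is.null(references)) {
    empt(c("species", "population", "typical_incubation_period_days",
           "median_bout_h", "uniparental_flag"))
  } else as.data.table(references)

  for (nm in c("temperature", "rfid", "events")) {
    tab <- get(nm)
    if (nrow(tab) && "timestamp_utc" %in% names(tab))
      tab[, timestamp_utc := parse_utc(timestamp_utc)]
  }
  if (nrow(metadata)) {
    for (cc in intersect(names(metadata), .ts_cols))
      metadata[, (cc) := parse_utc(metadata[[cc]])]
    for (cc in intersect(names(metadata), .date_cols))
      metadata[, (cc) := as.Date(metadata[[cc]])]
  }
  ds <- structure(list(temperature = temperature, rfid = rfid,
                       metadata = metadata, events = events, tags = tags,
                       references = references),
                  class = "unicub_dataset")
  if (validate) {
    issues <- validate_dataset(ds)
    if (nrow(issues)) {
      stop("dataset validation failed:\n",
           paste(utils::capture.output(print(issues)), collapse = "\n"))
    }
  }
  ds
}

#' Validate a dataset against the data-model invariants
#'
#' Checks are total: every offending row is reported with its table,
#' nest and reason; nothing is silently dropped.
#'
#' @param ds a `unicub_dataset`
#' @return data.table with columns `table`, `nest_id`, `problem`
#'   (zero rows when valid)
#' @export
validate_dataset <- function(ds) {
  iss <- list()
  add <- function(table, nest_id, problem) {
    iss[[length(iss) + 1]] <<- data.table(table = table,
                                          nest_id = as.character(nest_id),
                                          problem = problem)
  }
  tp <- ds$temperature
  if (nrow(tp)) {
    need <- c("nest_id", "timestamp_utc", "nest_temp_c", "surface_temp_c")
    miss <- setdiff(need, names(tp))
    if (length(miss)) add("temperature", NA, paste("missing columns:", paste(miss, collapse = ",")))
    else {
      bad <- tp[, .(mono = all(diff(as.numeric(timestamp_utc)) > 0)), by = nest_id][mono == FALSE]
      for (n in bad$nest_id) add("temperature", n, "timestamps not strictly increasing")
      inf <- tp[is.infinite(nest_temp_c) | is.infinite(surface_temp_c), unique(nest_id)]
      for (n in inf) add("temperature", n, "non-finite temperature (use NA for missing)")
    }
  }
  rf <- ds$rfid
  if (nrow(rf) && all(c("nest_id", "timestamp_utc") %in% names(rf))) {
    bad <- rf[, .(mono = all(diff(as.numeric(timestamp_utc)) >= 0)), by = nest_id][mono == FALSE]
    for (n in bad$nest_id) add("rfid", n, "timestamps decreasing")
  }
  md <- ds$metadata
  if (nrow(md)) {
    if ("latitude" %in% names(md))
      for (n in md[!is.na(latitude) & (latitude < -90 | latitude > 90), nest_id])
        add("metadata", n, "latitude outside [-90, 90]")
    if ("longitude" %in% names(md))
      for (n in md[!is.na(longitude) & (longitude < -180 | longitude > 180), nest_id])
        add("metadata", n, "longitude outside [-180, 180]")
    if (all(c("hatch_start", "chicks_found") %in% names(md)))
      for (n in md[!is.na(hatch_start) & !is.na(chicks_found) &
                   chicks_found < hatch_start, nest_id])
        add("metadata", n, "chicks_found precedes hatch_start")
    if (nrow(ds$references) && "species" %in% names(md)) {
      known <- unique(ds$references$species)
      for (i in which(!md$species %in% known))
        add("metadata", md$nest_id[i],
            paste0("unknown species code '", md$species[i], "'"))
    }
  }
  if (nrow(tp) && nrow(md) && "nest_id" %in% names(tp)) {
    orphan <- setdiff(unique(tp$nest_id), md$nest_id)
    for (n in orphan) add("temperature", n, "nest_id absent from metadata")
  }
  rfd <- ds$references
  if (nrow(rfd)) {
    bad <- rfd[typical_incubation_period_days <= 0 | median_bout_h <= 0]
    for (i in seq_len(nrow(bad)))
      add("references", bad$species[i], "non-positive reference value")
  }
  if (length(iss)) rbindlist(iss) else
    data.table(table = character(), nest_id = character(), problem = character())
}

#' Load a dataset from interchange CSV files
#'
#' @param paths named list/vector of file paths; `temperature` is
#'   required, `rfid`, `metadata`, `events`, `tags`, `references`
#'   optional.
#' @param validate stop on invariant violations (default TRUE)?
#' @return a `unicub_dataset`
#' @export
load_dataset <- function(paths, validate = TRUE) {
  paths <- as.list(paths)
  rd <- function(nm) {
    p <- paths[[nm]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) stop("cannot read ", nm, " file: ", p)
    read_interchange(p)
  }
  unicub_dataset(temperature = rd("temperature"), rfid = rd("rfid"),
                 metadata = rd("metadata"), events = rd("events"),
                 tags = rd("tags"), references = rd("references"),
                 validate = validate)
}

#' Read one interchange CSV, restoring instant/date column types
#' @param path file path
#' @return data.table
#' @export
read_interchange <- function(path) {
  dt <- fread(path, colClasses = "character", na.strings = c("", "NA"))
  for (cc in names(dt)) {
    if (cc %in% .ts_cols) { dt[, (cc) := parse_utc(dt[[cc]])]; next }
    if (cc %in% .date_cols) { dt[, (cc) := as.Date(dt[[cc]])]; next }
    v <- dt[[cc]]
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(v) == is.na(num))) {
      dt[, (cc) := num]
      if (all(is.na(num) | num == round(num)) &&
          all(abs(num) < 2^31, na.rm = TRUE) && cc %in%
          c("clutch_size", "eggs_remaining", "n", "n_readings", "n_obs"))
        dt[, (cc) := as.integer(dt[[cc]])]
    } else if (all(v %in% c("TRUE", "FALSE", NA))) {
      dt[, (cc) := as.logical(v)]
    }
  }
  dt
}

#' Write pipeline tables to CSV
#'
#' Round-trip stable: [read_interchange()] on a written file reproduces
#' the table field-for-field (instants at 1-s resolution).
#'
#' @param tables named list of data.frames (or a single data.frame, in
#'   which case `name` supplies the file stem)
#' @param dir output directory (created if absent)
#' @param name file stem when `tables` is a single table
#' @return invisible character vector of file paths written
#' @export
write_outputs <- function(tables, dir, name = "table") {
  if (is.data.frame(tables)) tables <- setNames(list(tables), name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.table(copy(tables[[nm]]))
    for (cc in names(tab)) {
      if (inherits(tab[[cc]], "POSIXct")) tab[, (cc) := format_utc(tab[[cc]])]
      if (inherits(tab[[cc]], "Date")) tab[, (cc) := format(tab[[cc]])]
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    fwrite(tab, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
#' @method print unicub_dataset
print.unicub_dataset <- function(x, ...) {
  cat("<unicub_dataset>\n")
  cat(sprintf("  temperature: %d readings, %d nest(s)\n",
              nrow(x$temperature),
              length(unique(x$temperature$nest_id))))
  cat(sprintf("  rfid: %d detections; metadata: %d nest(s); references: %d row(s)\n",
              nrow(x$rfid), nrow(x$metadata), nrow(x$references)))
  invisible(x)
}
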