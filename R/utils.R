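## Internal helpers: time handling, config parsing, small numerics.

#' Parse ISO-8601 UTC timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` or `YYYY-MM-DD HH:MM:SS`, always UTC.
#' @param x character vector
#' @return POSIXct (UTC)
#' @keywords internal
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

#' Format timestamps for interchange files
#' @param x POSIXct
#' @keywords internal
format_utc <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

## Columns (by name) holding instants / dates in interchange tables.
.ts_cols <- c("timestamp_utc", "timestamp_local", "hatch_start",
              "chicks_found", "incubation_start", "start", "end", "onset",
              "span_start", "span_end", "window_mid", "desertion_time",
              "hatch_time", "recording_end")
.date_cols <- c("first_egg_date", "flotation_date", "local_date")

#' Snap instants to a sampling grid
#' @keywords internal
snap_to_grid <- function(t, origin, dt_s) {
  origin + round(as.numeric(t - origin, units = "secs") / dt_s) * dt_s
}

#' Read a flat `key: value` config file
#'
#' The pipeline's config format is a flat set of `key: value` lines
#' (`#` comments allowed); files ending in `.json` are parsed with
#' jsonlite instead. Values that look numeric are coerced; comma-separated
#' values become vectors.
#'
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) {
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Median weighted by counts
#'
#' Smallest value whose cumulative weight reaches half the total; when it
#' hits half exactly, the midpoint with the next distinct value is used
#' (reduces to the usual sample median for unit weights).
#'
#' @param x numeric values
#' @param w non-negative weights
#' @return numeric scalar
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Derive a per-unit RNG seed from a master seed
#' @keywords internal
derive_seed <- function(seed, i) {
  (as.integer(seed) * 1009L + as.integer(i) * 101L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
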