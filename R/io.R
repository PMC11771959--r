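.ts_fmt <- "%Y-%m-%dT%H:%M:%OS6Z"

.format_ts <- function(t) format(t, .ts_fmt, tz = "UTC")

.parse_ts <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  if (anyNA(t) && !anyNA(s))
    stop("unparseable ISO-8601 timestamps, e.g. ", s[which(is.na(t))[1]])
  t
}

#' Write / read a localization fix table
#'
#' CSV schema: `tag_id`, `timestamp_utc` (ISO-8601, microsecond
#' precision), `x_m`, `y_m`, `stdloc_m`, `nbs`. The reader validates the
#' schema and time-ordering within tag so downstream stages can assume
#' clean input.
#'
#' @param fixes data.frame with columns `tag_id`, `t`, `x`, `y`, `stdloc`,
#'   `nbs`.
#' @param path File path.
#' @return `read_fixes` returns the fix data.frame in internal column
#'   names; `write_fixes` returns `path` invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(tag_id = fixes$tag_id, timestamp_utc = .format_ts(fixes$t),
                    x_m = fixes$x, y_m = fixes$y, stdloc_m = fixes$stdloc,
                    nbs = fixes$nbs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tag_id", "timestamp_utc", "x_m", "y_m", "stdloc_m", "nbs")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("fix table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  fx <- data.frame(tag_id = as.character(raw$tag_id),
                   t = .parse_ts(raw$timestamp_utc),
                   x = as.numeric(raw$x_m), y = as.numeric(raw$y_m),
                   stdloc = as.numeric(raw$stdloc_m),
                   nbs = as.integer(raw$nbs))
  .check_track(fx)
  fx
}

#' Write / read a radar echo table
#'
#' CSV schema: `timestamp_utc`, `altitude_m`, `rcs_mm2`, `class`.
#'
#' @param echoes data.frame with columns `t`, `altitude_m`, `rcs_mm2`,
#'   `class`.
#' @param path File path.
#' @export
write_echoes <- function(echoes, path) {
  out <- data.frame(timestamp_utc = .format_ts(echoes$t),
                    altitude_m = echoes$altitude_m,
                    rcs_mm2 = echoes$rcs_mm2, class = echoes$class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_echoes
#' @export
read_echoes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp_utc", "altitude_m", "rcs_mm2", "class")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("echo table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  data.frame(t = .parse_ts(raw$timestamp_utc),
             altitude_m = as.numeric(raw$altitude_m),
             rcs_mm2 = as.numeric(raw$rcs_mm2),
             class = as.character(raw$class))
}

#' Write / read the ground-truth record of a simulated world
#'
#' JSON keyed by section (`motr`, `tag_days`, `visits`, `outlier_rows`),
#' dates and times ISO-8601.
#'
#' @param truth Truth list from [generate_tracks()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  enc <- truth
  enc$motr$date <- as.character(enc$motr$date)
  enc$tag_days$date <- as.character(enc$tag_days$date)
  if (!is.null(enc$visits)) {
    enc$visits$date <- as.character(enc$visits$date)
    enc$visits$entry <- .format_ts(enc$visits$entry)
    enc$visits$exit <- .format_ts(enc$visits$exit)
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$motr$date <- as.Date(tr$motr$date)
  tr$tag_days$date <- as.Date(tr$tag_days$date)
  if (!is.null(tr$visits) && length(tr$visits)) {
    tr$visits$date <- as.Date(tr$visits$date)
    tr$visits$entry <- .parse_ts(tr$visits$entry)
    tr$visits$exit <- .parse_ts(tr$visits$exit)
  }
  tr$outlier_rows <- as.integer(tr$outlier_rows)
  tr
}
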