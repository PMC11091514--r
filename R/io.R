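# On-disk formats: cases.csv (ISO-8601 datetimes) and observations.jsonl
# (one observation per line, fixed key order).

#' @noRd
or_fmt_time <- function(x, frac = FALSE) {
  out <- format(x, if (frac) "%Y-%m-%dT%H:%M:%OS3Z" else "%Y-%m-%dT%H:%M:%SZ",
                tz = .or_tz)
  out[is.na(x)] <- NA_character_
  out
}

#' @noRd
or_parse_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = .or_tz)
}

#' Write / read a case table
#'
#' CSV with a header row and ISO-8601 (UTC) datetimes; lossless round-trip.
#'
#' @param cases Case table from [generate_cases()].
#' @param path File path.
#' @return `write_cases` returns `path` invisibly; `read_cases` returns the
#'   case table with POSIXct datetimes.
#' @export
write_cases <- function(cases, path) {
  out <- cases
  for (col in c("scheduled_start", "scheduled_end",
                "anaesthesia_start", "anaesthesia_stop"))
    out[[col]] <- or_fmt_time(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("scheduled_start", "scheduled_end",
                "anaesthesia_start", "anaesthesia_stop"))
    out[[col]] <- or_parse_time(out[[col]])
  if ("captured" %in% names(out)) out$captured <- as.logical(out$captured)
  out
}

#' Write / read an observation stream
#'
#' JSON Lines, one observation per line with keys exactly `case_id`,
#' `stream`, `name`, `action`, `value`, `charted_time`, `ingest_time`
#' (ISO-8601 UTC, millisecond precision for ingestion times; `null` for
#' absent action/value). Lossless round-trip at that precision.
#'
#' @param observations Observation table.
#' @param path File path.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` returns the observation table.
#' @export
write_observations <- function(observations, path) {
  df <- data.frame(
    case_id = observations$case_id,
    stream = observations$stream,
    name = observations$name,
    action = observations$action,
    value = observations$value,
    charted_time = or_fmt_time(observations$charted_time),
    ingest_time = or_fmt_time(observations$ingest_time, frac = TRUE),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  for (col in c("action")) if (!col %in% names(df)) df[[col]] <- NA_character_
  if (!"value" %in% names(df)) df$value <- NA_real_
  df$charted_time <- or_parse_time(df$charted_time)
  df$ingest_time <- or_parse_time(df$ingest_time)
  df[c("case_id", "stream", "name", "action", "value",
       "charted_time", "ingest_time")]
}
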