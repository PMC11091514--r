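#' Latency-respecting minute-level replay of one case
#'
#' Reconstructs what the real-time pipeline would have seen for a case at
#' elapsed minute `t`: exactly those observations whose *ingestion* time is
#' at or before `anaesthesia_start + t` minutes. Visibility is governed by
#' ingestion, not charting, so information that had not yet crossed the
#' EHR-to-server latency is excluded — the replayed view can never leak the
#' future. Observation offsets are whole charted minutes since anaesthesia
#' start.
#'
#' @param case One-row case table (the case to replay).
#' @param observations Observation table (may contain other cases; filtered).
#' @param t Elapsed minutes since anaesthesia start, `1 <= t <=
#'   floor(actual_duration)`.
#' @param vocab Frozen [or_vocab] used to tokenize names.
#' @param lookback Flowsheet series lookback in minutes; older readings are
#'   summarized by their most recent value per channel.
#' @return An object of class `or_snapshot`: `case_id`, `t`, `preop`
#'   (attributes + token ids + scheduled duration), `events` (id, offset),
#'   `meds` (id, action, offset), `flowsheet` (per-channel value/offset
#'   series plus older-value summary), and `label` (actual total duration;
#'   for scoring only, never a model input).
#' @export
replay <- function(case, observations, t, vocab, lookback = 120) {
  if (!is.data.frame(case) || nrow(case) != 1L)
    or_stopf("unknown case: replay() needs exactly one case row, got %d",
             if (is.data.frame(case)) nrow(case) else 0L)
  if (!isTRUE(vocab$frozen)) or_stopf("vocabulary must be frozen before replay")
  D <- floor(case$actual_duration)
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > D)
    or_stopf("t out of range: must be in 1..%d for case %s (got %s)",
             D, case$case_id, as.character(t))

  start <- case$anaesthesia_start
  obs <- observations[observations$case_id == case$case_id, , drop = FALSE]
  vis <- or_minutes(obs$ingest_time, start) <= t
  obs <- obs[!is.na(vis) & vis, , drop = FALSE]
  off <- pmin(pmax(floor(or_minutes(obs$charted_time, start)), 0), t)

  ev <- obs$stream == "event"
  md <- obs$stream == "medication"
  events <- list(id = tokenize(vocab, "event", obs$name[ev]),
                 offset = as.integer(off[ev]))
  o_ev <- order(events$offset, events$id)
  events <- list(id = events$id[o_ev], offset = events$offset[o_ev])
  meds <- list(id = tokenize(vocab, "medication", obs$name[md]),
               action = tokenize(vocab, "action", obs$action[md]),
               offset = as.integer(off[md]))
  o_md <- order(meds$offset, meds$id, meds$action)
  meds <- list(id = meds$id[o_md], action = meds$action[o_md],
               offset = meds$offset[o_md])

  flow <- list()
  for (ch in or_flowsheet_channels()) {
    sel <- obs$stream == "flowsheet" & obs$name == ch
    v <- obs$value[sel]
    o <- as.integer(off[sel])
    ordc <- order(o)
    v <- v[ordc]; o <- o[ordc]
    recent <- o > t - lookback
    older <- if (any(!recent)) {
      list(value = v[max(which(!recent))], offset = o[max(which(!recent))])
    } else {
      list(value = NA_real_, offset = NA_integer_)
    }
    flow[[ch]] <- list(value = v[recent], offset = o[recent], older = older)
  }

  structure(list(
    case_id = case$case_id,
    t = t,
    preop = list(
      hospital = case$hospital, service = case$service,
      location = case$location, urgency = case$urgency,
      scheduled_duration = case$scheduled_duration,
      hospital_id = tokenize(vocab, "hospital", case$hospital),
      service_id = tokenize(vocab, "service", case$service),
      location_id = tokenize(vocab, "location", case$location),
      urgency_id = tokenize(vocab, "urgency", case$urgency),
      procedure_ids = tokenize(vocab, "procedure",
                               strsplit(tolower(case$procedure_name), "\\s+")[[1]])
    ),
    events = events, meds = meds, flowsheet = flow,
    label = case$actual_duration,
    vocab_md5 = vocab$md5
  ), class = "or_snapshot")
}

#' @export
print.or_snapshot <- function(x, ...) {
  cat(sprintf("<or_snapshot> %s t=%d: %d events, %d meds, %d flowsheet points\n",
              x$case_id, x$t, length(x$events$id), length(x$meds$id),
              sum(vapply(x$flowsheet, function(f) length(f$value), integer(1)))))
  invisible(x)
}

#' Replay every in-window minute of a cohort
#'
#' Yields one snapshot per case per prediction minute (all of `1..D` when no
#' capture log is given, otherwise only minutes inside the live operating
#' window), ordered chronologically within case. A fully in-window case of
#' duration D yields exactly `floor(D)` snapshots.
#'
#' @param cases Case table (only rows with `captured == TRUE` are replayed if
#'   that column is present).
#' @param observations Observation table.
#' @param vocab Frozen [or_vocab].
#' @param capture_log Optional capture log from [apply_operating_window()].
#' @param lookback Flowsheet lookback in minutes.
#' @return List of `or_snapshot` objects.
#' @export
snapshot_stream <- function(cases, observations, vocab, capture_log = NULL,
                            lookback = 120) {
  if ("captured" %in% names(cases)) cases <- cases[cases$captured, , drop = FALSE]
  out <- vector("list", 0L)
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, , drop = FALSE]
    obs_i <- observations[observations$case_id == case$case_id, , drop = FALSE]
    mins <- prediction_minutes(case$anaesthesia_start, case$actual_duration,
                               capture_log)
    snaps <- lapply(mins, function(t) replay(case, obs_i, t, vocab, lookback))
    out <- c(out, snaps)
  }
  out
}

# Canonical plain-list form used for JSONL persistence.
#' @noRd
snapshot_to_list <- function(s) {
  list(case_id = s$case_id, t = s$t, label = s$label,
       preop = s$preop, events = s$events, meds = s$meds,
       flowsheet = s$flowsheet, vocab_md5 = s$vocab_md5)
}

#' @noRd
snapshot_from_list <- function(x) {
  ivec <- function(v) as.integer(unlist(v))
  nvec <- function(v) as.numeric(unlist(v))
  flow <- list()
  for (ch in or_flowsheet_channels()) {
    f <- x$flowsheet[[ch]]
    older_val <- if (is.null(f$older$value)) NA_real_ else as.numeric(f$older$value)
    older_off <- if (is.null(f$older$offset)) NA_integer_ else as.integer(f$older$offset)
    flow[[ch]] <- list(value = nvec(f$value), offset = ivec(f$offset),
                       older = list(value = older_val, offset = older_off))
  }
  structure(list(
    case_id = as.character(x$case_id), t = as.integer(x$t),
    preop = list(
      hospital = as.character(x$preop$hospital),
      service = as.character(x$preop$service),
      location = as.character(x$preop$location),
      urgency = as.character(x$preop$urgency),
      scheduled_duration = as.numeric(x$preop$scheduled_duration),
      hospital_id = as.integer(x$preop$hospital_id),
      service_id = as.integer(x$preop$service_id),
      location_id = as.integer(x$preop$location_id),
      urgency_id = as.integer(x$preop$urgency_id),
      procedure_ids = ivec(x$preop$procedure_ids)
    ),
    events = list(id = ivec(x$events$id), offset = ivec(x$events$offset)),
    meds = list(id = ivec(x$meds$id), action = ivec(x$meds$action),
                offset = ivec(x$meds$offset)),
    flowsheet = flow,
    label = as.numeric(x$label),
    vocab_md5 = if (is.null(x$vocab_md5)) NULL else as.character(x$vocab_md5)
  ), class = "or_snapshot")
}

#' Persist / load snapshots as JSON Lines
#'
#' One snapshot per line; `read_snapshots(persist_snapshots(x))` reproduces
#' the snapshots exactly, so offline scoring of stored tensors matches the
#' live computation.
#'
#' @param snapshots List of `or_snapshot` objects (may be empty).
#' @param path File path.
#' @return `persist_snapshots` returns `path` invisibly; `read_snapshots`
#'   the list of snapshots.
#' @export
persist_snapshots <- function(snapshots, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (s in snapshots) {
    writeLines(jsonlite::toJSON(snapshot_to_list(s), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' @rdname persist_snapshots
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    snapshot_from_list(jsonlite::fromJSON(l, simplifyVector = TRUE))
  })
}
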