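#' Generate a synthetic surgical case table
#'
#' Draws one row per anaesthetic: hospital, anaesthetising location, surgical
#' service, urgency, a free-text procedure name from a template grammar, the
#' scheduled start/end times, and the true anaesthesia start/stop times.
#' Scheduled duration is drawn per-service from a log-normal; actual duration
#' follows the configured linear link
#' `actual = slope * scheduled + intercept + N(0, sd)`, so an ordinary
#' least-squares bias correction of the schedule has a recoverable truth.
#' Deterministic given the config seed.
#'
#' @param config An [or_sim_config].
#' @return A data.frame with one row per case: `case_id`, `hospital`,
#'   `location`, `service`, `urgency`, `procedure_name`, `scheduled_start`,
#'   `scheduled_end`, `scheduled_duration`, `anaesthesia_start`,
#'   `anaesthesia_stop`, `actual_duration` (minutes, whole).
#' @export
generate_cases <- function(config) {
  validate_sim_config(config)
  set.seed(or_derive_seed(config$seed, 1L))

  days <- config$start_date + 0:(config$n_days - 1L)
  wday <- as.POSIXlt(days)$wday                 # 0 = Sunday
  vol <- ifelse(wday %in% 1:5, config$cases_per_weekday,
                config$cases_per_weekend_day)
  if (is.null(config$n_cases)) {
    n_day <- stats::rpois(length(days), vol)
  } else {
    n_day <- as.vector(stats::rmultinom(1, config$n_cases, vol))
  }
  n <- sum(n_day)
  if (n == 0L) or_stopf("configuration produced zero cases")
  case_day <- rep(days, n_day)

  svc_names <- names(config$services)
  svc_w <- vapply(config$services, `[[`, numeric(1), "weight")
  service <- or_sample(svc_names, n, svc_w)
  hospital <- or_sample(names(config$hospitals), n, config$hospitals)
  location <- sprintf("OR_%02d",
                      or_sample(seq_len(config$n_locations), n,
                                1 / seq_len(config$n_locations)))
  urgency <- ifelse(stats::runif(n) < config$urgency_elective_prob,
                    "elective", "non-elective")

  # Scheduled duration per service; actual through the linear link.
  sl <- config$schedule_link
  med_a <- vapply(config$services, `[[`, numeric(1), "median")[service]
  sdl <- vapply(config$services, `[[`, numeric(1), "sdlog")[service]
  dl <- config$duration_limits
  med_s <- pmax((med_a - sl$intercept) / sl$slope, 10)
  sched <- stats::rlnorm(n, meanlog = log(med_s), sdlog = sdl)
  sched <- round(pmin(pmax(sched, dl[1]), dl[2]))
  actual <- sl$slope * sched + sl$intercept + stats::rnorm(n, 0, sl$sd)
  actual <- round(pmin(pmax(actual, dl[1]), dl[2]))

  # Start times: mostly morning/afternoon, a configurable off-hours tail.
  off <- stats::runif(n) < config$off_hours_prob
  hr_in <- 7 + 11.5 * stats::rbeta(n, 1.5, 2.6)
  u <- stats::runif(n, 0, 11)
  hr_off <- ifelse(u < 5, 19 + u, u - 5)
  start_hr <- ifelse(off, hr_off, hr_in)
  sched_start <- as.POSIXct(case_day, tz = .or_tz) +
    round(start_hr * 12) / 12 * 3600        # 5-min scheduling grid
  anae_start <- sched_start + 60 * pmax(round(stats::rnorm(n, 5, 12)), -15)

  side <- or_sample(c("left", "right", "bilateral", ""), n,
                    c(0.28, 0.28, 0.05, 0.39))
  organ <- vapply(service, function(s) sample(.or_organs[[s]], 1), character(1))
  verb <- sample(c("resection", "repair", "replacement", "excision", "biopsy",
                   "bypass", "fusion", "release", "reconstruction"), n,
                 replace = TRUE)
  pname <- toupper(trimws(paste(side, organ, verb)))

  out <- data.frame(
    case_id = sprintf("C%06d", seq_len(n)),
    hospital = hospital, location = location, service = service,
    urgency = urgency, procedure_name = pname,
    scheduled_start = sched_start,
    scheduled_end = sched_start + sched * 60,
    scheduled_duration = sched,
    anaesthesia_start = anae_start,
    anaesthesia_stop = anae_start + actual * 60,
    actual_duration = actual,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$anaesthesia_start, out$case_id), ]
  out$case_id <- sprintf("C%06d", seq_len(n))
  rownames(out) <- NULL
  out
}

.or_organs <- list(
  general_surgery = c("colon", "gallbladder", "hernia", "appendix", "stomach", "thyroid"),
  orthopaedics = c("knee", "hip", "shoulder", "femur", "ankle", "wrist"),
  gynaecology = c("uterus", "ovary", "cervix", "fallopian tube"),
  urology = c("kidney", "bladder", "prostate", "ureter"),
  otolaryngology = c("tonsil", "sinus", "larynx", "ear", "septum"),
  ophthalmology = c("cataract", "retina", "cornea", "eyelid"),
  neurosurgery = c("craniotomy", "lumbar spine", "cervical spine", "pituitary"),
  plastics = c("breast", "skin flap", "hand", "scar"),
  vascular = c("aorta", "carotid", "femoral artery", "av fistula"),
  cardiothoracic = c("coronary artery", "mitral valve", "aortic valve", "lung lobe"),
  gastroenterology = c("oesophagus", "duodenum", "bile duct", "colon polyp")
)

# End-of-case signature labels used by the generator; exported as constants
# so downstream feature extraction names the same tokens.
#' Labels of end-of-case signature observations
#' @return Named list with `reversal_meds`, `antiemetic_meds`,
#'   `emergence_events`.
#' @export
or_signature_labels <- function() {
  list(reversal_meds = c("sugammadex", "neostigmine"),
       antiemetic_meds = "ondansetron",
       emergence_events = "emergence")
}

#' Flowsheet channel names
#' @return Character vector of the six per-minute flowsheet channels.
#' @export
or_flowsheet_channels <- function() {
  c("exp_sevoflurane", "exp_desflurane", "exp_n2o", "fio2", "bis", "heart_rate")
}

#' Generate intraoperative observation streams
#'
#' For each case, emits per-minute flowsheet observations on the six
#' channels (expired sevoflurane / desflurane / nitrous oxide, inspired
#' oxygen fraction, bispectral index, heart rate), start-of-case events and
#' medications (induction, intubation, induction agents, antibiotics), and
#' the end-of-case signature: a neuromuscular reversal agent, an antiemetic,
#' and an emergence event, each charted uniformly 5-15 whole minutes before
#' anaesthesia stop. Expired-agent channels wash out toward zero over the
#' final minutes and the bispectral index rises, so the remaining duration
#' becomes learnable near case end. Some minutes are deliberately missing
#' (pre-induction BIS, first-minute agent readings) to exercise downstream
#' missing-value handling.
#'
#' Charted times fall on whole minutes `anaesthesia_start + m` for
#' `m = 1..actual_duration`; `ingest_time` is left `NA` until
#' [inject_latency()] is applied.
#'
#' @param cases Case table from [generate_cases()].
#' @param config The same [or_sim_config].
#' @return A data.frame of observations: `case_id`, `stream` (event /
#'   medication / flowsheet), `name`, `action` (medications only), `value`
#'   (flowsheet only), `charted_time`, `ingest_time` (NA).
#' @export
generate_streams <- function(cases, config) {
  validate_sim_config(config)
  set.seed(or_derive_seed(config$seed, 2L))
  n <- nrow(cases)
  sig <- or_signature_labels()

  acc <- vector("list", n)
  for (i in seq_len(n)) {
    D <- cases$actual_duration[i]
    m <- seq_len(D)
    agent <- sample(c("sevo", "des", "tiva"), 1, prob = c(0.70, 0.20, 0.10))
    use_n2o <- agent != "tiva" && stats::runif(1) < 0.15

    # --- flowsheet ---------------------------------------------------------
    hr <- 72 + as.numeric(stats::filter(stats::rnorm(D, 0, 3.5), 0.85,
                                        method = "recursive"))
    hr <- round(pmin(pmax(hr, 40), 140))

    bis <- 45 + stats::rnorm(D, 0, 2.5)
    if (D > 7) {
      tail_idx <- (D - 4):D
      bis[tail_idx] <- bis[tail_idx] + seq(6, 30, length.out = 5)
    }
    bis <- round(pmin(pmax(bis, 20), 98))
    bis_keep <- m > 2                          # pre-induction BIS not charted

    ramp <- pmin(1, pmax(0, (m - 2) / 6))
    wash <- rep(1, D)
    if (D > 9) {
      wi <- m > D - 8
      wash[wi] <- exp(-(m[wi] - (D - 8)) / 3)
    }
    sevo <- if (agent == "sevo") pmax(2.0 * ramp * wash + stats::rnorm(D, 0, 0.08), 0) else rep(0, D)
    des <- if (agent == "des") pmax(6.0 * ramp * wash + stats::rnorm(D, 0, 0.2), 0) else rep(0, D)
    n2o <- if (use_n2o) pmax(50 * pmin(1, pmax(0, (m - 4) / 4)) * wash + stats::rnorm(D, 0, 1.5), 0) else rep(0, D)
    agent_keep <- m > 1                        # first-minute agent reading missing

    fio2 <- 0.4 + stats::rnorm(D, 0, 0.02)
    fio2[m <= 4] <- 0.8 + stats::rnorm(sum(m <= 4), 0, 0.02)
    if (D > 8) fio2[m > D - 4] <- 0.8 + stats::rnorm(sum(m > D - 4), 0, 0.02)
    fio2 <- round(pmin(pmax(fio2, 0.21), 1), 2)

    fl_min <- c(m, m[bis_keep], m[agent_keep], m[agent_keep], m[agent_keep], m)
    fl_name <- c(rep("heart_rate", D), rep("bis", sum(bis_keep)),
                 rep("exp_sevoflurane", sum(agent_keep)),
                 rep("exp_desflurane", sum(agent_keep)),
                 rep("exp_n2o", sum(agent_keep)), rep("fio2", D))
    fl_val <- c(hr, bis[bis_keep], round(sevo[agent_keep], 2),
                round(des[agent_keep], 2), round(n2o[agent_keep], 1), fio2)

    # --- events ------------------------------------------------------------
    ev_name <- "induction"; ev_min <- 1L
    if (D >= 6) { ev_name <- c(ev_name, "intubation"); ev_min <- c(ev_min, sample(3:6, 1)) }
    if (D >= 35) { ev_name <- c(ev_name, "incision"); ev_min <- c(ev_min, sample(12:25, 1)) }
    ev_name <- c(ev_name, sig$emergence_events)
    ev_min <- c(ev_min, max(1L, D - sample(5:15, 1)))

    # --- medications -------------------------------------------------------
    md_name <- c("propofol", "fentanyl"); md_min <- c(1L, 1L)
    md_act <- c("given", "given")
    if (D >= 20 && stats::runif(1) < 0.8) {
      md_name <- c(md_name, "rocuronium"); md_min <- c(md_min, 2L); md_act <- c(md_act, "given")
    }
    if (stats::runif(1) < 0.7) {
      md_name <- c(md_name, "cefazolin"); md_min <- c(md_min, min(3L, D)); md_act <- c(md_act, "given")
    }
    n_phe <- stats::rpois(1, D / 45)
    if (n_phe > 0) {
      md_name <- c(md_name, rep("phenylephrine", n_phe))
      md_min <- c(md_min, sample(seq_len(D), n_phe, replace = TRUE))
      md_act <- c(md_act, sample(c("given", "rate_adjustment"), n_phe,
                                 replace = TRUE, prob = c(0.6, 0.4)))
    }
    if (agent == "tiva") {
      n_adj <- max(1L, stats::rpois(1, D / 60))
      md_name <- c(md_name, rep("propofol", n_adj))
      md_min <- c(md_min, sample(seq_len(D), n_adj, replace = TRUE))
      md_act <- c(md_act, rep("rate_adjustment", n_adj))
    }
    md_name <- c(md_name, sample(sig$reversal_meds, 1), sig$antiemetic_meds)
    md_min <- c(md_min, max(1L, D - sample(5:15, 1)), max(1L, D - sample(5:15, 1)))
    md_act <- c(md_act, "given", "given")

    acc[[i]] <- list(
      minute = c(fl_min, ev_min, md_min),
      stream = c(rep("flowsheet", length(fl_min)), rep("event", length(ev_min)),
                 rep("medication", length(md_min))),
      name = c(fl_name, ev_name, md_name),
      action = c(rep(NA_character_, length(fl_min) + length(ev_min)), md_act),
      value = c(fl_val, rep(NA_real_, length(ev_min) + length(md_min)))
    )
  }

  len <- vapply(acc, function(a) length(a$minute), integer(1))
  minute <- unlist(lapply(acc, `[[`, "minute"), use.names = FALSE)
  obs <- data.frame(
    case_id = rep(cases$case_id, len),
    stream = unlist(lapply(acc, `[[`, "stream"), use.names = FALSE),
    name = unlist(lapply(acc, `[[`, "name"), use.names = FALSE),
    action = unlist(lapply(acc, `[[`, "action"), use.names = FALSE),
    value = unlist(lapply(acc, `[[`, "value"), use.names = FALSE),
    charted_time = rep(cases$anaesthesia_start, len) + 60 * minute,
    stringsAsFactors = FALSE
  )
  obs$ingest_time <- as.POSIXct(rep(NA_real_, nrow(obs)), tz = .or_tz,
                                origin = "1970-01-01")
  ord <- order(obs$case_id, obs$charted_time, obs$stream, obs$name)
  obs <- obs[ord, ]
  rownames(obs) <- NULL
  obs
}

#' Apply EHR-to-ingestion latency to an observation stream
#'
#' Sets `ingest_time = charted_time + max(0, N(mean, sd))` minutes with the
#' per-stream-type latency parameters of the config (defaults: 3.22/1.13 min
#' for medications, 3.26/1.17 for events, 2.72/1.08 for flowsheet data).
#' Latency is truncated at zero: nothing is ingestible before it is charted.
#' Deterministic given the config seed.
#'
#' @param observations Observation table with `ingest_time` unset (all NA).
#' @param config An [or_sim_config].
#' @return The observation table with `ingest_time` filled in.
#' @export
inject_latency <- function(observations, config) {
  validate_sim_config(config)
  if (!all(is.na(observations$ingest_time)))
    or_stopf("observations already carry ingest_time; latency must be injected once")
  set.seed(or_derive_seed(config$seed, 3L))
  lat <- numeric(nrow(observations))
  for (s in c("event", "medication", "flowsheet")) {
    idx <- which(observations$stream == s)
    p <- config$latency_model[[s]]
    lat[idx] <- pmax(0, stats::rnorm(length(idx), p[["mean"]], p[["sd"]]))
  }
  observations$ingest_time <- observations$charted_time + lat * 60
  observations
}

#' Apply the pipeline operating window and downtime censoring
#'
#' The data pipeline runs Monday-Friday between `window_start` and
#' `window_end`, with each in-window hour independently lost to downtime
#' with probability `downtime_prob`. A case is captured if at least one of
#' its elapsed minutes falls inside the live window; cases entirely outside
#' (weekends, overnight cases) or entirely inside downtime are flagged
#' not-captured. Predictions are later made only at captured in-window
#' minutes.
#'
#' @param observations Observation table (latency already injected).
#' @param cases Case table.
#' @param config An [or_sim_config].
#' @return An object of class `or_capture`: list with `cases` (plus logical
#'   `captured` column), `observations` (captured cases only), and
#'   `capture_log` (downtime table, window bounds, capture fraction).
#' @export
apply_operating_window <- function(observations, cases, config) {
  validate_sim_config(config)
  set.seed(or_derive_seed(config$seed, 4L))
  ws <- or_parse_clock(config$window_start, "window_start")
  we <- or_parse_clock(config$window_end, "window_end")

  d0 <- min(as.Date(cases$anaesthesia_start))
  d1 <- max(as.Date(cases$anaesthesia_stop)) + 1
  all_days <- seq(d0, d1, by = "day")
  hours <- seq(floor(ws), ceiling(we) - 1L)
  grid <- expand.grid(date = all_days, hour = hours)
  down <- grid[stats::runif(nrow(grid)) < config$downtime_prob, , drop = FALSE]
  rownames(down) <- NULL

  capture_log <- list(window_start = ws, window_end = we,
                      downtime = down,
                      downtime_keys = paste(down$date, down$hour))

  captured <- vapply(seq_len(nrow(cases)), function(i) {
    length(prediction_minutes(cases$anaesthesia_start[i],
                              cases$actual_duration[i], capture_log)) > 0L
  }, logical(1))

  cases$captured <- captured
  keep_ids <- cases$case_id[captured]
  capture_log$n_cases <- nrow(cases)
  capture_log$n_captured <- sum(captured)
  capture_log$capture_fraction <- mean(captured)

  structure(list(cases = cases,
                 observations = observations[observations$case_id %in% keep_ids, ],
                 capture_log = capture_log),
            class = "or_capture")
}

#' @export
print.or_capture <- function(x, ...) {
  cl <- x$capture_log
  cat(sprintf("<or_capture> %d / %d cases captured (%.1f%%), %d downtime hours\n",
              cl$n_captured, cl$n_cases, 100 * cl$capture_fraction,
              nrow(cl$downtime)))
  invisible(x)
}

#' In-window prediction minutes of one case
#'
#' Elapsed minutes `t = 1..actual_duration` at which the pipeline is live:
#' the wall-clock time `anaesthesia_start + t` falls on a weekday inside the
#' operating window and outside any downtime hour.
#'
#' @param start Anaesthesia start (POSIXct).
#' @param duration Actual duration in whole minutes.
#' @param capture_log The `capture_log` of an [apply_operating_window()]
#'   result, or `NULL` for no censoring (all minutes).
#' @return Integer vector of prediction minutes (possibly empty).
#' @export
prediction_minutes <- function(start, duration, capture_log = NULL) {
  t <- seq_len(duration)
  if (is.null(capture_log)) return(t)
  tm <- start + 60 * t
  lt <- as.POSIXlt(tm, tz = .or_tz)
  hrfrac <- lt$hour + lt$min / 60
  ok <- lt$wday %in% 1:5 & hrfrac >= capture_log$window_start &
    hrfrac < capture_log$window_end
  if (length(capture_log$downtime_keys)) {
    key <- paste(as.Date(tm, tz = .or_tz), lt$hour)
    ok <- ok & !(key %in% capture_log$downtime_keys)
  }
  t[ok]
}

#' Simulate a full operating-room dataset
#'
#' Convenience wrapper: [generate_cases()], [generate_streams()],
#' [inject_latency()], [apply_operating_window()].
#'
#' @param config An [or_sim_config].
#' @return An `or_capture` object (cases, observations, capture log).
#' @export
or_simulate <- function(config) {
  cases <- generate_cases(config)
  obs <- generate_streams(cases, config)
  obs <- inject_latency(obs, config)
  apply_operating_window(obs, cases, config)
}
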