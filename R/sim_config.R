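#' Configuration of the synthetic operating-room generator
#'
#' Defines the study conditions the generator emulates: a multi-hospital
#' surgical population with per-service duration distributions, a linear link
#' between scheduled and actual duration (so a bias-corrected benchmark has a
#' recoverable truth), per-stream EHR ingestion latency, and a weekday
#' operating window with sporadic downtime that censors capture.
#'
#' Defaults are calibrated so the simulated population resembles a large
#' four-hospital anaesthetic case mix: overall median duration around 80 min,
#' mean around 115 min, per-prediction ingestion latency near 3 min, and a
#' capture fraction near 74% of cases once the weekday 07:00-19:00 window and
#' downtime are applied.
#'
#' @param n_days Number of calendar days simulated.
#' @param start_date First simulated day (`Date` or "YYYY-MM-DD"); defaults to
#'   a Monday.
#' @param n_cases Optional total case count; if `NULL`, daily counts are
#'   Poisson with means `cases_per_weekday` / `cases_per_weekend_day`.
#' @param cases_per_weekday,cases_per_weekend_day Mean daily case volume.
#' @param hospitals Named numeric vector of hospital case-volume weights
#'   (normalized internally).
#' @param services Named list; each element a list with `weight`, `median`
#'   (median actual duration, minutes) and `sdlog` (log-scale dispersion of
#'   the per-service log-normal).
#' @param n_locations Number of anaesthetising locations (volume skewed
#'   proportional to 1/rank).
#' @param urgency_elective_prob Probability a case is elective.
#' @param schedule_link List with `slope`, `intercept` (minutes) and `sd`
#'   (minutes): actual duration = slope * scheduled + intercept + N(0, sd).
#' @param off_hours_prob Probability a case starts outside 07:00-19:00
#'   (evening/night starts, largely uncaptured).
#' @param latency_model Named list with elements `event`, `medication`,
#'   `flowsheet`, each `c(mean, sd)` in minutes, for the EHR-to-ingestion
#'   delay.
#' @param window_start,window_end Pipeline operating window clock hours
#'   ("HH:MM"), weekdays only.
#' @param downtime_prob Probability a given weekday in-window hour is lost to
#'   pipeline downtime.
#' @param duration_limits Length-2 vector `c(min, max)` of minutes to which
#'   scheduled and actual durations are clamped. The default floor of 15 min
#'   reflects that anaesthesia time includes induction and emergence; note
#'   the floor truncates the scheduled-to-actual linear link near the
#'   boundary.
#' @param seed Integer master seed; every generator stage derives its own
#'   stream from it.
#' @return An object of class `or_sim_config`.
#' @examples
#' cfg <- or_sim_config(n_days = 5, n_cases = 50, seed = 1)
#' cases <- generate_cases(cfg)
#' @export
or_sim_config <- function(n_days = 35,
                          start_date = "2022-10-03",
                          n_cases = NULL,
                          cases_per_weekday = 46,
                          cases_per_weekend_day = 9,
                          hospitals = c(academic_adult = 0.58,
                                        academic_paediatric = 0.16,
                                        community_a = 0.20,
                                        community_b = 0.06),
                          services = or_default_services(),
                          n_locations = 12,
                          urgency_elective_prob = 0.85,
                          schedule_link = list(slope = 0.987,
                                               intercept = -4.419,
                                               sd = 20),
                          off_hours_prob = 0.20,
                          latency_model = list(event = c(mean = 3.26, sd = 1.17),
                                               medication = c(mean = 3.22, sd = 1.13),
                                               flowsheet = c(mean = 2.72, sd = 1.08)),
                          window_start = "07:00",
                          window_end = "19:00",
                          downtime_prob = 0.18,
                          duration_limits = c(15, 1080),
                          seed = 20221001) {
  cfg <- list(
    n_days = n_days, start_date = as.Date(start_date), n_cases = n_cases,
    cases_per_weekday = cases_per_weekday,
    cases_per_weekend_day = cases_per_weekend_day,
    hospitals = hospitals, services = services, n_locations = n_locations,
    urgency_elective_prob = urgency_elective_prob,
    schedule_link = schedule_link, off_hours_prob = off_hours_prob,
    latency_model = latency_model,
    window_start = window_start, window_end = window_end,
    downtime_prob = downtime_prob, duration_limits = duration_limits,
    seed = as.integer(seed)
  )
  class(cfg) <- "or_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-service duration parameters
#'
#' Ten surgical services with case-volume weights and log-normal actual
#' durations whose mixture median/mean sit near 80/115 min.
#' @return Named list of per-service parameter lists.
#' @export
or_default_services <- function() {
  list(
    general_surgery  = list(weight = 0.20, median = 85,  sdlog = 0.62),
    orthopaedics     = list(weight = 0.16, median = 95,  sdlog = 0.60),
    gynaecology      = list(weight = 0.10, median = 70,  sdlog = 0.58),
    urology          = list(weight = 0.10, median = 65,  sdlog = 0.62),
    otolaryngology   = list(weight = 0.09, median = 50,  sdlog = 0.60),
    ophthalmology    = list(weight = 0.08, median = 35,  sdlog = 0.45),
    neurosurgery     = list(weight = 0.07, median = 160, sdlog = 0.60),
    plastics         = list(weight = 0.06, median = 85,  sdlog = 0.62),
    vascular         = list(weight = 0.06, median = 120, sdlog = 0.65),
    cardiothoracic   = list(weight = 0.05, median = 230, sdlog = 0.55),
    gastroenterology = list(weight = 0.03, median = 40,  sdlog = 0.50)
  )
}

#' @noRd
validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      or_stopf("invalid configuration: '%s' must be a probability in [0, 1]", field)
  }
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      or_stopf("invalid configuration: '%s' must be a positive number", field)
  }
  chk_pos(cfg$n_days, "n_days")
  chk_pos(cfg$cases_per_weekday, "cases_per_weekday")
  chk_pos(cfg$n_locations, "n_locations")
  chk_prob(cfg$urgency_elective_prob, "urgency_elective_prob")
  chk_prob(cfg$off_hours_prob, "off_hours_prob")
  chk_prob(cfg$downtime_prob, "downtime_prob")
  if (!is.numeric(cfg$hospitals) || is.null(names(cfg$hospitals)) ||
      any(cfg$hospitals < 0) || sum(cfg$hospitals) <= 0)
    or_stopf("invalid configuration: 'hospitals' must be a named nonnegative weight vector")
  for (s in names(cfg$services)) {
    p <- cfg$services[[s]]
    if (!all(c("weight", "median", "sdlog") %in% names(p)))
      or_stopf("invalid configuration: 'services$%s' needs weight, median, sdlog", s)
    if (p$weight < 0) or_stopf("invalid configuration: 'services$%s$weight' must be >= 0", s)
    if (p$median <= 0) or_stopf("invalid configuration: 'services$%s$median' must be > 0", s)
    if (p$sdlog < 0) or_stopf("invalid configuration: 'services$%s$sdlog' must be >= 0", s)
  }
  sl <- cfg$schedule_link
  if (!all(c("slope", "intercept", "sd") %in% names(sl)))
    or_stopf("invalid configuration: 'schedule_link' needs slope, intercept, sd")
  if (sl$slope <= 0) or_stopf("invalid configuration: 'schedule_link$slope' must be > 0")
  if (sl$sd < 0) or_stopf("invalid configuration: 'schedule_link$sd' must be >= 0")
  for (s in c("event", "medication", "flowsheet")) {
    lm_ <- cfg$latency_model[[s]]
    if (is.null(lm_) || length(lm_) < 2L || lm_[["sd"]] < 0)
      or_stopf("invalid configuration: 'latency_model$%s' must be c(mean, sd) with sd >= 0", s)
  }
  dl <- cfg$duration_limits
  if (!is.numeric(dl) || length(dl) != 2L || dl[1] < 1 || dl[1] >= dl[2])
    or_stopf("invalid configuration: 'duration_limits' must be c(min, max) with 1 <= min < max")
  ws <- or_parse_clock(cfg$window_start, "window_start")
  we <- or_parse_clock(cfg$window_end, "window_end")
  if (ws >= we)
    or_stopf("invalid configuration: 'window_start' must be before 'window_end'")
  if (is.na(cfg$seed))
    or_stopf("invalid configuration: 'seed' must be an integer")
  invisible(cfg)
}

# "HH:MM" -> fractional hours
#' @noRd
or_parse_clock <- function(x, field) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L)
    or_stopf("invalid configuration: '%s' must be 'HH:MM'", field)
  as.numeric(m[2]) + as.numeric(m[3]) / 60
}

#' @export
print.or_sim_config <- function(x, ...) {
  cat(sprintf("<or_sim_config> %d days from %s, %d hospitals, %d services, seed %d\n",
              x$n_days, format(x$start_date), length(x$hospitals),
              length(x$services), x$seed))
  cat(sprintf("  window %s-%s weekdays, downtime/hour %.2f, off-hours starts %.2f\n",
              x$window_start, x$window_end, x$downtime_prob, x$off_hours_prob))
  invisible(x)
}
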