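# Shared fixtures and independent oracles, all built in code.

# Exact CRPS of a discrete distribution by the pairwise-expectation identity
# CRPS(F, y) = E|X - y| - 0.5 E|X - X'| (brute-force double sum; independent
# of the package's piecewise integration).
crps_oracle_pair <- function(support, probs, y) {
  sum(probs * abs(support - y)) -
    0.5 * sum(outer(probs, probs) * abs(outer(support, support, `-`)))
}

# Numeric integration of (F(x) - 1{x >= y})^2 on a fine trapezoid grid.
crps_oracle_trap <- function(support, probs, y, h = 0.001) {
  lo <- min(support, y) - 1
  hi <- max(support, y) + 1
  x <- seq(lo, hi, by = h)
  Fx <- vapply(x, function(v) sum(probs[support <= v]), numeric(1))
  H <- as.numeric(x >= y)
  f <- (Fx - H)^2
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

random_distribution <- function(max_bins = 50, span = 500) {
  K <- sample(2:max_bins, 1)
  edges <- sort(stats::runif(K + 1, 0, span))
  while (any(diff(edges) <= 0)) edges <- sort(stats::runif(K + 1, 0, span))
  p <- stats::rexp(K)
  duration_distribution(edges, p / sum(p))
}

# Small fast simulation config.
tiny_sim <- function(seed = 99, n_days = 6, cases_per_weekday = 12,
                     cases_per_weekend_day = 3, ...) {
  or_sim_config(n_days = n_days, cases_per_weekday = cases_per_weekday,
                cases_per_weekend_day = cases_per_weekend_day,
                seed = seed, ...)
}

# Hand-built one-row case table.
make_case <- function(case_id = "C000001", start = "2022-10-03 08:00:00",
                      duration = 60, sched = duration,
                      hospital = "academic_adult", service = "general_surgery",
                      urgency = "elective", procedure = "LEFT COLON RESECTION",
                      location = "OR_01") {
  st <- as.POSIXct(start, tz = "UTC")
  data.frame(case_id = case_id, hospital = hospital, location = location,
             service = service, urgency = urgency, procedure_name = procedure,
             scheduled_start = st, scheduled_end = st + sched * 60,
             scheduled_duration = sched,
             anaesthesia_start = st, anaesthesia_stop = st + duration * 60,
             actual_duration = duration, stringsAsFactors = FALSE)
}

empty_obs <- function() {
  data.frame(case_id = character(0), stream = character(0),
             name = character(0), action = character(0), value = numeric(0),
             charted_time = as.POSIXct(character(0), tz = "UTC"),
             ingest_time = as.POSIXct(character(0), tz = "UTC"))
}

# One observation row builder (minutes are offsets from the case start).
make_obs <- function(case, minute, stream, name, action = NA_character_,
                     value = NA_real_, latency_min = 0) {
  ct <- case$anaesthesia_start + minute * 60
  data.frame(case_id = case$case_id, stream = stream, name = name,
             action = action, value = value, charted_time = ct,
             ingest_time = ct + latency_min * 60, stringsAsFactors = FALSE)
}

# Cohort of constant-duration cases with no intraoperative data; used for
# degenerate-target model fits.
constant_cases <- function(n = 40, duration = 60) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_case(case_id = sprintf("C%06d", i), duration = duration)
  }))
}

# Independent brute-force reconstruction of the observation set visible at
# minute t (used against replay()).
visible_by_ingest <- function(case, observations, t) {
  obs <- observations[observations$case_id == case$case_id, , drop = FALSE]
  cut <- case$anaesthesia_start + t * 60
  obs[obs$ingest_time <= cut, , drop = FALSE]
}
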