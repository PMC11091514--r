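test_that("invalid configuration errors name the offending field", {
  expect_error(or_sim_config(urgency_elective_prob = 1.4), "urgency_elective_prob")
  expect_error(or_sim_config(downtime_prob = -0.1), "downtime_prob")
  expect_error(or_sim_config(window_start = "19:00", window_end = "07:00"),
               "window_start")
  expect_error(or_sim_config(schedule_link = list(slope = -1, intercept = 0, sd = 5)),
               "slope")
  bad_svc <- or_default_services()
  bad_svc$urology$median <- -4
  expect_error(or_sim_config(services = bad_svc), "urology")
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_sim(seed = 123)
  a <- or_simulate(cfg)
  b <- or_simulate(cfg)
  expect_identical(a$cases, b$cases)
  expect_identical(a$observations, b$observations)
  expect_identical(a$capture_log$downtime, b$capture_log$downtime)
  cfg2 <- tiny_sim(seed = 124)
  expect_false(identical(generate_cases(cfg)$actual_duration,
                         generate_cases(cfg2)$actual_duration))
})

test_that("a noiseless identity schedule link makes scheduled equal actual", {
  cfg <- tiny_sim(schedule_link = list(slope = 1, intercept = 0, sd = 0))
  cases <- generate_cases(cfg)
  expect_identical(cases$scheduled_duration, cases$actual_duration)
  expect_true(all(cases$actual_duration > 0))
  expect_equal(cases$actual_duration,
               as.numeric(difftime(cases$anaesthesia_stop,
                                   cases$anaesthesia_start, units = "mins")))
})

test_that("per-service and population duration distributions match the configured targets", {
  cfg <- or_sim_config(n_days = 60, seed = 12)
  cases <- generate_cases(cfg)
  expect_gt(nrow(cases), 1900)
  med_cfg <- vapply(cfg$services, `[[`, numeric(1), "median")
  n_svc <- table(cases$service)
  # 10% is ~2 median standard errors only once a service has a few hundred
  # cases; thinner services are covered by the population-level assertions
  for (s in names(med_cfg)[n_svc[names(med_cfg)] >= 200]) {
    emp <- stats::median(cases$actual_duration[cases$service == s])
    expect_lt(abs(emp - med_cfg[s]) / med_cfg[s], 0.10)
  }
  # Population shape near a large mixed surgical cohort: median around
  # 76-83 min and mean around 112-124 min, asserted within +/-20%.
  expect_gt(stats::median(cases$actual_duration), 76 * 0.8)
  expect_lt(stats::median(cases$actual_duration), 83 * 1.2)
  expect_gt(mean(cases$actual_duration), 112 * 0.8)
  expect_lt(mean(cases$actual_duration), 124 * 1.2)
})

test_that("latency injection honours its degenerate and default regimes", {
  cfg <- tiny_sim(latency_model = list(event = c(mean = 3, sd = 0),
                                       medication = c(mean = 3, sd = 0),
                                       flowsheet = c(mean = 3, sd = 0)))
  cases <- generate_cases(cfg)[1:20, ]
  obs <- inject_latency(generate_streams(cases, cfg), cfg)
  lag <- as.numeric(difftime(obs$ingest_time, obs$charted_time, units = "mins"))
  expect_equal(lag, rep(3, nrow(obs)))
  expect_error(inject_latency(obs, cfg), "already")

  cfg0 <- tiny_sim(latency_model = list(event = c(mean = 0, sd = 0),
                                        medication = c(mean = 0, sd = 0),
                                        flowsheet = c(mean = 0, sd = 0)))
  obs0 <- inject_latency(generate_streams(cases, cfg0), cfg0)
  expect_identical(obs0$ingest_time, obs0$charted_time)
})

test_that("default latency matches the configured per-stream means and is never negative", {
  cfg <- or_sim_config(n_days = 50, seed = 5)
  cases <- generate_cases(cfg)
  obs <- inject_latency(generate_streams(cases, cfg), cfg)
  lag <- as.numeric(difftime(obs$ingest_time, obs$charted_time, units = "mins"))
  expect_true(all(lag >= 0))
  med <- obs$stream == "medication"
  expect_gt(sum(med), 10000)
  expect_lt(abs(mean(lag[med]) - 3.22), 0.1)
  expect_lt(abs(mean(lag[obs$stream == "event"]) - 3.26), 0.1)
  expect_lt(abs(mean(lag[obs$stream == "flowsheet"]) - 2.72), 0.1)
})

test_that("flowsheet cadence is one observation per whole elapsed minute", {
  case <- make_case(duration = 10)
  cfg <- tiny_sim()
  obs <- generate_streams(case, cfg)
  hr <- obs[obs$name == "heart_rate", ]
  expect_equal(nrow(hr), 10)
  expect_equal(sort(as.numeric(difftime(hr$charted_time, case$anaesthesia_start,
                                        units = "mins"))), 1:10)
})

test_that("every case carries an end-of-case reversal signature 5-15 min before stop", {
  cfg <- or_sim_config(n_days = 15, seed = 8)
  cases <- generate_cases(cfg)
  cases <- cases[seq_len(min(nrow(cases), 600)), ]
  obs <- generate_streams(cases, cfg)
  rev <- obs[obs$name %in% or_signature_labels()$reversal_meds, ]
  expect_true(all(cases$case_id %in% rev$case_id))
  last_rev <- tapply(as.numeric(rev$charted_time), rev$case_id, max)
  stop_t <- as.numeric(cases$anaesthesia_stop)[match(names(last_rev), cases$case_id)]
  gap <- (stop_t - last_rev) / 60
  expect_true(all(gap >= 0 & gap <= 15))
  expect_gte(mean(gap), 5)
  expect_lte(mean(gap), 15)
})

test_that("the operating window captures weekday daytime cases and drops weekend cases", {
  cfg <- tiny_sim(seed = 31, off_hours_prob = 0, downtime_prob = 0,
                  cases_per_weekend_day = 0.001)
  cases <- generate_cases(cfg)
  wd <- as.POSIXlt(cases$anaesthesia_start)$wday
  cases <- cases[wd %in% 1:5, ]
  hr <- as.POSIXlt(cases$anaesthesia_start)$hour
  cases <- cases[hr >= 7 & hr < 18, ]
  cap <- apply_operating_window(empty_obs(), cases, cfg)
  expect_true(all(cap$cases$captured))

  sat <- make_case(start = "2022-10-08 10:00:00", duration = 90)  # a Saturday
  cap2 <- apply_operating_window(empty_obs(), sat, cfg)
  expect_false(any(cap2$cases$captured))
})

test_that("default downtime and off-hours settings give a capture fraction near 0.74", {
  cfg <- or_sim_config(n_days = 150, n_cases = 5000, seed = 17)
  cases <- generate_cases(cfg)
  cap <- apply_operating_window(empty_obs(), cases, cfg)
  expect_gt(cap$capture_log$capture_fraction, 0.74 - 0.05)
  expect_lt(cap$capture_log$capture_fraction, 0.74 + 0.05)
})

test_that("remaining duration is more predictable once a reversal agent is visible", {
  cfg <- or_sim_config(n_days = 50, seed = 21)
  cases <- generate_cases(cfg)
  cases <- cases[seq_len(min(nrow(cases), 1200)), ]
  obs <- inject_latency(generate_streams(cases, cfg), cfg)
  rev <- obs[obs$name %in% or_signature_labels()$reversal_meds, ]
  first_vis <- tapply(as.numeric(rev$ingest_time), rev$case_id, min)
  rem_all <- c(); rem_sig <- c()
  for (i in seq_len(nrow(cases))) {
    D <- cases$actual_duration[i]
    t <- seq_len(D)
    rem <- D - t
    rem_all <- c(rem_all, rem)
    v <- ceiling((first_vis[cases$case_id[i]] -
                    as.numeric(cases$anaesthesia_start[i])) / 60)
    rem_sig <- c(rem_sig, rem[t >= v])
  }
  expect_lt(stats::sd(rem_sig), stats::sd(rem_all))
})

test_that("case and observation tables survive an on-disk round trip", {
  cfg <- tiny_sim(seed = 3)
  cases <- generate_cases(cfg)[1:15, ]
  obs <- inject_latency(generate_streams(cases, cfg), cfg)
  fc <- tempfile(fileext = ".csv"); fo <- tempfile(fileext = ".jsonl")
  write_cases(cases, fc)
  back <- read_cases(fc)
  expect_equal(back, cases, tolerance = 1e-9)
  write_observations(obs, fo)
  obs2 <- read_observations(fo)
  expect_equal(obs2$value, obs$value)
  expect_equal(obs2$charted_time, obs$charted_time)
  expect_equal(as.numeric(obs2$ingest_time), as.numeric(obs$ingest_time),
               tolerance = 0.001)                     # millisecond precision
  expect_identical(names(obs2), c("case_id", "stream", "name", "action",
                                  "value", "charted_time", "ingest_time"))
})
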