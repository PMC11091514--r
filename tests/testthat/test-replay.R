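test_that("vocabulary construction is dense, reserved, frequency-ordered and thresholded", {
  case <- make_case()
  obs <- rbind(make_obs(case, 1, "event", "intubation"),
               make_obs(case, 50, "event", "emergence"))
  v <- build_vocab(case, obs)
  expect_equal(length(v$maps$event), 4)           # pad, unk, two events
  expect_equal(unname(v$maps$event[c("<pad>", "<unk>")]), c(0L, 1L))
  expect_setequal(names(v$maps$event), c("<pad>", "<unk>", "intubation", "emergence"))
  expect_equal(tokenize(v, "event", "aortic clamp applied"), 1L)

  obs_rare <- do.call(rbind, c(
    lapply(1:3, function(i) make_obs(case, i, "event", "rare_event")),
    lapply(1:6, function(i) make_obs(case, i + 3, "event", "intubation"))))
  v5 <- build_vocab(case, obs_rare, min_count = 5)
  expect_false("rare_event" %in% names(v5$maps$event))
  expect_equal(tokenize(v5, "event", "rare_event"), 1L)
  expect_equal(tokenize(v5, "event", "intubation"), 2L)
  expect_error(build_vocab(case[0, ], obs), "empty")
})

test_that("replay validates its inputs", {
  case <- make_case(duration = 30)
  obs <- make_obs(case, 5, "event", "induction")
  v <- build_vocab(case, obs)
  expect_error(replay(case, obs, 0, v), "out of range")
  expect_error(replay(case, obs, 31, v), "out of range")
  expect_error(replay(case[0, ], obs, 5, v), "unknown case")
})

test_that("visibility is governed by ingestion, not charting", {
  case <- make_case(duration = 30)
  obs <- rbind(make_obs(case, 1, "event", "induction", latency_min = 2),
               make_obs(case, 2, "medication", "propofol", action = "given",
                        latency_min = 2),
               make_obs(case, 1, "flowsheet", "heart_rate", value = 70,
                        latency_min = 2))
  v <- build_vocab(case, obs)
  s1 <- replay(case, obs, 1, v)
  expect_equal(length(s1$events$id) + length(s1$meds$id) +
                 sum(vapply(s1$flowsheet, function(f) length(f$value), integer(1))),
               0)
  expect_equal(s1$preop$scheduled_duration, case$scheduled_duration)

  # zero latency: everything charted in minutes 1..t is present at t
  obs0 <- rbind(make_obs(case, 3, "event", "induction"),
                make_obs(case, 7, "medication", "propofol", action = "given"),
                make_obs(case, 10, "flowsheet", "heart_rate", value = 80),
                make_obs(case, 11, "event", "intubation"))
  v0 <- build_vocab(case, obs0)
  s10 <- replay(case, obs0, 10, v0)
  expect_equal(length(s10$events$id), 1)
  expect_equal(length(s10$meds$id), 1)
  expect_equal(s10$flowsheet$heart_rate$value, 80)

  # charted minute 8, 3-minute latency: absent at t = 10, present at t = 11
  obs8 <- make_obs(case, 8, "event", "incision", latency_min = 3)
  v8 <- build_vocab(case, obs8)
  expect_equal(length(replay(case, obs8, 10, v8)$events$id), 0)
  expect_equal(length(replay(case, obs8, 11, v8)$events$id), 1)
  expect_equal(replay(case, obs8, 11, v8)$events$offset, 8L)
})

test_that("no snapshot ever contains an observation not yet ingested (brute force)", {
  cfg <- tiny_sim(seed = 61)
  cap <- or_simulate(cfg)
  cases <- cap$cases[cap$cases$captured, ]
  obs <- cap$observations
  v <- build_vocab(cases, obs)
  set.seed(77)
  for (k in 1:40) {
    i <- sample(nrow(cases), 1)
    case <- cases[i, , drop = FALSE]
    t <- sample(case$actual_duration, 1)
    snap <- replay(case, obs, t, v)
    ref <- visible_by_ingest(case, obs, t)
    expect_equal(length(snap$events$id), sum(ref$stream == "event"))
    expect_equal(length(snap$meds$id), sum(ref$stream == "medication"))
    # flowsheet: recent series must hold exactly the visible points inside
    # the lookback; anything older is summarized by its latest value
    for (ch in or_flowsheet_channels()) {
      ref_ch <- ref[ref$stream == "flowsheet" & ref$name == ch, ]
      off_ch <- floor(as.numeric(difftime(ref_ch$charted_time,
                                          case$anaesthesia_start,
                                          units = "mins")))
      recent <- off_ch > t - 120
      expect_equal(sort(snap$flowsheet[[ch]]$offset), sort(off_ch[recent]))
      expect_equal(!is.na(snap$flowsheet[[ch]]$older$value), any(!recent))
    }
    # event offsets match the brute-force charted minutes
    ev_ref <- sort(floor(as.numeric(difftime(
      ref$charted_time[ref$stream == "event"], case$anaesthesia_start,
      units = "mins"))))
    expect_equal(sort(as.numeric(snap$events$offset)), ev_ref)
    expect_true(all(snap$events$offset <= t))
    expect_true(all(snap$meds$offset <= t))
  }
})

test_that("the information set grows monotonically in elapsed time", {
  cfg <- tiny_sim(seed = 62)
  cap <- or_simulate(cfg)
  cases <- cap$cases[cap$cases$captured, ]
  v <- build_vocab(cases, cap$observations)
  case <- cases[which.max(cases$actual_duration >= 40), , drop = FALSE]
  prev <- 0
  for (t in seq_len(min(case$actual_duration, 60))) {
    s <- replay(case, cap$observations, t, v)
    n_now <- length(s$events$id) + length(s$meds$id) +
      sum(vapply(s$flowsheet, function(f) length(f$value), integer(1)))
    expect_gte(n_now, prev)
    prev <- n_now
  }
})

test_that("snapshot_stream yields one snapshot per in-window case-minute", {
  cfg <- tiny_sim(seed = 63, downtime_prob = 0)
  case <- make_case(duration = 90, start = "2022-10-03 09:00:00")  # Monday
  obs <- inject_latency(generate_streams(case, cfg), cfg)
  v <- build_vocab(case, obs)
  snaps <- snapshot_stream(case, obs, v)
  expect_length(snaps, 90)
  expect_equal(vapply(snaps, `[[`, integer(1), "t"), 1:90)

  # case running 18:30 - 19:30: only minutes before the 19:00 window close
  case2 <- make_case(case_id = "C000002", start = "2022-10-03 18:30:00",
                     duration = 60)
  obs2 <- inject_latency(generate_streams(case2, cfg), cfg)
  cap_log <- apply_operating_window(obs2, case2, cfg)$capture_log
  snaps2 <- snapshot_stream(case2, obs2, v, cap_log)
  expect_length(snaps2, 29)                   # minutes 18:31 .. 18:59
  expect_true(all(vapply(snaps2, `[[`, integer(1), "t") <= 29))
})

test_that("cohort snapshot totals match a brute-force count of in-window minutes", {
  cfg <- tiny_sim(seed = 64)
  cap <- or_simulate(cfg)
  cases <- cap$cases[cap$cases$captured, ][1:20, ]
  v <- build_vocab(cases, cap$observations)
  snaps <- snapshot_stream(cases, cap$observations, v, cap$capture_log)
  brute <- 0L
  for (i in seq_len(nrow(cases))) {
    for (t in seq_len(cases$actual_duration[i])) {
      tm <- as.POSIXlt(cases$anaesthesia_start[i] + 60 * t, tz = "UTC")
      in_win <- tm$wday %in% 1:5 && (tm$hour + tm$min / 60) >= 7 &&
        (tm$hour + tm$min / 60) < 19 &&
        !(paste(as.Date(cases$anaesthesia_start[i] + 60 * t, tz = "UTC"),
                tm$hour) %in% cap$capture_log$downtime_keys)
      brute <- brute + in_win
    }
  }
  expect_length(snaps, brute)
})

test_that("snapshots survive a JSONL round trip and an empty file is valid", {
  cfg <- tiny_sim(seed = 65)
  cap <- or_simulate(cfg)
  cases <- cap$cases[cap$cases$captured, ][1:3, ]
  v <- build_vocab(cases, cap$observations)
  snaps <- snapshot_stream(cases, cap$observations, v, cap$capture_log)
  f <- tempfile(fileext = ".jsonl")
  persist_snapshots(snaps, f)
  expect_equal(read_snapshots(f), snaps)
  f0 <- tempfile(fileext = ".jsonl")
  persist_snapshots(list(), f0)
  expect_true(file.exists(f0))
  expect_length(read_snapshots(f0), 0)
})

test_that("tokenizing test-window data never mutates a frozen vocabulary", {
  case <- make_case()
  obs <- make_obs(case, 1, "event", "induction")
  v <- build_vocab(case, obs)
  before <- v$maps
  invisible(tokenize(v, "event", c("induction", "never_seen_event", "another")))
  invisible(tokenize(v, "medication", "novel_drug"))
  expect_identical(v$maps, before)
  expect_true(v$frozen)
})

test_that("vocabulary JSON round trip preserves ids and digest", {
  cfg <- tiny_sim(seed = 66)
  cap <- or_simulate(cfg)
  v <- build_vocab(cap$cases, cap$observations)
  f <- tempfile(fileext = ".json")
  write_vocab(v, f)
  v2 <- read_vocab(f)
  expect_identical(v2$maps, v$maps)
  expect_identical(v2$md5, v$md5)
})

test_that("bulk features equal single-snapshot features at random case-minutes", {
  cfg <- tiny_sim(seed = 67)
  cap <- or_simulate(cfg)
  cases <- cap$cases[cap$cases$captured, ]
  obs <- cap$observations
  v <- build_vocab(cases, obs)
  fspec <- build_feature_spec(cases, v)
  fs <- or_features(cases, obs, fspec, cap$capture_log)
  set.seed(91)
  for (k in 1:25) {
    i <- sample(nrow(fs$X), 1)
    case <- cases[cases$case_id == fs$meta$case_id[i], , drop = FALSE]
    snap <- replay(case, obs, fs$meta$t[i], v)
    expect_equal(snapshot_features(snap, fspec, v), fs$X[i, ],
                 tolerance = 1e-12)
  }
})
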