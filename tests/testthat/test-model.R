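# Shared small trained model for the prediction-contract tests.
local_small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      cfg <- tiny_sim(seed = 301, n_days = 10)
      cap <- or_simulate(cfg)
      cases <- cap$cases[cap$cases$captured, ]
      obs <- cap$observations
      vocab <- build_vocab(cases, obs)
      fspec <- build_feature_spec(cases, vocab)
      fs <- or_features(cases, obs, fspec, cap$capture_log)
      model <- train_model(fs, duration_model_spec(epochs = 3, seed = 5),
                           vocab, fspec)
      fit <<- list(model = model, cases = cases, obs = obs, vocab = vocab,
                   fspec = fspec, fs = fs, cap = cap)
    }
    fit
  }
})

test_that("model specification and bin-range preconditions are enforced", {
  expect_error(duration_model_spec(bins = 1), "bins")
  f <- local_small_fit()
  small <- duration_model_spec(max_minutes = 30, epochs = 1)
  expect_error(train_model(f$fs, small, f$vocab, f$fspec), "bin range")
})

test_that("every emitted forecast is a valid distribution supported above the elapsed time", {
  f <- local_small_fit()
  set.seed(13)
  for (k in 1:10) {
    i <- sample(nrow(f$cases), 1)
    case <- f$cases[i, , drop = FALSE]
    t <- sample(case$actual_duration, 1)
    snap <- replay(case, f$obs, t, f$vocab)
    d <- predict(f$model, snap)
    expect_s3_class(d, "duration_distribution")
    expect_equal(sum(d$probs), 1, tolerance = 1e-6)
    expect_gte(min(d$bin_edges), t)
    d2 <- predict(f$model, snap)
    expect_identical(d$probs, d2$probs)     # same snapshot, same output
  }
})

test_that("prediction with a mismatched vocabulary is refused", {
  f <- local_small_fit()
  other_vocab <- build_vocab(f$cases[1:3, ],
                             f$obs[f$obs$case_id %in% f$cases$case_id[1:3], ])
  case <- f$cases[1, , drop = FALSE]
  snap <- replay(case, f$obs, 5, other_vocab)
  expect_error(predict(f$model, snap), "vocabulary mismatch")
})

test_that("training is reproducible given the seed", {
  f <- local_small_fit()
  spec <- duration_model_spec(epochs = 2, seed = 99)
  m1 <- train_model(f$fs, spec, f$vocab, f$fspec)
  m2 <- train_model(f$fs, spec, f$vocab, f$fspec)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$loss_history, m2$loss_history)
  P1 <- ortime:::or_predict_probs(m1, f$fs$X)
  P2 <- ortime:::or_predict_probs(m2, f$fs$X)
  y <- pmax(f$fs$meta$label - f$fs$meta$t, 0)
  expect_lt(abs(mean(ortime:::crps_hist(P1, m1$mids, y)) -
                  mean(ortime:::crps_hist(P2, m2$mids, y))), 1e-6)
})

test_that("a constant-duration cohort concentrates mass in the correct bin", {
  cases <- constant_cases(40, duration = 60)
  obs <- empty_obs()
  vocab <- build_vocab(cases, obs)
  fspec <- build_feature_spec(cases, vocab)
  fs <- or_features(cases, obs, fspec)
  spec <- duration_model_spec(bins = 32, max_minutes = 240, epochs = 500,
                              batch = 4096, lr = 0.02, loss = "xent", seed = 3)
  m <- train_model(fs, spec, vocab, fspec)
  P <- ortime:::or_predict_probs(m, fs$X)
  rem <- 60 - fs$meta$t
  bin_of <- findInterval(pmax(rem, 1), m$edges, rightmost.closed = TRUE)
  mass <- P[cbind(seq_len(nrow(P)), bin_of)]
  expect_gte(mean(mass), 0.9)
})

test_that("a two-bin model with all labels in the first bin learns probability one", {
  cases <- constant_cases(30, duration = 15)   # remaining always < sqrt(240)
  obs <- empty_obs()
  vocab <- build_vocab(cases, obs)
  fspec <- build_feature_spec(cases, vocab)
  fs <- or_features(cases, obs, fspec)
  spec <- duration_model_spec(bins = 2, max_minutes = 240, epochs = 150,
                              batch = 4096, lr = 0.05, loss = "xent", seed = 3)
  m <- train_model(fs, spec, vocab, fspec)
  P <- ortime:::or_predict_probs(m, fs$X)
  expect_gte(min(P[, 1]), 0.95)
})

test_that("snapshots with an end-of-case signature score better than matched snapshots without", {
  cfg <- or_sim_config(n_days = 28, cases_per_weekday = 15,
                       cases_per_weekend_day = 3, seed = 100)
  cap <- or_simulate(cfg)
  tr <- cap$cases[cap$cases$captured, ]
  vocab <- build_vocab(tr, cap$observations)
  fspec <- build_feature_spec(tr, vocab)
  fs <- or_features(tr, cap$observations, fspec, cap$capture_log)
  model <- train_model(fs, duration_model_spec(epochs = 10, seed = 7), vocab, fspec)
  bl <- fit_baseline(tr)

  cfg_te <- or_sim_config(n_days = 21, cases_per_weekday = 15,
                          cases_per_weekend_day = 3, seed = 200)
  cap_te <- or_simulate(cfg_te)
  fs_te <- or_features(cap_te$cases, cap_te$observations, fspec,
                       cap_te$capture_log)
  P <- ortime:::or_predict_probs(model, fs_te$X)
  sc <- ortime:::crps_hist(P, model$mids, pmax(fs_te$meta$label - fs_te$meta$t, 0))
  sig <- fs_te$X[, "rev_seen"] + fs_te$X[, "anti_seen"] + fs_te$X[, "emerg_seen"] > 0
  tt <- fs_te$meta$t
  sel <- tt >= 20 & tt <= 120
  per_t <- sapply(split(seq_len(length(sc))[sel], tt[sel]), function(i) {
    if (length(unique(sig[i])) < 2) return(NA_real_)
    mean(sc[i][!sig[i]]) - mean(sc[i][sig[i]])
  })
  expect_gt(mean(per_t, na.rm = TRUE), 0)
})

test_that("checkpoints round-trip and simulate() draws from the forecast support", {
  f <- local_small_fit()
  p <- tempfile(fileext = ".rds")
  save_model(f$model, p)
  m2 <- load_model(p)
  expect_identical(m2$W2, f$model$W2)
  case <- f$cases[1, , drop = FALSE]
  snap <- replay(case, f$obs, 3, f$vocab)
  draws <- simulate(f$model, nsim = 200, seed = 1, snapshot = snap)
  d <- predict(f$model, snap)
  expect_true(all(draws >= min(d$bin_edges) & draws <= max(d$bin_edges)))
})
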