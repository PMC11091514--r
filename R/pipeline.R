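#' End-to-end pipeline configuration
#'
#' One configuration object drives the full run: simulate an operating-room
#' stream, split it into training and test windows by calendar date, build
#' the vocabulary and features, fit the baseline and the duration model,
#' score every in-window prediction minute, aggregate, and run the drift
#' regression.
#'
#' @param sim An [or_sim_config()].
#' @param train_days Number of initial calendar days forming the training
#'   window; later days form the test window.
#' @param model A [duration_model_spec()].
#' @param min_count Vocabulary frequency threshold.
#' @param write_observations Whether to write the (large) observations.jsonl
#'   artifact.
#' @return Object of class `or_run_config`.
#' @export
or_run_config <- function(sim = or_sim_config(), train_days = 20,
                          model = duration_model_spec(), min_count = 1,
                          write_observations = FALSE) {
  if (train_days >= sim$n_days)
    or_stopf("train_days (%d) must be smaller than sim$n_days (%d)",
             train_days, sim$n_days)
  structure(list(sim = sim, train_days = train_days, model = model,
                 min_count = min_count,
                 write_observations = write_observations),
            class = "or_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Per-stage sections (`sim`, `model`, top-level `train_days`, `min_count`)
#' with defaults for anything omitted.
#'
#' @param path YAML file path.
#' @return An `or_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(or_sim_config, y$sim %||% list())
  model <- do.call(duration_model_spec, y$model %||% list())
  or_run_config(sim = sim, train_days = y$train_days %||% 20,
                model = model, min_count = y$min_count %||% 1,
                write_observations = isTRUE(y$write_observations))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes simulate -> capture -> vocabulary -> features -> baseline ->
#' train -> score -> aggregate -> drift, writing artifacts and a run
#' manifest (config digest, seeds, per-stage timestamps, file digests) to
#' `out_dir`. Stages are pure functions of the configuration seed, so a
#' rerun with the same config reproduces identical artifact digests. With
#' `resume = TRUE`, stages whose artifacts already exist on disk are
#' reloaded instead of recomputed (e.g. rerunning after deleting only the
#' score table resumes from the stored model and snapshots).
#'
#' @param config An [or_run_config()] (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage artifacts where present.
#' @return Object of class `or_run`: manifest plus in-memory results
#'   (baseline, model, scores, aggregates, drift fit when >= 3 weeks).
#' @export
run_all <- function(config, out_dir, resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "or_run_config")) or_stopf("config must be an or_run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_time <- list()
  tick <- function(nm) stage_time[[nm]] <<- format(Sys.time(), tz = .or_tz)
  pth <- function(f) file.path(out_dir, f)
  log_msg <- function(fmt, ...) message(sprintf(paste0("[ortime] ", fmt), ...))

  # -- simulate -------------------------------------------------------------
  # The raw stream is always regenerated (deterministic given the seed);
  # resume applies to the derived stages below.
  cases_f <- pth("cases.csv")
  cap <- or_simulate(config$sim)
  cases <- cap$cases
  obs <- cap$observations
  write_cases(cases, cases_f)
  if (config$write_observations) write_observations(obs, pth("observations.jsonl"))
  tick("simulate")
  log_msg("simulated %d cases (%d captured, %.1f%%), %d observations",
          nrow(cases), cap$capture_log$n_captured,
          100 * cap$capture_log$capture_fraction, nrow(obs))

  # -- split ----------------------------------------------------------------
  split_date <- config$sim$start_date + config$train_days
  cal_date <- as.Date(cases$anaesthesia_start, tz = .or_tz)
  train_cases <- cases[cases$captured & cal_date < split_date, , drop = FALSE]
  test_cases <- cases[cases$captured & cal_date >= split_date, , drop = FALSE]
  if (nrow(train_cases) < 10L || nrow(test_cases) < 10L)
    or_stopf("split produced too few cases (train %d, test %d)",
             nrow(train_cases), nrow(test_cases))
  obs_of <- function(cs) obs[obs$case_id %in% cs$case_id, , drop = FALSE]
  log_msg("window split at %s: %d training cases, %d test cases",
          format(split_date), nrow(train_cases), nrow(test_cases))

  # -- vocabulary + baseline ------------------------------------------------
  vocab_f <- pth("vocab.json")
  if (resume && file.exists(vocab_f)) {
    vocab <- read_vocab(vocab_f)
  } else {
    vocab <- build_vocab(train_cases, obs_of(train_cases), config$min_count)
    write_vocab(vocab, vocab_f)
  }
  tick("vocab")
  baseline <- fit_baseline(train_cases)
  log_msg("baseline: slope %.3f (se %.3f), intercept %.3f (se %.3f)",
          baseline$slope, baseline$slope_se, baseline$intercept,
          baseline$intercept_se)

  # -- train ----------------------------------------------------------------
  model_f <- pth("model.rds")
  fspec <- build_feature_spec(train_cases, vocab)
  if (resume && file.exists(model_f)) {
    model <- load_model(model_f)
    log_msg("resumed model from %s", model_f)
  } else {
    fs_train <- or_features(train_cases, obs_of(train_cases), fspec,
                            cap$capture_log)
    log_msg("training on %d snapshots", nrow(fs_train$X))
    model <- train_model(fs_train, config$model, vocab, fspec)
    save_model(model, model_f)
  }
  tick("train")

  # -- score ----------------------------------------------------------------
  scores_f <- pth("scores.csv")
  if (resume && file.exists(scores_f)) {
    scores <- utils::read.csv(scores_f, stringsAsFactors = FALSE)
    scores$pred_time <- or_parse_time(scores$pred_time)
  } else {
    scores <- score_model(model, baseline, test_cases, obs_of(test_cases),
                          cap$capture_log)
    sc_out <- scores
    sc_out$pred_time <- or_fmt_time(sc_out$pred_time)
    utils::write.csv(sc_out, scores_f, row.names = FALSE)
  }
  tick("score")
  log_msg("%d predictions scored: mean CRPS model %.2f, baseline %.2f (ratio %.3f)",
          nrow(scores), mean(scores$crps_model), mean(scores$crps_baseline),
          mean(scores$crps_model) / mean(scores$crps_baseline))

  # -- aggregate + drift ----------------------------------------------------
  aggs <- do.call(rbind, lapply(
    c("month", "hospital", "service", "sched_bin", "pct_bin"),
    function(b) aggregate_scores(scores, b)))
  utils::write.csv(aggs, pth("aggregates.csv"), row.names = FALSE)
  drift_fit <- if (length(unique(scores$week)) >= 3L) drift(scores) else NULL
  if (!is.null(drift_fit)) {
    utils::write.csv(drift_fit$weekly, pth("drift.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(list(
      slope = drift_fit$slope, ci = as.list(drift_fit$ci),
      n_weeks = drift_fit$n_weeks), auto_unbox = TRUE, digits = NA),
      pth("drift_summary.json"))
  }
  tick("evaluate")

  # -- manifest -------------------------------------------------------------
  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest\\.json$", arts)]
  digests <- tools::md5sum(arts)
  manifest <- list(
    package_version = "0.1.0",
    seed = config$sim$seed,
    model_seed = config$model$seed,
    stages = stage_time,
    counts = list(cases = nrow(cases),
                  captured = cap$capture_log$n_captured,
                  train_cases = nrow(train_cases),
                  test_cases = nrow(test_cases),
                  observations = nrow(obs),
                  predictions = nrow(scores)),
    artifacts = as.list(stats::setNames(unname(digests), basename(arts)))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             pth("manifest.json"))

  structure(list(manifest = manifest, baseline = baseline, model = model,
                 scores = scores, aggregates = aggs, drift = drift_fit,
                 capture = cap$capture_log, out_dir = out_dir),
            class = "or_run")
}

#' @export
print.or_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat(sprintf("<or_run> %d cases (%d captured), %d predictions -> %s\n",
              cnt$cases, cnt$captured, cnt$predictions, x$out_dir))
  cat(sprintf("  mean CRPS: model %.2f vs baseline %.2f min\n",
              mean(x$scores$crps_model), mean(x$scores$crps_baseline)))
  invisible(x)
}
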