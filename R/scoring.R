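#' Score a prediction set against cases
#'
#' Produces one score record per prediction: the CRPS of the probabilistic
#' forecast and, for the same case-minute, the CRPS (absolute error) of the
#' bias-corrected scheduled duration, which is a constant point forecast over
#' all minutes of a case. Each record carries the stratification keys used
#' downstream (month, ISO week, hospital, service, scheduled duration,
#' percentage elapsed).
#'
#' @param predictions List of predictions, each a list with `case_id`, `t`
#'   and `dist` (a [duration_distribution] over total duration).
#' @param cases Case table (every prediction must join to a case).
#' @param baseline A [fit_baseline()] model.
#' @return A data.frame of score records.
#' @export
score_predictions <- function(predictions, cases, baseline) {
  ids <- vapply(predictions, `[[`, character(1), "case_id")
  hit <- match(ids, cases$case_id)
  if (anyNA(hit)) {
    orphans <- unique(ids[is.na(hit)])
    or_stopf("predictions reference unknown case_id(s): %s",
             paste(orphans, collapse = ", "))
  }
  tt <- vapply(predictions, function(p) as.numeric(p$t), numeric(1))
  actual <- cases$actual_duration[hit]
  sched <- cases$scheduled_duration[hit]
  crps_model <- vapply(seq_along(predictions), function(i) {
    crps(predictions[[i]]$dist, actual[i])
  }, numeric(1))
  pred_time <- cases$anaesthesia_start[hit] + 60 * tt
  data.frame(
    case_id = ids, t = tt,
    pct_elapsed = 100 * tt / actual,
    crps_model = crps_model,
    crps_baseline = crps_point(apply_baseline(baseline, sched), actual),
    month = or_month_key(pred_time), week = or_iso_week(pred_time),
    hospital = cases$hospital[hit], service = cases$service[hit],
    scheduled_duration = sched, pred_time = pred_time,
    stringsAsFactors = FALSE
  )
}

#' Score a trained model over a cohort (bulk path)
#'
#' Computes the per-minute probabilistic forecast for every captured
#' in-window case-minute and scores model and baseline with CRPS. Equivalent
#' to [score_predictions()] over [snapshot_stream()] forecasts, but
#' vectorized over the shared bin grid.
#'
#' @param model An `or_duration_model`.
#' @param baseline A [fit_baseline()] model.
#' @param cases Case table.
#' @param observations Observation table.
#' @param capture_log Optional capture log from [apply_operating_window()].
#' @return A data.frame of score records (one per prediction).
#' @export
score_model <- function(model, baseline, cases, observations,
                        capture_log = NULL) {
  fs <- or_features(cases, observations, model$fspec, capture_log)
  P <- or_predict_probs(model, fs$X)
  y_rem <- pmax(fs$meta$label - fs$meta$t, 0)
  crps_model <- crps_hist(P, model$mids, y_rem)
  data.frame(
    case_id = fs$meta$case_id, t = fs$meta$t,
    pct_elapsed = fs$meta$pct_elapsed,
    crps_model = crps_model,
    crps_baseline = crps_point(
      apply_baseline(baseline, fs$meta$scheduled_duration), fs$meta$label),
    month = fs$meta$month, week = fs$meta$week,
    hospital = fs$meta$hospital, service = fs$meta$service,
    scheduled_duration = fs$meta$scheduled_duration,
    pred_time = fs$meta$pred_time,
    stringsAsFactors = FALSE
  )
}

# Scheduled-duration stratum edges (minutes) and percent-elapsed bin width.
.sched_breaks <- c(0, 60, 120, 240, Inf)
.pct_width <- 5

#' @noRd
or_stratum_key <- function(scores, by) {
  switch(by,
    month = scores$month,
    week = scores$week,
    hospital = scores$hospital,
    service = scores$service,
    sched_bin = as.character(cut(scores$scheduled_duration, .sched_breaks,
                                 right = FALSE)),
    pct_bin = as.character(cut(scores$pct_elapsed,
                               seq(0, 100, .pct_width), right = TRUE)),
    or_stopf("unknown stratifier '%s'", by)
  )
}

#' Aggregate score records by stratum
#'
#' Per-stratum prediction count, mean CRPS with naive standard error
#' (sd/sqrt(n), treating predictions as independent), and the ratio of mean
#' model CRPS to mean baseline CRPS (< 1 means the model outperforms the
#' benchmark). Strata with fewer than `min_n` predictions are excluded, as
#' when thinly-sampled surgical services are dropped from stratified
#' reporting.
#'
#' @param scores Score records from [score_model()] / [score_predictions()].
#' @param by One of "month", "week", "hospital", "service", "sched_bin"
#'   (0-60 / 60-120 / 120-240 / 240+ min), "pct_bin" (5%-wide bins of
#'   percentage elapsed).
#' @param min_n Minimum predictions per stratum.
#' @return Data.frame: stratum, n, mean/se of model and baseline CRPS, ratio.
#' @export
aggregate_scores <- function(scores, by, min_n = 1) {
  if (nrow(scores) == 0L) or_stopf("empty score table")
  key <- or_stratum_key(scores, by)
  grp <- split(seq_len(nrow(scores)), key)
  rows <- lapply(names(grp), function(g) {
    i <- grp[[g]]
    n <- length(i)
    m <- scores$crps_model[i]
    b <- scores$crps_baseline[i]
    se <- function(v) if (n > 1L) stats::sd(v) / sqrt(n) else 0
    data.frame(stratum = g, n = n,
               mean_crps_model = mean(m),
               se_model = se(m),
               mean_crps_baseline = mean(b),
               se_baseline = se(b),
               ratio = mean(m) / mean(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n >= min_n, , drop = FALSE]
  if (nrow(out)) {
    out$stratifier <- by
    out <- out[order(out$stratum), ]
    rownames(out) <- NULL
  }
  out
}
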