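#' Weekly-batched performance-drift regression
#'
#' Batches score records by ISO-8601 week of the prediction timestamp (to
#' damp per-prediction outliers), forms the weekly ratio of mean model CRPS
#' to mean baseline CRPS (< 1 means the model is beating the benchmark), and
#' regresses the ratio on week index by ordinary least squares. A slope
#' distinguishable from zero indicates performance drift relative to the
#' benchmark.
#'
#' @param scores Score records spanning at least 3 ISO weeks.
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `or_drift`: weekly table (week, n, mean model /
#'   baseline CRPS, ratio), slope per week, confidence interval, `n_weeks`.
#' @export
drift <- function(scores, conf_level = 0.95) {
  wk <- sort(unique(scores$week))
  if (length(wk) < 3L)
    or_stopf("drift regression needs scores spanning >= 3 ISO weeks (got %d)",
             length(wk))
  grp <- split(seq_len(nrow(scores)), scores$week)
  weekly <- do.call(rbind, lapply(wk, function(w) {
    i <- grp[[w]]
    mm <- mean(scores$crps_model[i])
    mb <- mean(scores$crps_baseline[i])
    data.frame(week = w, week_index = NA_integer_, n = length(i),
               mean_crps_model = mm, mean_crps_baseline = mb,
               ratio = mm / mb, stringsAsFactors = FALSE)
  }))
  weekly$week_index <- seq_len(nrow(weekly)) - 1L
  fit <- stats::lm(ratio ~ week_index, data = weekly)
  ci <- stats::confint(fit, "week_index", level = conf_level)
  structure(list(
    weekly = weekly,
    slope = unname(stats::coef(fit)["week_index"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    ci = c(lower = ci[1], upper = ci[2]),
    conf_level = conf_level,
    n_weeks = nrow(weekly),
    fit = fit
  ), class = "or_drift")
}

#' @export
print.or_drift <- function(x, ...) {
  cat(sprintf("<or_drift> %d weeks; ratio slope %.5f per week (%.0f%% CI %.5f to %.5f)\n",
              x$n_weeks, x$slope, 100 * x$conf_level, x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  weekly CRPS ratio (model/baseline): min %.3f, median %.3f, max %.3f\n",
              min(x$weekly$ratio), stats::median(x$weekly$ratio),
              max(x$weekly$ratio)))
  invisible(x)
}

#' @export
plot.or_drift <- function(x, ...) {
  graphics::plot(x$weekly$week_index, x$weekly$ratio, type = "b",
                 xlab = "week index", ylab = "CRPS ratio (model / baseline)",
                 main = "Weekly performance ratio", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Define a retraining comparison plan
#'
#' Primary and secondary training windows plus a comparison window that must
#' start after both training windows end (the comparison data are unseen by
#' either model).
#'
#' @param primary,secondary,comparison Each a length-2 vector of dates
#'   (start, end), inclusive of start and exclusive of end.
#' @return Object of class `or_retrain_plan`.
#' @export
retrain_plan <- function(primary, secondary, comparison) {
  as_win <- function(w, nm) {
    w <- as.Date(w)
    if (length(w) != 2L || anyNA(w) || w[1] >= w[2])
      or_stopf("invalid %s window: need two ordered dates", nm)
    w
  }
  p <- as_win(primary, "primary")
  s <- as_win(secondary, "secondary")
  cmp <- as_win(comparison, "comparison")
  if (cmp[1] < p[2] || cmp[1] < s[2])
    or_stopf("comparison window overlaps a training window: it must start after both end")
  structure(list(primary = p, secondary = s, comparison = cmp),
            class = "or_retrain_plan")
}

#' @noRd
window_cases <- function(cases, win) {
  d <- as.Date(cases$anaesthesia_start, tz = .or_tz)
  cases[d >= win[1] & d < win[2], , drop = FALSE]
}

#' Primary-versus-secondary retraining comparison
#'
#' Trains two models with the identical spec — the primary on its training
#' window, the secondary only on a more proximal window — and scores both on
#' the comparison window. Reports mean CRPS with naive standard errors for
#' each model and the paired per-prediction CRPS difference
#' (primary - secondary; positive favours retraining on proximal data).
#'
#' @param plan A [retrain_plan()].
#' @param cases,observations Full dataset (the plan's windows select rows).
#' @param spec A [duration_model_spec()] shared by both models.
#' @param capture_log Optional capture log.
#' @param baseline Optional [fit_baseline()]; defaults to a fit on the
#'   primary training window.
#' @param min_count Vocabulary min_count for both models.
#' @return Object of class `or_retrain`: per-model table, paired difference
#'   with naive (per-prediction) and case-clustered standard errors, and the
#'   per-prediction score tables.
#' @export
run_retrain_comparison <- function(plan, cases, observations,
                                   spec = duration_model_spec(),
                                   capture_log = NULL, baseline = NULL,
                                   min_count = 1) {
  if (!inherits(plan, "or_retrain_plan")) or_stopf("plan must be a retrain_plan")
  fit_one <- function(win) {
    cs <- window_cases(cases, win)
    if (nrow(cs) < 10L)
      or_stopf("training window %s to %s holds too few cases (%d)",
               win[1], win[2], nrow(cs))
    ob <- observations[observations$case_id %in% cs$case_id, , drop = FALSE]
    vocab <- build_vocab(cs, ob, min_count)
    fspec <- build_feature_spec(cs, vocab)
    fs <- or_features(cs, ob, fspec, capture_log)
    list(model = train_model(fs, spec, vocab, fspec), cases = cs)
  }
  prim <- fit_one(plan$primary)
  sec <- fit_one(plan$secondary)
  if (is.null(baseline)) baseline <- fit_baseline(prim$cases)

  cmp_cases <- window_cases(cases, plan$comparison)
  cmp_obs <- observations[observations$case_id %in% cmp_cases$case_id, , drop = FALSE]
  s_prim <- score_model(prim$model, baseline, cmp_cases, cmp_obs, capture_log)
  s_sec <- score_model(sec$model, baseline, cmp_cases, cmp_obs, capture_log)
  stopifnot(identical(s_prim$case_id, s_sec$case_id),
            identical(s_prim$t, s_sec$t))

  d <- s_prim$crps_model - s_sec$crps_model
  n <- length(d)
  # Case-clustered se of the paired difference: predictions within a case
  # are strongly correlated, so the naive per-prediction se overstates
  # precision; the cluster se treats per-case mean differences as the
  # independent unit.
  case_means <- tapply(d, s_prim$case_id, mean)
  se_cluster <- stats::sd(case_means) / sqrt(length(case_means))
  tab <- data.frame(
    model = c("primary", "secondary"),
    train_start = c(plan$primary[1], plan$secondary[1]),
    train_end = c(plan$primary[2], plan$secondary[2]),
    n_predictions = n,
    mean_crps = c(mean(s_prim$crps_model), mean(s_sec$crps_model)),
    se = c(stats::sd(s_prim$crps_model), stats::sd(s_sec$crps_model)) / sqrt(n),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = tab,
    paired_diff = mean(d),
    paired_se = stats::sd(d) / sqrt(n),
    paired_se_cluster = se_cluster,
    n_cases = length(case_means),
    n_predictions = n,
    scores_primary = s_prim, scores_secondary = s_sec,
    plan = plan
  ), class = "or_retrain")
}

#' @export
print.or_retrain <- function(x, ...) {
  cat("<or_retrain> comparison window", format(x$plan$comparison[1]), "to",
      format(x$plan$comparison[2]), "\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  paired CRPS difference (primary - secondary): %.3f min (naive se %.3f, case-cluster se %.3f)\n",
              x$paired_diff, x$paired_se, x$paired_se_cluster))
  invisible(x)
}
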