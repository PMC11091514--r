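#' Fit the bias-corrected scheduled-duration benchmark
#'
#' Ordinary least-squares regression of actual duration on raw scheduled
#' duration over the training-window cases. The fitted linear map is applied
#' to scheduled durations to produce the benchmark point forecast against
#' which the probabilistic model is scored.
#'
#' @param cases Training-window case table with `scheduled_duration` and
#'   `actual_duration` (at least two distinct scheduled durations).
#' @return Object of class `sched_baseline`: slope, intercept, their standard
#'   errors, and the underlying `lm` fit.
#' @examples
#' cases <- data.frame(scheduled_duration = c(30, 60, 90, 120),
#'                     actual_duration = c(63, 123, 183, 243))
#' fit <- fit_baseline(cases)   # actual = 2 * scheduled + 3
#' coef(fit)
#' predict(fit, scheduled_duration = 100)
#' @export
fit_baseline <- function(cases) {
  if (nrow(cases) < 2L)
    or_stopf("fit_baseline needs at least 2 training cases")
  if (length(unique(cases$scheduled_duration)) < 2L)
    or_stopf("degenerate design: scheduled_duration is constant")
  fit <- stats::lm(actual_duration ~ scheduled_duration, data = cases)
  cf <- summary(fit)$coefficients
  structure(list(
    slope = unname(cf["scheduled_duration", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope_se = unname(cf["scheduled_duration", "Std. Error"]),
    intercept_se = unname(cf["(Intercept)", "Std. Error"]),
    n = nrow(cases), fit = fit
  ), class = "sched_baseline")
}

#' @export
coef.sched_baseline <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.sched_baseline <- function(x, ...) {
  cat(sprintf("<sched_baseline> actual = %.3f * scheduled %+.3f  (se %.3f / %.3f, n = %d)\n",
              x$slope, x$intercept, x$slope_se, x$intercept_se, x$n))
  invisible(x)
}

#' Bias-corrected scheduled duration
#'
#' Applies the fitted linear correction `slope * scheduled + intercept`,
#' floored at 1 minute so the benchmark never forecasts a non-positive
#' duration.
#'
#' @param model A [fit_baseline()] object.
#' @param scheduled_duration Scheduled durations in minutes (vectorized).
#' @return Bias-corrected durations in minutes.
#' @export
apply_baseline <- function(model, scheduled_duration) {
  pmax(model$slope * scheduled_duration + model$intercept, 1)
}

#' @export
predict.sched_baseline <- function(object, scheduled_duration, ...) {
  apply_baseline(object, scheduled_duration)
}

#' @export
residuals.sched_baseline <- function(object, ...) {
  stats::residuals(object$fit)
}
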