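# Internal helpers: minute arithmetic, calendar keys, seed derivation.

# All datetimes in the package are POSIXct, UTC.
.or_tz <- "UTC"

#' @noRd
or_minutes <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

#' @noRd
or_add_minutes <- function(time, mins) {
  time + mins * 60
}

# ISO-8601 week key, e.g. "2023-W07", on a POSIXct/Date vector.
#' @noRd
or_iso_week <- function(time) {
  format(time, "%G-W%V")
}

#' @noRd
or_month_key <- function(time) {
  format(time, "%Y-%m")
}

# Derive a stream-specific seed from a master seed; stays below 2^31.
#' @noRd
or_derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483629L
}

#' @noRd
or_stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Weighted sampling that is deterministic under set.seed and normalizes
# weights defensively.
#' @noRd
or_sample <- function(x, n, weights) {
  weights <- weights / sum(weights)
  x[sample.int(length(x), n, replace = TRUE, prob = weights)]
}
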