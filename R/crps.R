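#' Discrete probability distribution over duration bins
#'
#' Constructs and validates the forecast object emitted by the duration
#' model: a histogram over total-duration bins, interpreted as probability
#' mass placed at the arithmetic centre of each bin (a step CDF). The
#' support therefore begins strictly after the first bin edge, which for
#' model forecasts is the current elapsed time, so no mass lies on totals
#' already ruled out.
#'
#' @param bin_edges Strictly increasing numeric vector of bin boundaries in
#'   minutes, length K+1.
#' @param probs Nonnegative numeric vector of bin probabilities, length K;
#'   must sum to 1 within 1e-6 (renormalized exactly on construction).
#' @return An object of class `duration_distribution` with elements
#'   `bin_edges`, `probs` and `support` (the bin centres).
#' @examples
#' d <- duration_distribution(c(0, 60, 120, 240), c(0.2, 0.5, 0.3))
#' crps(d, 95)
#' @export
duration_distribution <- function(bin_edges, probs) {
  bin_edges <- as.numeric(bin_edges)
  probs <- as.numeric(probs)
  if (length(bin_edges) != length(probs) + 1L)
    or_stopf("bin_edges must have length(probs) + 1 (got %d edges, %d probs)",
             length(bin_edges), length(probs))
  if (any(diff(bin_edges) <= 0))
    or_stopf("bin_edges must be strictly increasing")
  if (any(probs < 0))
    or_stopf("probs must be nonnegative")
  s <- sum(probs)
  if (abs(s - 1) > 1e-6)
    or_stopf("probs must sum to 1 within 1e-6 (sum = %.8f)", s)
  probs <- probs / s
  structure(
    list(bin_edges = bin_edges, probs = probs,
         support = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2),
    class = "duration_distribution"
  )
}

#' @export
print.duration_distribution <- function(x, ...) {
  K <- length(x$probs)
  m <- sum(x$support * x$probs)
  cat(sprintf("<duration_distribution> %d bins on [%.1f, %.1f] min, mean %.1f min\n",
              K, x$bin_edges[1], x$bin_edges[K + 1], m))
  invisible(x)
}

#' Continuous ranked probability score of a binned forecast
#'
#' Computes CRPS(F, y) = integral of (F(x) - 1\{x >= y\})^2 dx exactly, where
#' F is the step CDF of the binned forecast (mass at bin centres). CRPS is a
#' proper scoring rule measured in minutes; it generalizes absolute error to
#' probabilistic forecasts and equals 0 only for a point mass at the outcome.
#'
#' @param dist A [duration_distribution].
#' @param y Observed outcome in minutes; must be finite and nonnegative.
#' @return CRPS in minutes (nonnegative scalar).
#' @seealso [crps_point()] for the point-forecast special case.
#' @export
crps <- function(dist, y) {
  if (!inherits(dist, "duration_distribution"))
    or_stopf("dist must be a duration_distribution")
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) || y < 0)
    or_stopf("y must be a single finite nonnegative number of minutes")
  drop(crps_hist(matrix(dist$probs, nrow = 1), dist$support, y))
}

#' CRPS of a deterministic (point) forecast
#'
#' For a point forecast the CRPS reduces to the absolute error
#' |forecast - y|; this is how the bias-corrected scheduled-duration
#' benchmark is scored.
#'
#' @param forecast Point forecast in minutes (vectorized).
#' @param y Observed outcome in minutes (vectorized, recycled).
#' @return Absolute error in minutes.
#' @export
crps_point <- function(forecast, y) {
  abs(forecast - y)
}

# Vectorized exact CRPS for n forecasts sharing one support grid.
#
# P: n x K matrix of probabilities (rows sum to 1); x: increasing support
# points (mass locations), length K; y: outcomes, length n (or 1).
# Piecewise-constant integration of (F - H)^2 between consecutive support
# points plus the two tails; exact for the step CDF.
#' @noRd
crps_hist <- function(P, x, y) {
  n <- nrow(P)
  K <- ncol(P)
  if (length(x) != K) or_stopf("support length must equal ncol(P)")
  y <- rep_len(as.numeric(y), n)
  if (K == 1L) return(abs(x - y))

  d <- diff(x)                              # K-1 segment widths
  # Row-wise cumulative sums (column loop keeps it vectorized over rows).
  F <- P
  for (k in 2:K) F[, k] <- F[, k - 1L] + P[, k]

  # Base: every segment scored with H = 0, i.e. sum_k F_k^2 d_k (k < K).
  base <- as.vector((F[, -K, drop = FALSE]^2) %*% d)

  # Correction term (1 - 2 F_k) d_k for segments wholly at or above y,
  # accumulated from the right so row i needs suffix starting at j_i + 1.
  C <- sweep(1 - 2 * F[, -K, drop = FALSE], 2, d, `*`)
  S <- cbind(C, 0)                          # S[, k] = sum_{m >= k} C[, m]
  for (k in (K - 1L):1L) S[, k] <- S[, k + 1L] + C[, k]

  j <- findInterval(y, x)                   # largest index with x_j <= y
  idx <- cbind(seq_len(n), pmin(j + 1L, K))
  out <- base + S[idx] * (j < K)            # full segments at/above y
  # Partial segment containing y (x_j <= y < x_{j+1}), only when 1<=j<=K-1:
  inner <- j >= 1L & j <= K - 1L
  if (any(inner)) {
    ji <- j[inner]
    rows <- which(inner)
    Fj <- F[cbind(rows, ji)]
    out[inner] <- out[inner] + (1 - 2 * Fj) * (x[ji + 1L] - y[inner])
  }
  # Tails: below the support (H = 1 on [y, x_1)) and above (F = 1 on [x_K, y)).
  out <- out + pmax(x[1] - y, 0) + pmax(y - x[K], 0)
  pmax(out, 0)
}
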