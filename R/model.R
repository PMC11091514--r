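#' Specification of the probabilistic duration model
#'
#' The model predicts *remaining* duration at each minute as a probability
#' histogram over K geometric bins spanning `[1, max_minutes]`; the forecast
#' over total duration is this histogram shifted by the elapsed time, so no
#' probability mass falls on totals that are already impossible. The network
#' is a single-hidden-layer feedforward net (tanh) with a softmax head over
#' the bins, trained with minibatch Adam on either the discretized CRPS
#' (default: matches the evaluation metric) or cross-entropy over bin
#' indices. Training is deterministic given the seed.
#'
#' @param hidden Hidden-layer width.
#' @param bins Number of duration bins K (>= 2).
#' @param max_minutes Upper edge of the last bin; must be at least the
#'   longest training duration.
#' @param loss `"crps"` (discretized CRPS) or `"xent"` (cross-entropy).
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param l2 L2 weight penalty.
#' @param max_snapshots Training snapshots are subsampled (seeded) to at most
#'   this many rows to bound training time.
#' @param seed Seed for initialization, subsampling and batching.
#' @return Object of class `or_model_spec`.
#' @export
duration_model_spec <- function(hidden = 32, bins = 128, max_minutes = 1440,
                                loss = c("crps", "xent"), epochs = 15,
                                batch = 1024, lr = 0.005, l2 = 1e-5,
                                max_snapshots = 80000, seed = 1) {
  loss <- match.arg(loss)
  if (bins < 2) or_stopf("bins must be >= 2")
  if (max_minutes <= 1) or_stopf("max_minutes must exceed 1")
  structure(list(hidden = hidden, bins = as.integer(bins),
                 max_minutes = max_minutes, loss = loss,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, l2 = l2, max_snapshots = as.integer(max_snapshots),
                 seed = as.integer(seed)),
            class = "or_model_spec")
}

# Geometric bin edges over remaining minutes.
#' @noRd
or_bin_edges <- function(spec) {
  exp(seq(log(1), log(spec$max_minutes), length.out = spec$bins + 1L))
}

#' Train the probabilistic duration model
#'
#' @param train Either a feature set from [or_features()] (list with `X` and
#'   `meta`) or a list of `or_snapshot` objects (featurized internally).
#' @param spec An [duration_model_spec()].
#' @param vocab The frozen [or_vocab] the snapshots were tokenized with.
#' @param fspec Optional [build_feature_spec()]; required when `train` is a
#'   feature set (it must be the template used to build it).
#' @return Object of class `or_duration_model`.
#' @export
train_model <- function(train, spec = duration_model_spec(), vocab,
                        fspec = NULL) {
  if (is.list(train) && length(train) && inherits(train[[1]], "or_snapshot")) {
    if (is.null(fspec)) or_stopf("fspec is required to featurize snapshots")
    X <- t(vapply(train, snapshot_features, numeric(length(feature_names(fspec))),
                  fspec = fspec, vocab = vocab))
    label <- vapply(train, `[[`, numeric(1), "label")
    tt <- vapply(train, function(s) as.numeric(s$t), numeric(1))
  } else if (is.list(train) && !is.null(train$X)) {
    X <- train$X
    label <- train$meta$label
    tt <- train$meta$t
    if (is.null(fspec)) or_stopf("fspec is required alongside a feature matrix")
  } else {
    or_stopf("train must be an or_features() result or a list of snapshots")
  }
  if (nrow(X) == 0L) or_stopf("empty training set")
  if (max(label) > spec$max_minutes)
    or_stopf("bin range too small: max_minutes = %g but longest training case is %g min",
             spec$max_minutes, max(label))

  y <- pmin(pmax(label - tt, 1), spec$max_minutes)   # remaining minutes
  edges <- or_bin_edges(spec)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  K <- spec$bins

  set.seed(spec$seed)
  n_all <- nrow(X)
  if (n_all > spec$max_snapshots) {
    keep <- sample.int(n_all, spec$max_snapshots)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  p <- ncol(Xs)
  H <- spec$hidden
  r1 <- sqrt(6 / (p + H)); r2 <- sqrt(6 / (H + K))
  W1 <- matrix(stats::runif(p * H, -r1, r1), p, H)
  b1 <- numeric(H)
  W2 <- matrix(stats::runif(H * K, -r2, r2), H, K)
  b2 <- numeric(K)

  gaps <- diff(mids)                                  # K-1 segment widths
  bin_idx <- pmin(pmax(findInterval(y, edges, rightmost.closed = TRUE), 1L), K)

  adam <- list(m = list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0),
               v = list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0),
               t = 0)
  upd <- function(par, g, nm) {
    adam$t <<- adam$t
    adam$m[[nm]] <<- 0.9 * adam$m[[nm]] + 0.1 * g
    adam$v[[nm]] <<- 0.999 * adam$v[[nm]] + 0.001 * g * g
    mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
    vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
    par - spec$lr * mhat / (sqrt(vhat) + 1e-8)
  }

  loss_hist <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (bs in split(perm, ceiling(seq_along(perm) / spec$batch))) {
      nb <- length(bs)
      Xb <- Xs[bs, , drop = FALSE]
      A <- tanh(sweep(Xb %*% W1, 2, b1, `+`))
      Z <- sweep(A %*% W2, 2, b2, `+`)
      Z <- Z - apply(Z, 1, max)
      E <- exp(Z)
      P <- E / rowSums(E)

      if (spec$loss == "crps") {
        F <- P
        for (k in 2:K) F[, k] <- F[, k - 1L] + P[, k]
        Hm <- outer(y[bs], mids[-K], `<=`)            # step indicator at y
        R <- F[, -K, drop = FALSE] - Hm
        Lb <- as.vector((R^2) %*% gaps)
        dF <- sweep(2 * R, 2, gaps, `*`)
        g <- cbind(dF, 0)
        for (k in (K - 1L):1L) g[, k] <- g[, k + 1L] + dF[, k]
      } else {
        bi <- bin_idx[bs]
        Lb <- -log(pmax(P[cbind(seq_len(nb), bi)], 1e-12))
        g <- matrix(0, nb, K)
        g[cbind(seq_len(nb), bi)] <- -1 / pmax(P[cbind(seq_len(nb), bi)], 1e-12)
      }
      ep_loss <- ep_loss + sum(Lb)

      dZ <- (P * (g - rowSums(P * g))) / nb
      adam$t <- adam$t + 1
      gW2 <- crossprod(A, dZ) + spec$l2 * W2
      gb2 <- colSums(dZ)
      dA <- tcrossprod(dZ, W2) * (1 - A^2)
      gW1 <- crossprod(Xb, dA) + spec$l2 * W1
      gb1 <- colSums(dA)
      W2 <- upd(W2, gW2, "W2"); b2 <- upd(b2, gb2, "b2")
      W1 <- upd(W1, gW1, "W1"); b1 <- upd(b1, gb1, "b1")
    }
    loss_hist[ep] <- ep_loss / n
  }

  structure(list(
    spec = spec, fspec = fspec, vocab = vocab, vocab_md5 = vocab$md5,
    feature_names = colnames(X), center = ctr, scale = scl,
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    edges = edges, mids = mids, n_train = n,
    loss_history = loss_hist, version = "0.1.0"
  ), class = "or_duration_model")
}

# Bin probabilities for a feature matrix (rows = case-minutes).
#' @noRd
or_predict_probs <- function(model, X) {
  Xs <- sweep(sweep(X[, model$feature_names, drop = FALSE], 2, model$center),
              2, model$scale, `/`)
  A <- tanh(sweep(Xs %*% model$W1, 2, model$b1, `+`))
  Z <- sweep(A %*% model$W2, 2, model$b2, `+`)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Predict the duration distribution for a snapshot
#'
#' Returns the forecast over *total* anaesthesia time at the snapshot's
#' elapsed minute: the remaining-duration histogram shifted by `t`. The
#' support therefore starts at `t`, so no probability is assigned to totals
#' that have already been exceeded. Errors if the snapshot was tokenized
#' with a different vocabulary than the model.
#'
#' @param object An `or_duration_model`.
#' @param newdata An `or_snapshot`.
#' @param ... Unused.
#' @return A [duration_distribution] over total duration in minutes.
#' @export
predict.or_duration_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "or_snapshot"))
    or_stopf("newdata must be an or_snapshot")
  if (!is.null(newdata$vocab_md5) && !identical(newdata$vocab_md5, object$vocab_md5))
    or_stopf("vocabulary mismatch: snapshot tokenized with a different vocabulary than the model")
  x <- snapshot_features(newdata, object$fspec, object$vocab)
  P <- or_predict_probs(object, matrix(x, 1, dimnames = list(NULL, names(x))))
  p <- as.vector(P)
  p <- p / sum(p)                       # guard renormalization
  duration_distribution(newdata$t + object$edges, p)
}

#' @export
print.or_duration_model <- function(x, ...) {
  cat(sprintf("<or_duration_model> %d features -> %d hidden -> %d bins on [1, %g] min\n",
              length(x$feature_names), x$spec$hidden, x$spec$bins,
              x$spec$max_minutes))
  cat(sprintf("  loss %s, %d epochs on %d snapshots; final training loss %.3f\n",
              x$spec$loss, x$spec$epochs, x$n_train,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.or_duration_model <- function(object, ...) {
  out <- list(spec = object$spec, n_train = object$n_train,
              loss_history = object$loss_history,
              n_parameters = length(object$W1) + length(object$b1) +
                length(object$W2) + length(object$b2))
  class(out) <- "summary.or_duration_model"
  out
}

#' @export
print.summary.or_duration_model <- function(x, ...) {
  cat(sprintf("Duration model: %d parameters, trained %d epochs on %d snapshots (loss %s)\n",
              x$n_parameters, x$spec$epochs, x$n_train, x$spec$loss))
  cat("Training loss by epoch:\n")
  print(round(x$loss_history, 4))
  invisible(x)
}

#' @export
plot.or_duration_model <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = sprintf("mean training %s (min)", x$spec$loss),
                 main = "Duration model training loss", ...)
  invisible(x)
}

#' Draw total durations from a model forecast
#'
#' Samples total-duration values from the predictive distribution of one
#' snapshot (bin sampled by probability, uniform within the bin).
#'
#' @param object An `or_duration_model`.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param snapshot The `or_snapshot` to forecast.
#' @param ... Unused.
#' @return Numeric vector of simulated total durations in minutes.
#' @export
simulate.or_duration_model <- function(object, nsim = 1, seed = NULL,
                                       snapshot, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- predict(object, snapshot)
  k <- sample.int(length(d$probs), nsim, replace = TRUE, prob = d$probs)
  stats::runif(nsim, d$bin_edges[k], d$bin_edges[k + 1L])
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint embedding the model spec, feature template,
#' weights and the vocabulary digest.
#'
#' @param model An `or_duration_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "or_duration_model")) or_stopf("not a model checkpoint: %s", path)
  m
}
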