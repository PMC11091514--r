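# Model-ready features. The intraoperative sequences are summarized per
# minute into fixed-length vectors: elapsed/scheduled time geometry, stream
# counts, recency of the end-of-case signature tokens (reversal agent,
# antiemetic, emergence event), and last values / recent deltas of the six
# flowsheet channels with explicit missingness masks. Both the bulk path
# (whole cohort, vectorized per case) and the single-snapshot path compute
# the identical vector; tests assert their equality.

#' Feature template for the duration model
#'
#' Fixes the categorical levels (from the training cases) and the effective
#' end-of-case signature label sets (signature labels that survived
#' tokenization) so that feature vectors are identical at train and predict
#' time.
#'
#' @param cases Training-window case table.
#' @param vocab Frozen [or_vocab].
#' @return An object of class `or_feature_spec`.
#' @export
build_feature_spec <- function(cases, vocab) {
  sig <- or_signature_labels()
  known_med <- names(vocab$maps$medication)
  known_ev <- names(vocab$maps$event)
  structure(list(
    hospital_levels = sort(unique(cases$hospital)),
    service_levels = sort(unique(cases$service)),
    rev_set = intersect(sig$reversal_meds, known_med),
    anti_set = intersect(sig$antiemetic_meds, known_med),
    emerg_set = intersect(sig$emergence_events, known_ev),
    channels = or_flowsheet_channels(),
    delta_channels = c("exp_sevoflurane", "exp_desflurane", "exp_n2o", "bis"),
    recency_cap = 30
  ), class = "or_feature_spec")
}

#' @noRd
feature_names <- function(fspec) {
  ch <- fspec$channels
  c("t", "log1p_t", "sched", "log_sched", "sched_remain", "log1p_sched_remain",
    "frac_sched", "elective", "n_events", "n_meds",
    "rev_seen", "rev_rec", "anti_seen", "anti_rec", "emerg_seen", "emerg_rec",
    paste0(ch, "_last"), paste0(ch, "_miss"),
    paste0(fspec$delta_channels, "_d5"),
    paste0("hosp_", fspec$hospital_levels),
    paste0("svc_", fspec$service_levels))
}

# Recency transform: 0 = signature just seen, 1 = >= cap minutes ago / never.
#' @noRd
.recency <- function(seen, t, last_off, cap) {
  ifelse(seen, pmin(t - last_off, cap) / cap, 1)
}

#' Per-minute feature matrix for a cohort
#'
#' Computes the model's feature vector for every prediction minute of every
#' (captured) case, respecting ingestion latency: a datum contributes from
#' the first elapsed minute `t` with `ingest_time <= anaesthesia_start + t`.
#'
#' @param cases Case table (rows with `captured == FALSE` are skipped when
#'   the column is present).
#' @param observations Observation table with ingestion times.
#' @param fspec An [build_feature_spec()] template.
#' @param capture_log Optional capture log restricting prediction minutes to
#'   the live operating window.
#' @return List with `X` (numeric matrix, one row per case-minute) and
#'   `meta` (data.frame: case_id, t, label, pred_time, month, week, hospital,
#'   service, scheduled_duration, pct_elapsed).
#' @export
or_features <- function(cases, observations, fspec, capture_log = NULL) {
  if ("captured" %in% names(cases)) cases <- cases[cases$captured, , drop = FALSE]
  fn <- feature_names(fspec)
  obs_idx <- split(seq_len(nrow(observations)), observations$case_id)
  Xs <- vector("list", nrow(cases))
  metas <- vector("list", nrow(cases))

  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    tt <- prediction_minutes(cs$anaesthesia_start, cs$actual_duration, capture_log)
    if (length(tt) == 0L) next
    oi <- obs_idx[[cs$case_id]]
    ob <- observations[oi, , drop = FALSE]
    vmin <- ceiling(round(or_minutes(ob$ingest_time, cs$anaesthesia_start), 9))
    omin <- pmax(floor(or_minutes(ob$charted_time, cs$anaesthesia_start)), 0)

    n_t <- length(tt)
    X <- matrix(0, n_t, length(fn), dimnames = list(NULL, fn))

    sched <- cs$scheduled_duration
    X[, "t"] <- tt
    X[, "log1p_t"] <- log1p(tt)
    X[, "sched"] <- sched
    X[, "log_sched"] <- log(sched)
    X[, "sched_remain"] <- pmax(sched - tt, 0)
    X[, "log1p_sched_remain"] <- log1p(pmax(sched - tt, 0))
    X[, "frac_sched"] <- pmin(tt / sched, 3)
    X[, "elective"] <- as.numeric(cs$urgency == "elective")

    ev <- ob$stream == "event"
    md <- ob$stream == "medication"
    X[, "n_events"] <- log1p(findInterval(tt, sort(vmin[ev])))
    X[, "n_meds"] <- log1p(findInterval(tt, sort(vmin[md])))

    sig_cols <- list(
      rev = md & ob$name %in% fspec$rev_set,
      anti = md & ob$name %in% fspec$anti_set,
      emerg = ev & ob$name %in% fspec$emerg_set
    )
    for (nm in names(sig_cols)) {
      sel <- which(sig_cols[[nm]])
      seen <- rep(FALSE, n_t)
      last_off <- rep(-Inf, n_t)
      for (j in sel) {                      # at most a few signature tokens
        visj <- tt >= vmin[j]
        seen <- seen | visj
        last_off <- pmax(last_off, ifelse(visj, omin[j], -Inf))
      }
      X[, paste0(nm, "_seen")] <- as.numeric(seen)
      X[, paste0(nm, "_rec")] <- .recency(seen, tt, last_off, fspec$recency_cap)
    }

    fl <- ob$stream == "flowsheet"
    for (ch in fspec$channels) {
      sel <- which(fl & ob$name == ch)
      res <- .last_visible(vmin[sel], omin[sel], ob$value[sel], tt)
      X[, paste0(ch, "_last")] <- ifelse(is.na(res$value), 0, res$value)
      X[, paste0(ch, "_miss")] <- as.numeric(is.na(res$value))
      if (ch %in% fspec$delta_channels) {
        ref <- .last_visible(pmax(vmin[sel], omin[sel] + 5), omin[sel],
                             ob$value[sel], tt)
        d5 <- res$value - ref$value
        X[, paste0(ch, "_d5")] <- ifelse(is.na(d5), 0, d5)
      }
    }

    hc <- paste0("hosp_", cs$hospital)
    if (hc %in% fn) X[, hc] <- 1
    sc <- paste0("svc_", cs$service)
    if (sc %in% fn) X[, sc] <- 1

    Xs[[i]] <- X
    pred_time <- cs$anaesthesia_start + 60 * tt
    metas[[i]] <- data.frame(
      case_id = cs$case_id, t = tt, label = cs$actual_duration,
      pred_time = pred_time,
      month = or_month_key(pred_time), week = or_iso_week(pred_time),
      hospital = cs$hospital, service = cs$service,
      scheduled_duration = sched,
      pct_elapsed = 100 * tt / cs$actual_duration,
      stringsAsFactors = FALSE
    )
  }
  keep <- !vapply(Xs, is.null, logical(1))
  list(X = do.call(rbind, Xs[keep]),
       meta = do.call(rbind, metas[keep]))
}

# Last visible value per minute: among observations with visibility minute
# v <= t, the value at the largest charted offset. O(n + T).
#' @noRd
.last_visible <- function(v, o, val, tt) {
  if (length(v) == 0L)
    return(list(value = rep(NA_real_, length(tt)),
                offset = rep(NA_real_, length(tt))))
  ord <- order(v, o)
  v <- v[ord]; o <- o[ord]; val <- val[ord]
  runmax <- cummax(o)
  is_best <- o == runmax
  best_idx <- cummax(ifelse(is_best, seq_along(o), 0L))
  k <- findInterval(tt, v)
  idx <- ifelse(k >= 1L, best_idx[pmax(k, 1L)], 0L)
  list(value = ifelse(idx >= 1L, val[pmax(idx, 1L)], NA_real_),
       offset = ifelse(idx >= 1L, o[pmax(idx, 1L)], NA_real_))
}

#' Feature vector of a single snapshot
#'
#' Maps one [replay()] snapshot to the same feature vector the bulk path
#' produces for that case-minute.
#'
#' @param snapshot An `or_snapshot`.
#' @param fspec An [build_feature_spec()] template.
#' @param vocab The [or_vocab] the snapshot was tokenized with.
#' @return Named numeric feature vector.
#' @export
snapshot_features <- function(snapshot, fspec, vocab) {
  fn <- feature_names(fspec)
  x <- stats::setNames(numeric(length(fn)), fn)
  t <- snapshot$t
  sched <- snapshot$preop$scheduled_duration
  x["t"] <- t
  x["log1p_t"] <- log1p(t)
  x["sched"] <- sched
  x["log_sched"] <- log(sched)
  x["sched_remain"] <- max(sched - t, 0)
  x["log1p_sched_remain"] <- log1p(max(sched - t, 0))
  x["frac_sched"] <- min(t / sched, 3)
  x["elective"] <- as.numeric(snapshot$preop$urgency == "elective")
  x["n_events"] <- log1p(length(snapshot$events$id))
  x["n_meds"] <- log1p(length(snapshot$meds$id))

  med_names <- detokenize(vocab, "medication", snapshot$meds$id)
  ev_names <- detokenize(vocab, "event", snapshot$events$id)
  sig <- list(rev = list(names = med_names, off = snapshot$meds$offset, set = fspec$rev_set),
              anti = list(names = med_names, off = snapshot$meds$offset, set = fspec$anti_set),
              emerg = list(names = ev_names, off = snapshot$events$offset, set = fspec$emerg_set))
  for (nm in names(sig)) {
    s <- sig[[nm]]
    hit <- s$names %in% s$set
    seen <- any(hit)
    last_off <- if (seen) max(s$off[hit]) else -Inf
    x[paste0(nm, "_seen")] <- as.numeric(seen)
    x[paste0(nm, "_rec")] <- .recency(seen, t, last_off, fspec$recency_cap)
  }

  for (ch in fspec$channels) {
    f <- snapshot$flowsheet[[ch]]
    vals <- c(f$older$value, f$value)
    offs <- c(f$older$offset, f$offset)
    ok <- !is.na(vals)
    vals <- vals[ok]; offs <- offs[ok]
    if (length(vals)) {
      j <- which.max(offs)
      x[paste0(ch, "_last")] <- vals[j]
      x[paste0(ch, "_miss")] <- 0
      if (ch %in% fspec$delta_channels) {
        back <- offs <= t - 5
        if (any(back)) {
          jr <- which(back)[which.max(offs[back])]
          x[paste0(ch, "_d5")] <- vals[j] - vals[jr]
        }
      }
    } else {
      x[paste0(ch, "_miss")] <- 1
    }
  }

  hc <- paste0("hosp_", snapshot$preop$hospital)
  if (hc %in% fn) x[hc] <- 1
  sc <- paste0("svc_", snapshot$preop$service)
  if (sc %in% fn) x[sc] <- 1
  x
}
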