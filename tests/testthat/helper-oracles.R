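# Independent brute-force oracles. These re-derive expected values from the
# rules directly (per-hour loops, exhaustive pair counting, closed forms)
# and deliberately share no code with the implementation they check.

# Hour h is IMV-active iff [h, h+1) overlaps any interval.
oracle_active <- function(vent_stay, h) {
  if (nrow(vent_stay) == 0) return(FALSE)
  any(vent_stay$start_hours < h + 1 & vent_stay$end_hours > h)
}

oracle_states <- function(vent_stay, los) {
  H <- floor(los)
  act <- vapply(0:(H - 1), function(h) oracle_active(vent_stay, h), logical(1))
  st <- character(H)
  for (h in seq_len(H)) {
    prev <- if (h == 1) FALSE else act[h - 1]
    st[h] <- if (act[h] && !prev) "ONSET"
    else if (act[h] && prev) "STAY_ON"
    else if (!act[h] && prev) "WEAN"
    else "STAY_OFF"
  }
  list(active = act, state = st)
}

# Exhaustive window enumerator: loops every t and re-checks every rule.
oracle_windows <- function(vent_stay, los, fw = 6, gap = 6, tw = 4,
                           stride = 1) {
  H <- floor(los)
  os <- oracle_states(vent_stay, los)
  onset_hours <- which(os$state == "ONSET") - 1
  out <- list()
  t <- fw
  while (t <= H - gap - tw) {
    excl_hours <- (t - fw):(t + gap - 1)
    if (!any(os$active[excl_hours + 1])) {
      lab_hours <- (t + gap):(t + gap + tw - 1)
      out[[length(out) + 1]] <-
        c(t = t, label = as.integer(any(onset_hours %in% lab_hours)))
    }
    t <- t + stride
  }
  if (length(out) == 0) {
    return(tibble::tibble(t = integer(), label = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(t = as.integer(m[, "t"]), label = as.integer(m[, "label"]))
}

# Per-hour triplet recomputation straight from raw events.
oracle_triplets <- function(events_stay_feature, H) {
  value <- rep(NA_real_, H); mask <- integer(H); tsl <- integer(H)
  last <- -Inf
  for (h in 0:(H - 1)) {
    inhr <- events_stay_feature$value[events_stay_feature$time_hours >= h &
                                        events_stay_feature$time_hours < h + 1]
    if (length(inhr) > 0) {
      value[h + 1] <- mean(inhr); mask[h + 1] <- 1L; last <- h
      tsl[h + 1] <- 0L
    } else {
      tsl[h + 1] <- if (is.infinite(last)) h + 1L else h - as.integer(last)
    }
  }
  list(value = value, mask = mask, tsl = tsl)
}

# O(n^2) pairwise AUC with tie halving.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_fbeta <- function(tp, fp, fn, beta) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p == 0 && r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
}

oracle_mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Fast synthetic windows for model tests: n samples, planted linear signal
# in the first feature, remaining features noise. Returns a vw_windows-like
# object through the package's own constructor path.
planted_windows <- function(n, seed, signal = 2, n_features = 5,
                            separable = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_features), n,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  eta <- signal * X[, 1] + rnorm(n, sd = if (separable) 0.01 else 1)
  lab <- as.integer(eta > stats::quantile(eta, 0.8))
  meta <- tibble::tibble(stay_id = sprintf("p%04d", seq_len(n)),
                         t = 6L, label = lab)
  man <- tibble::tibble(column = colnames(X),
                        feature_id = colnames(X),
                        channel = "value", win_hour = 0L)
  ventwatch:::new_vw_windows(X, meta, man, window_config(),
                             tibble::tibble(), colnames(X))
}
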