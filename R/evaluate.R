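#' Evaluation configuration
#'
#' @param target_fpr The false-positive-rate anchor for the decision
#'   threshold mu (default 0.2: the alarm threshold is set so roughly 20%
#'   of negatives would trip it).
#' @param beta Fbeta weight (default 0.5).
#' @param bin_edges Probability bin edges for the precision-by-bin view;
#'   edges at or below mu are discarded at evaluation time so the first bin
#'   is `[mu, next surviving edge)` and the last is closed at 1.
#' @param n_splits Repeated random splits for the AUC confidence interval
#'   (default 30).
#' @param ci_level Confidence level (default 0.95).
#' @return An `eval_config` list.
#' @export
eval_config <- function(target_fpr = 0.2, beta = 0.5,
                        bin_edges = c(seq(0.1, 0.9, by = 0.1), 1.0),
                        n_splits = 30L, ci_level = 0.95) {
  stopifnot(target_fpr > 0, target_fpr < 1, beta > 0,
            all(diff(bin_edges) > 0), tail(bin_edges, 1) == 1.0,
            n_splits >= 2, ci_level > 0, ci_level < 1)
  structure(list(target_fpr = target_fpr, beta = beta, bin_edges = bin_edges,
                 n_splits = n_splits, ci_level = ci_level),
            class = "eval_config")
}

check_binary <- function(labels, scores = NULL) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  if (!is.null(scores) && length(scores) != length(labels)) {
    abort("labels and probabilities differ in length")
  }
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Tie-corrected pairwise-comparison statistic: the fraction of
#' (positive, negative) pairs in which the positive outscores the negative,
#' counting ties as 1/2. Computed via midranks.
#'
#' @param labels 0/1 vector with at least one of each class.
#' @param probabilities Scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, probabilities) {
  check_binary(labels, probabilities)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    abort(sprintf("roc_auc: single-class labels (%d positive, %d negative)",
                  npos, nneg))
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble `threshold`, `fpr`, `tpr`, one row per distinct score
#'   plus the all-positive endpoint.
#' @export
roc_curve <- function(labels, probabilities) {
  check_binary(labels, probabilities)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; lab <- labels[ord]
  # cumulative counts at the last row of each tied score block =
  # counts for the rule "predict positive iff score >= threshold"
  ends <- which(c(p[-1] != p[-length(p)], TRUE))
  ctp <- cumsum(lab == 1)[ends]
  cfp <- cumsum(lab == 0)[ends]
  tibble(threshold = c(Inf, p[ends]),
         fpr = c(0, cfp / nneg),
         tpr = c(0, ctp / npos))
}

#' Decision threshold anchored at a false positive rate
#'
#' mu is chosen among the observed scores to maximize sensitivity subject
#' to the FPR cap `target_fpr`, and among the qualifying thresholds with
#' that sensitivity, the one with the lowest FPR. With overlapping score
#' distributions this lands the FPR as close to the anchor as the discrete
#' scores allow; with separable scores it yields FPR 0 at unchanged
#' sensitivity (alarms are never spent when they buy no recall). The
#' achieved FPR is reported alongside. If no observed score satisfies the
#' cap, mu is set just above the maximum score (the all-negative
#' classifier, FPR 0).
#'
#' @inheritParams roc_auc
#' @param target_fpr Anchor in (0, 1), default 0.2.
#' @return One-row tibble `threshold`, `achieved_fpr`.
#' @export
threshold_at_fpr <- function(labels, probabilities, target_fpr = 0.2) {
  check_binary(labels, probabilities)
  neg <- probabilities[labels == 0]
  pos <- probabilities[labels == 1]
  if (length(neg) == 0) abort("threshold_at_fpr: no negatives")
  cand <- sort(unique(probabilities))
  fprs <- vapply(cand, function(m) mean(neg >= m), numeric(1))
  ok <- fprs <= target_fpr
  if (!any(ok)) {
    mu <- max(probabilities) + .Machine$double.eps
    return(tibble(threshold = mu, achieved_fpr = 0))
  }
  tprs <- if (length(pos) == 0) rep(0, length(cand))
          else vapply(cand, function(m) mean(pos >= m), numeric(1))
  best_tpr <- max(tprs[ok])
  i <- which(ok & tprs == best_tpr & fprs == min(fprs[ok & tprs == best_tpr]))[1]
  tibble(threshold = cand[i], achieved_fpr = fprs[i])
}

#' Confusion matrix at a threshold
#'
#' Predicted positive iff `probability >= mu` (non-strict, so `mu = 0` is
#' the all-positive classifier).
#'
#' @inheritParams roc_auc
#' @param mu Decision threshold.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `threshold`.
#' @export
confusion_at <- function(labels, probabilities, mu) {
  check_binary(labels, probabilities)
  pred <- probabilities >= mu
  tibble(
    tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1),
    threshold = mu
  )
}

#' F-beta score
#'
#' `(1 + beta^2) P R / (beta^2 P + R)`; defined as 0 when precision and
#' recall are both 0. `beta < 1` weights precision more than recall (the
#' standard convention).
#'
#' @param cm A confusion-matrix row from [confusion_at()].
#' @param beta Weight, default 0.5.
#' @return Scalar in `[0, 1]`.
#' @export
f_beta <- function(cm, beta = 0.5) {
  p <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
  r <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  if (p == 0 && r == 0) return(0)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in `[-1, 1]`;
#' defined as 0 when any marginal factor is 0.
#'
#' @inheritParams f_beta
#' @export
mcc <- function(cm) {
  with(cm, {
    denom <- sqrt(as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (denom == 0) return(0)
    (as.double(tp) * tn - as.double(fp) * fn) / denom
  })
}

#' Precision-recall curve
#'
#' One (recall, precision) point per distinct score used as a threshold
#' (predict positive iff score >= threshold), recall monotone.
#'
#' @inheritParams roc_auc
#' @return Tibble `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, probabilities) {
  check_binary(labels, probabilities)
  npos <- sum(labels == 1)
  if (npos == 0) abort("pr_curve: no positives")
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; lab <- labels[ord]
  ends <- which(c(p[-1] != p[-length(p)], TRUE))
  ctp <- cumsum(lab == 1)[ends]
  npred <- ends
  tibble(threshold = p[ends],
         recall = ctp / npos,
         precision = ctp / npred)
}

#' Precision by probability bin
#'
#' The probability interval above the decision threshold mu is partitioned
#' into bins: fixed edges at or below mu are discarded, the first bin is
#' `[mu, next surviving edge)`, interior bins are half-open, and the last
#' bin is closed at 1. Precision (fraction of true positives) and the
#' sample count are reported per bin; empty bins report `NA` precision,
#' not 0. The count-weighted mean of bin precisions equals the overall
#' precision above mu.
#'
#' @inheritParams roc_auc
#' @param mu Decision threshold (must be < 1).
#' @param bin_edges Fixed edges, last = 1.
#' @return Tibble `bin_lo`, `bin_hi`, `count`, `precision`.
#' @export
precision_by_bin <- function(labels, probabilities, mu,
                             bin_edges = c(seq(0.1, 0.9, by = 0.1), 1.0)) {
  check_binary(labels, probabilities)
  stopifnot(mu < 1)
  edges <- c(mu, bin_edges[bin_edges > mu])
  lo <- head(edges, -1); hi <- tail(edges, -1)
  purrr::map2_dfr(lo, hi, function(a, b) {
    inbin <- probabilities >= a &
      (if (b == tail(edges, 1)) probabilities <= b else probabilities < b)
    n <- sum(inbin)
    tibble(bin_lo = a, bin_hi = b, count = n,
           precision = if (n > 0) sum(labels[inbin] == 1) / n else NA_real_)
  })
}

#' Full evaluation report
#'
#' Runs the whole battery on one set of predictions: AUC, ROC and PR
#' points, the FPR-anchored threshold and its confusion matrix, precision,
#' recall, F-beta, Matthews correlation, and precision by probability bin.
#'
#' @inheritParams roc_auc
#' @param cfg An [eval_config()].
#' @return A `vw_eval` object; see [tidy.vw_eval()] / [glance.vw_eval()].
#' @export
evaluate_predictions <- function(labels, probabilities, cfg = eval_config()) {
  check_binary(labels, probabilities)
  thr <- threshold_at_fpr(labels, probabilities, cfg$target_fpr)
  cm <- confusion_at(labels, probabilities, thr$threshold)
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  structure(list(
    auc = roc_auc(labels, probabilities),
    roc = roc_curve(labels, probabilities),
    pr = pr_curve(labels, probabilities),
    confusion = cm,
    threshold = thr$threshold,
    achieved_fpr = thr$achieved_fpr,
    precision = precision,
    recall = recall,
    f_beta = f_beta(cm, cfg$beta),
    beta = cfg$beta,
    mcc = mcc(cm),
    bins = precision_by_bin(labels, probabilities,
                            min(thr$threshold, 1 - 1e-12), cfg$bin_edges),
    n = length(labels),
    n_pos = sum(labels == 1),
    config = cfg
  ), class = "vw_eval")
}

#' @export
print.vw_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<vw_eval> n=%d (%d positive)\n  AUC %.3f | mu %.3f (FPR %.3f)",
           " | P %.3f R %.3f | F%.1f %.3f | MCC %.3f\n"),
    x$n, x$n_pos, x$auc, x$threshold, x$achieved_fpr,
    x$precision, x$recall, x$beta, x$f_beta, x$mcc))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-bin precision table; `glance()` the one-row
#' summary metrics.
#'
#' @param x A `vw_eval`.
#' @param ... Unused.
#' @export
tidy.vw_eval <- function(x, ...) x$bins

#' @rdname tidy.vw_eval
#' @export
glance.vw_eval <- function(x, ...) {
  tibble(auc = x$auc, threshold = x$threshold, achieved_fpr = x$achieved_fpr,
         tp = x$confusion$tp, fp = x$confusion$fp, tn = x$confusion$tn,
         fn = x$confusion$fn, precision = x$precision, recall = x$recall,
         f_beta = x$f_beta, mcc = x$mcc, n = x$n, n_pos = x$n_pos)
}

#' Repeated-split AUC confidence interval
#'
#' Re-runs a full split-train-test procedure `n_splits` times with
#' different patient-level splits and reports the mean AUC and a
#' t-distribution confidence interval over the split AUCs. A split whose
#' procedure returns `NA` (e.g. a single-class test set) is resampled with
#' a logged fresh seed.
#'
#' @param run_split A function `(seed) -> AUC` performing one complete
#'   split/train/evaluate cycle; return `NA` to request a resample.
#' @param n_splits Number of splits (default 30).
#' @param seed Master seed; per-split seeds derive from it.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble `mean_auc`, `ci_lo`, `ci_hi`, `sd`, `n_splits`,
#'   with the per-split AUCs in the `aucs` attribute.
#' @export
sensitivity_auc_ci <- function(run_split, n_splits = 30L, seed = 1L,
                               level = 0.95) {
  stopifnot(is.function(run_split), n_splits >= 2)
  aucs <- numeric(n_splits)
  for (i in seq_len(n_splits)) {
    s <- child_seed(seed, i)
    auc <- run_split(s)
    tries <- 0
    while (is.na(auc) && tries < 20) {
      tries <- tries + 1
      s <- child_seed(seed, i + 7919L * tries)
      vw_log("sensitivity", "split %d resampled with seed %d", i, s)
      auc <- run_split(s)
    }
    if (is.na(auc)) abort(sprintf("split %d: no usable split after resampling", i))
    aucs[i] <- auc
  }
  m <- mean(aucs)
  s <- sd(aucs)
  half <- qt(1 - (1 - level) / 2, n_splits - 1) * s / sqrt(n_splits)
  out <- tibble(mean_auc = m, ci_lo = m - half, ci_hi = m + half,
                sd = s, n_splits = n_splits)
  attr(out, "aucs") <- aucs
  out
}

#' Cohort summary table
#'
#' Baseline-characteristics summary of a filtered cohort: stay counts,
#' categorical counts with percentages, mean and SD of statics and of
#' first-24-hour vitals/labs, and respiratory-support exposure (IMV during
#' stay). Percentages follow the usual convention of `digits` decimals.
#'
#' @param cohort An `icu_cohort`.
#' @param digits Decimals for percentages (default 1).
#' @return Tibble `characteristic`, `n`, `percent`, `mean`, `sd`.
#' @export
cohort_summary <- function(cohort, digits = 1) {
  stopifnot(inherits(cohort, "icu_cohort"))
  st <- cohort$stays
  n_total <- nrow(st)
  if (n_total == 0) {
    return(tibble(characteristic = character(), n = integer(),
                  percent = numeric(), mean = numeric(), sd = numeric()))
  }
  row_cnt <- function(name, n) tibble(characteristic = name, n = n,
                                      percent = pct(n, n_total, digits),
                                      mean = NA_real_, sd = NA_real_)
  row_num <- function(name, x) tibble(characteristic = name, n = sum(!is.na(x)),
                                      percent = NA_real_,
                                      mean = mean(x, na.rm = TRUE),
                                      sd = sd(x, na.rm = TRUE))
  imv_ids <- unique(cohort$vent$stay_id)
  first24 <- cohort$events %>%
    filter(.data$time_hours < 24) %>%
    group_by(.data$stay_id, .data$feature_id) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  f24_rows <- first24 %>%
    group_by(.data$feature_id) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") %>%
    mutate(characteristic = paste0("first24_", .data$feature_id),
           percent = NA_real_) %>%
    select("characteristic", "n", "percent", "mean", "sd")
  bind_rows(
    row_cnt("n_stays", n_total),
    row_cnt("male_sex", sum(st$sex == "male", na.rm = TRUE)),
    row_num("age_years", st$age),
    row_num("weight_kg", st$weight),
    row_num("height_cm", st$height),
    row_num("los_hours", st$los_hours),
    f24_rows,
    row_cnt("imv_during_stay", sum(st$stay_id %in% imv_ids))
  )
}
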