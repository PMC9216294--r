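test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9)), 1)     # separable
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.1, .2, .8, .9)), 0)     # inverted
  expect_equal(roc_auc(c(0, 1), c(.5, .5)), 0.5)                 # pure tie
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    lab <- rbinom(n, 1, 0.4)
    if (sum(lab) == 0 || sum(lab) == n) next
    # coarse scores force plenty of ties
    sc <- round(runif(n), sample(1:2, 1))
    expect_equal(roc_auc(lab, sc), oracle_auc(lab, sc))
  }
  # chance level at large n
  set.seed(1)
  lab <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(lab, runif(10000)) - 0.5), 0.02)
  expect_error(roc_auc(rep(1, 5), runif(5)), "single-class")
})

test_that("FPR-anchored threshold matches an exhaustive scan and bounds FPR", {
  # separable: achieved FPR 0
  lab <- c(rep(0, 10), rep(1, 5))
  sc <- c(seq(0.1, 0.28, by = 0.02), seq(0.6, 0.68, by = 0.02))
  thr <- threshold_at_fpr(lab, sc, 0.2)
  expect_equal(thr$achieved_fpr, 0)
  expect_true(all(sc[lab == 0] < thr$threshold))

  set.seed(7)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    lab <- rbinom(n, 1, 0.3)
    if (all(lab == 1)) next
    sc <- round(runif(n), 2)
    thr <- threshold_at_fpr(lab, sc, 0.2)
    neg <- sc[lab == 0]; pos <- sc[lab == 1]
    # oracle: scan every candidate, maximize TPR under the cap, then
    # minimize FPR
    cand <- sort(unique(sc))
    fpr <- vapply(cand, function(m) mean(neg >= m), numeric(1))
    tpr <- vapply(cand, function(m) mean(pos >= m), numeric(1))
    elig <- which(fpr <= 0.2)
    if (length(elig) > 0) {
      best <- elig[tpr[elig] == max(tpr[elig])]
      best <- best[fpr[best] == min(fpr[best])][1]
      expect_equal(thr$threshold, cand[best])
      expect_equal(thr$achieved_fpr, fpr[best])
    }
    expect_lte(thr$achieved_fpr, 0.2)
  }
})

test_that("confusion matrix counts follow the non-strict threshold rule", {
  lab <- c(1, 0, 1, 0, 1)
  sc <- c(0.9, 0.8, 0.3, 0.1, 0.8)
  cm <- confusion_at(lab, sc, 0.8)
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1); expect_equal(cm$tn, 1)
  # mu = 0: everything positive
  cm0 <- confusion_at(lab, sc, 0)
  expect_equal(cm0$fn, 0); expect_equal(cm0$tn, 0)
  # mu above 1: everything negative
  cm1 <- confusion_at(lab, sc, 1 + 1e-9)
  expect_equal(cm1$tp, 0); expect_equal(cm1$fp, 0)
  # 30-point random set vs direct enumeration
  set.seed(3)
  lab <- rbinom(30, 1, 0.4); sc <- round(runif(30), 2)
  cm <- confusion_at(lab, sc, 0.5)
  expect_equal(cm$tp, sum(sc >= 0.5 & lab == 1))
  expect_equal(cm$fp, sum(sc >= 0.5 & lab == 0))
  expect_equal(cm$tp + cm$fn, sum(lab))
  expect_equal(cm$fp + cm$tn, sum(lab == 0))
})

test_that("F-beta and MCC equal their closed forms", {
  perfect <- tibble::tibble(tp = 10, fp = 0, tn = 10, fn = 0)
  for (b in c(0.5, 1, 2)) expect_equal(f_beta(perfect, b), 1)
  expect_equal(mcc(perfect), 1)
  inverted <- tibble::tibble(tp = 0, fp = 10, tn = 0, fn = 10)
  expect_equal(mcc(inverted), -1)
  expect_equal(f_beta(inverted, 1), 0)
  half <- tibble::tibble(tp = 5, fp = 5, tn = 5, fn = 5)   # P = R = 0.5
  expect_equal(f_beta(half, 1), 0.5)
  # beta = 0.5, P = 0.2, R = 0.8
  cm <- tibble::tibble(tp = 4, fp = 16, tn = 0, fn = 1)
  expect_equal(f_beta(cm, 0.5), (1 + 0.25) * 0.2 * 0.8 / (0.25 * 0.2 + 0.8))
  # random confusion matrices vs oracle closed forms
  set.seed(11)
  for (i in 1:25) {
    v <- as.list(rpois(4, 8)); names(v) <- c("tp", "fp", "tn", "fn")
    cm <- tibble::as_tibble(v)
    expect_equal(f_beta(cm, 0.5), oracle_fbeta(cm$tp, cm$fp, cm$fn, 0.5))
    expect_equal(mcc(cm), oracle_mcc(cm$tp, cm$fp, cm$tn, cm$fn))
  }
})

test_that("PR curve matches a threshold scan and handles ties", {
  lab <- c(rep(0, 10), rep(1, 5))
  sc <- c(runif(10, 0, 0.4), runif(5, 0.6, 1))
  pr <- pr_curve(lab, sc)
  expect_true(all(pr$precision[pr$recall > 0 & pr$threshold >= 0.6] == 1))
  # all scores tied: single point at (recall 1, precision = prevalence)
  prt <- pr_curve(lab, rep(0.7, 15))
  expect_equal(nrow(prt), 1)
  expect_equal(prt$recall, 1)
  expect_equal(prt$precision, 5 / 15)
  # 20-point random set vs exhaustive scan
  set.seed(5)
  lab <- rbinom(20, 1, 0.5); sc <- round(runif(20), 1)
  pr <- pr_curve(lab, sc)
  for (i in seq_len(nrow(pr))) {
    m <- pr$threshold[i]
    expect_equal(pr$recall[i], sum(sc >= m & lab == 1) / sum(lab))
    expect_equal(pr$precision[i], sum(sc >= m & lab == 1) / sum(sc >= m))
  }
})

test_that("precision by bin partitions [mu, 1] and aggregates to overall precision", {
  set.seed(13)
  lab <- rbinom(400, 1, 0.3)
  sc <- runif(400)
  mu <- 0.17
  bins <- precision_by_bin(lab, sc, mu)
  expect_equal(bins$bin_lo[1], mu)
  expect_equal(bins$bin_hi[1], 0.2)   # the 0.1 edge below mu is discarded
  expect_equal(dplyr::last(bins$bin_hi), 1)
  expect_equal(sum(bins$count), sum(sc >= mu))
  overall <- sum(lab[sc >= mu] == 1) / sum(sc >= mu)
  got <- sum(bins$precision * bins$count, na.rm = TRUE) / sum(bins$count)
  expect_equal(got, overall)
  # all probabilities inside one bin
  sc1 <- runif(400, 0.52, 0.58)
  b1 <- precision_by_bin(lab, sc1, 0.5)
  nz <- b1[b1$count > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$precision, mean(lab))
  # empty bins report NA precision, not zero
  expect_true(all(is.na(b1$precision[b1$count == 0])))
  # calibrated scores: precision non-decreasing across populated bins
  p_true <- sort(runif(4000))
  lab_c <- rbinom(4000, 1, p_true)
  bc <- precision_by_bin(lab_c, p_true, 0.1)
  pop <- bc$precision[bc$count > 20]
  expect_true(all(diff(pop) > -0.12))
})

test_that("evaluation report metrics are mutually consistent", {
  set.seed(17)
  lab <- rbinom(500, 1, 0.2)
  sc <- plogis(2 * lab + rnorm(500) - 1)
  ev <- evaluate_predictions(lab, sc)
  g <- glance(ev)
  expect_equal(g$precision, g$tp / (g$tp + g$fp))
  expect_equal(g$recall, g$tp / (g$tp + g$fn))
  expect_equal(g$tp + g$fn, sum(lab))
  expect_equal(g$auc, roc_auc(lab, sc))
  expect_equal(g$f_beta, f_beta(ev$confusion, 0.5))
  expect_equal(g$mcc, mcc(ev$confusion))
  expect_lte(g$achieved_fpr, 0.2)
  expect_s3_class(tidy(ev), "tbl_df")
})

test_that("repeated-split CI is a t interval, seed-order invariant", {
  # degenerate: identical AUC every split -> zero width
  ci0 <- sensitivity_auc_ci(function(s) 0.8, n_splits = 5, seed = 1)
  expect_equal(ci0$mean_auc, 0.8)
  expect_equal(ci0$ci_lo, 0.8)
  expect_equal(ci0$ci_hi, 0.8)
  # mean inside CI; t-formula reproduced
  run <- function(s) { set.seed(s); 0.8 + rnorm(1, 0, 0.02) }
  ci <- sensitivity_auc_ci(run, n_splits = 10, seed = 2)
  aucs <- attr(ci, "aucs")
  expect_true(ci$ci_lo <= ci$mean_auc && ci$mean_auc <= ci$ci_hi)
  half <- stats::qt(0.975, 9) * stats::sd(aucs) / sqrt(10)
  expect_equal(ci$ci_hi - ci$mean_auc, half)
  # deterministic given the master seed
  ci2 <- sensitivity_auc_ci(run, n_splits = 10, seed = 2)
  expect_equal(ci$mean_auc, ci2$mean_auc)
  # NA splits get resampled
  flaky <- function(s) if (s %% 2 == 0) NA else 0.7
  expect_no_error(suppressMessages(
    sensitivity_auc_ci(flaky, n_splits = 4, seed = 3)))
})

test_that("cohort summary percentages follow the printed-table convention", {
  expect_equal(ventwatch:::pct(6281, 11816, 0), 53)
  expect_equal(ventwatch:::pct(160, 1061, 1), 15.1)
  coh <- random_cohort(20, seed = 71)
  s <- cohort_summary(coh)
  expect_equal(s$n[s$characteristic == "n_stays"], 20)
  n_imv <- length(unique(coh$vent$stay_id))
  expect_equal(s$n[s$characteristic == "imv_during_stay"], n_imv)
  expect_equal(s$percent[s$characteristic == "imv_during_stay"],
               round(100 * n_imv / 20, 1))
  expect_equal(s$mean[s$characteristic == "age_years"], mean(coh$stays$age))
  # empty cohort: empty table, no division by zero
  e <- cohort_summary(icu_cohort(make_stay_tbl()[0, ], empty_events(),
                                 empty_vent()))
  expect_equal(nrow(e), 0)
})
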