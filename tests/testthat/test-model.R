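space_fast <- hyper_space(n_draws = 2, nrounds = c(20, 40))

split_planted <- function(n, seed, ...) {
  w <- planted_windows(n, seed, ...)
  idx <- seq_len(n)
  list(train = ventwatch:::new_vw_windows(
         w$features[idx %% 3 != 0, , drop = FALSE], w$meta[idx %% 3 != 0, ],
         w$manifest, w$config, w$standardization, w$feature_ids),
       valid = ventwatch:::new_vw_windows(
         w$features[idx %% 3 == 0, , drop = FALSE], w$meta[idx %% 3 == 0, ],
         w$manifest, w$config, w$standardization, w$feature_ids))
}

test_that("training is deterministic and learns a planted signal", {
  d <- split_planted(1500, seed = 2)
  m1 <- train_onset_model(d$train, d$valid, space_fast, seed = 4)
  m2 <- train_onset_model(d$train, d$valid, space_fast, seed = 4)
  expect_identical(xgboost::xgb.dump(m1$booster), xgboost::xgb.dump(m2$booster))
  expect_equal(m1$search_log$valid_auc, m2$search_log$valid_auc)

  # near-separable feature: validation AUC >= 0.95
  ds <- split_planted(1500, seed = 3, separable = TRUE)
  ms <- train_onset_model(ds$train, ds$valid, space_fast, seed = 4)
  expect_gte(max(ms$search_log$valid_auc), 0.95)
})

test_that("no-signal data yields chance-level validation AUC", {
  d <- split_planted(2000, seed = 5, signal = 0)
  m <- train_onset_model(d$train, d$valid, space_fast, seed = 6)
  expect_lt(abs(max(m$search_log$valid_auc) - 0.5), 0.1)
})

test_that("single-class training sets are rejected with class counts", {
  d <- split_planted(300, seed = 7)
  d$train$meta$label <- 0L
  expect_error(train_onset_model(d$train, d$valid, space_fast, seed = 1),
               "0 positive")
})

test_that("prediction checks the manifest and preserves order", {
  d <- split_planted(600, seed = 8)
  m <- train_onset_model(d$train, d$valid, space_fast, seed = 9)
  p <- predict(m, d$valid)
  expect_true(all(p > 0 & p < 1))
  # permutation invariance
  perm <- sample(nrow(d$valid$features))
  p2 <- predict(m, d$valid$features[perm, , drop = FALSE])
  expect_equal(p2, p[perm])
  # manifest mismatch errors list the offending columns
  bad <- d$valid$features
  colnames(bad)[2] <- "zz"
  expect_error(predict(m, bad), "missing: f2",
               class = "ventwatch_manifest_error")
  expect_error(predict(m, bad), "extra: zz",
               class = "ventwatch_manifest_error")
})

test_that("prediction equals an independent tree-walk oracle", {
  d <- split_planted(800, seed = 11)
  m <- train_onset_model(d$train, d$valid,
                         hyper_space(n_draws = 1, nrounds = c(2, 2),
                                     subsample = c(1, 1),
                                     colsample_bytree = c(1, 1)),
                         seed = 12)
  dump <- xgboost::xgb.model.dt.tree(model = m$booster)
  walk_tree <- function(tree, x) {
    node <- tree[tree$Node == 0, ]
    while (node$Feature != "Leaf") {
      xv <- x[[node$Feature]]
      nxt <- if (is.na(xv)) node$Missing
             else if (xv < node$Split) node$Yes else node$No
      node <- tree[tree$ID == nxt, ]
    }
    node$Gain      # leaf weight is stored in the Gain column
  }
  base_score <- xgboost::xgb.config(m$booster)$learner$learner_model_param$base_score
  X <- d$valid$features[1:20, , drop = FALSE]
  want <- vapply(seq_len(nrow(X)), function(i) {
    x <- as.list(X[i, ])
    margin <- sum(vapply(unique(dump$Tree), function(tr) {
      walk_tree(dump[dump$Tree == tr, ], x)
    }, numeric(1)))
    stats::plogis(margin + stats::qlogis(as.numeric(base_score)))
  }, numeric(1))
  got <- predict(m, X)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("importance is a normalized squared-gain ranking agreeing with the library", {
  d <- split_planted(1500, seed = 13, signal = 3)
  m <- train_onset_model(d$train, d$valid, space_fast, seed = 14)
  imp <- feature_importance(m)
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$importance, sort(imp$importance, decreasing = TRUE))
  expect_equal(imp$column[1], "f1")  # the planted signal dominates
  # independent recomputation from the dump
  dump <- xgboost::xgb.model.dt.tree(model = m$booster)
  sp <- dump[dump$Feature != "Leaf", ]
  want <- sum(sp$Gain[sp$Feature == "f1"]^2) / sum(tapply(sp$Gain^2, sp$Feature, sum))
  expect_equal(imp$importance[imp$column == "f1"], want)
  # top-5 membership vs the library's gain ranking
  lib <- xgboost::xgb.importance(model = m$booster)
  expect_gte(length(intersect(head(imp$column, 5), head(lib$Feature, 5))), 4)
})

test_that("adaptation preserves the source ensemble and its zero-round identity", {
  d <- split_planted(1200, seed = 15)
  m <- train_onset_model(d$train, d$valid, space_fast, seed = 16)
  tgt <- split_planted(600, seed = 17)
  p0 <- predict(m, tgt$valid)

  a0 <- adapt_model(m, tgt$train, tgt$valid,
                    adapt_config(rounds = c(0, 0), n_draws = 1), seed = 18)
  expect_identical(predict(a0, tgt$valid), p0)

  a <- adapt_model(m, tgt$train, tgt$valid,
                   adapt_config(rounds = c(5, 15), n_draws = 2), seed = 18)
  d_src <- xgboost::xgb.model.dt.tree(model = m$booster)
  d_ad <- xgboost::xgb.model.dt.tree(model = a$booster)
  n_src <- max(d_src$Tree) + 1
  expect_equal(a$n_source_rounds, n_src)
  expect_identical(d_ad[d_ad$Tree < n_src, ], d_src)
  # source model untouched by the adaptation
  expect_identical(predict(m, tgt$valid), p0)
  # zero target positives in the fit split is an error
  tgt$train$meta$label <- 0L
  expect_error(adapt_model(m, tgt$train, tgt$valid, seed = 1), "0 positive")
})

test_that("models survive a save/load round trip and reject corrupt artifacts", {
  d <- split_planted(600, seed = 19)
  m <- train_onset_model(d$train, d$valid, space_fast, seed = 20)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  expect_identical(predict(back, d$valid), predict(m, d$valid))
  expect_equal(back$seed, m$seed)
  expect_equal(back$kind, m$kind)
  expect_equal(back$manifest_cols, m$manifest_cols)
  expect_equal(back$hyperparams$nrounds, m$hyperparams$nrounds)

  # truncated booster file -> format error
  mf <- file.path(dir, "model.json")
  raw <- readBin(mf, "raw", file.size(mf))
  writeBin(raw[1:100], mf)
  expect_error(load_model(dir), class = "ventwatch_format_error")

  # version mismatch -> explicit error
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  meta$format_version <- 99
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "version", class = "ventwatch_format_error")
})

test_that("doubling training data does not hurt held-out AUC", {
  aucs <- purrr::map_dfr(1:3, function(s) {
    big <- planted_windows(2400, seed = 100 + s, signal = 1.2)
    test <- planted_windows(1200, seed = 200 + s, signal = 1.2)
    half_idx <- seq_len(1200)
    half <- ventwatch:::new_vw_windows(
      big$features[half_idx, , drop = FALSE], big$meta[half_idx, ],
      big$manifest, big$config, big$standardization, big$feature_ids)
    fit <- function(w) train_onset_model(
      w, test, hyper_space(n_draws = 1, nrounds = c(40, 40)), seed = s)
    tibble::tibble(
      small = roc_auc(test$meta$label, predict(fit(half), test)),
      large = roc_auc(test$meta$label, predict(fit(big), test)))
  })
  expect_gte(mean(aucs$large), mean(aucs$small) - 0.01)
})
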