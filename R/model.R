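#' Hyperparameter search space
#'
#' Ranges for the random search used by [train_onset_model()]. Each draw
#' samples tree depth, learning rate, boosting rounds, row/column
#' subsampling, minimum child weight and (optionally) the positive-class
#' weight; the draw maximizing validation AUC wins. When
#' `scale_pos_weight` is `NULL` it defaults to the training set's
#' negative/positive count ratio, the standard correction for
#' class-imbalanced boosting.
#'
#' @param max_depth Integer range `c(lo, hi)`.
#' @param learning_rate Range, sampled log-uniformly.
#' @param nrounds Integer range of boosting rounds (searched instead of
#'   early stopping, for reproducibility of the chosen configuration).
#' @param subsample,colsample_bytree Ranges in (0, 1].
#' @param min_child_weight Range.
#' @param scale_pos_weight `NULL` (use neg/pos of the training set) or a
#'   multiplier range applied to that default.
#' @param n_draws Number of random draws (>= 1).
#' @return A `hyper_space` list.
#' @export
hyper_space <- function(max_depth = c(3L, 8L), learning_rate = c(0.03, 0.3),
                        nrounds = c(50L, 300L), subsample = c(0.6, 1),
                        colsample_bytree = c(0.6, 1),
                        min_child_weight = c(1, 10),
                        scale_pos_weight = NULL, n_draws = 10L) {
  stopifnot(n_draws >= 1)
  structure(list(max_depth = max_depth, learning_rate = learning_rate,
                 nrounds = nrounds, subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 min_child_weight = min_child_weight,
                 scale_pos_weight = scale_pos_weight, n_draws = n_draws),
            class = "hyper_space")
}

draw_hyperparams <- function(space, seed, default_spw) {
  set.seed(seed)
  n <- space$n_draws
  runif_r <- function(r) runif(n, r[1], r[2])
  tibble(
    draw = seq_len(n),
    max_depth = as.integer(round(runif_r(space$max_depth))),
    learning_rate = exp(runif_r(log(space$learning_rate))),
    nrounds = as.integer(round(runif_r(space$nrounds))),
    subsample = runif_r(space$subsample),
    colsample_bytree = runif_r(space$colsample_bytree),
    min_child_weight = runif_r(space$min_child_weight),
    scale_pos_weight = if (is.null(space$scale_pos_weight)) default_spw
                       else default_spw * runif_r(space$scale_pos_weight)
  )
}

windows_dmatrix <- function(w) {
  xgboost::xgb.DMatrix(w$features, label = w$meta$label, nthread = 1)
}

check_classes <- function(meta, where) {
  npos <- sum(meta$label == 1)
  nneg <- sum(meta$label == 0)
  if (npos == 0 || nneg == 0) {
    abort(sprintf("%s: need both classes, got %d positive and %d negative",
                  where, npos, nneg))
  }
  c(pos = npos, neg = nneg)
}

#' Train the gradient-boosted onset classifier
#'
#' Fits a boosted-tree binary classifier to labeled window samples by
#' random hyperparameter search: each draw from `space` is trained on
#' `train` and scored by AUC on `valid` (disjoint patient sets); the best
#' draw's model is returned. The positive class is up-weighted by
#' `scale_pos_weight` (defaulting to the training neg/pos ratio). Fully
#' reproducible given `seed`: the search draws and each booster's own RNG
#' are seeded deterministically, and training is single-threaded.
#'
#' @param train,valid `vw_windows` from disjoint patient sets, each holding
#'   both classes.
#' @param space A [hyper_space()].
#' @param seed Integer seed.
#' @return A `vw_model`: the booster plus the column manifest, window
#'   config, standardization parameters, chosen hyperparameters, the full
#'   search log, and training metadata.
#' @export
train_onset_model <- function(train, valid, space = hyper_space(), seed = 1L) {
  stopifnot(inherits(train, "vw_windows"), inherits(valid, "vw_windows"))
  cls <- check_classes(train$meta, "train_onset_model (training set)")
  check_classes(valid$meta, "train_onset_model (validation set)")
  if (!identical(colnames(train$features), colnames(valid$features))) {
    abort("train_onset_model: train/valid feature manifests differ")
  }
  default_spw <- unname(cls["neg"] / cls["pos"])
  draws <- draw_hyperparams(space, seed, default_spw)
  dtrain <- windows_dmatrix(train)
  dvalid_x <- valid$features

  fit_one <- function(i) {
    d <- draws[i, ]
    params <- xgboost::xgb.params(
      objective = "binary:logistic", tree_method = "hist", nthread = 1,
      seed = child_seed(seed, i),
      max_depth = d$max_depth, learning_rate = d$learning_rate,
      subsample = d$subsample, colsample_bytree = d$colsample_bytree,
      min_child_weight = d$min_child_weight,
      scale_pos_weight = d$scale_pos_weight
    )
    booster <- xgboost::xgb.train(params, dtrain, nrounds = d$nrounds,
                                  verbose = 0)
    auc <- roc_auc(valid$meta$label, predict(booster, dvalid_x))
    list(booster = booster, auc = auc)
  }

  fits <- purrr::map(seq_len(nrow(draws)), fit_one)
  draws$valid_auc <- purrr::map_dbl(fits, "auc")
  best <- which.max(draws$valid_auc)
  new_vw_model(
    booster = fits[[best]]$booster,
    manifest_cols = colnames(train$features),
    manifest = train$manifest,
    feature_ids = train$feature_ids,
    config = train$config,
    standardization = train$standardization,
    hyperparams = as.list(draws[best, ]),
    search_log = draws,
    seed = seed,
    kind = "source"
  )
}

new_vw_model <- function(booster, manifest_cols, manifest, feature_ids,
                         config, standardization, hyperparams, search_log,
                         seed, kind, n_source_rounds = NULL) {
  structure(list(booster = booster, manifest_cols = manifest_cols,
                 manifest = manifest, feature_ids = feature_ids,
                 config = config, standardization = standardization,
                 hyperparams = hyperparams, search_log = search_log,
                 seed = seed, kind = kind,
                 n_source_rounds = n_source_rounds),
            class = "vw_model")
}

#' @export
print.vw_model <- function(x, ...) {
  cat(sprintf("<vw_model> %s, %d boosting rounds, %d features, gap %d h\n",
              x$kind, xgboost::xgb.get.num.boosted.rounds(x$booster),
              length(x$manifest_cols), x$config$gap))
  invisible(x)
}

#' Predict onset probabilities
#'
#' @param object A `vw_model`.
#' @param newdata A `vw_windows` or a numeric matrix whose columns match
#'   the model's feature manifest exactly (order and names); a mismatch is
#'   an error listing missing and extra columns.
#' @param type `"prob"` for probabilities, `"margin"` for raw log-odds.
#' @param ... Unused.
#' @return Numeric vector, one value per sample row, order-preserving.
#' @export
predict.vw_model <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "vw_windows")) newdata$features else newdata
  check_manifest(object$manifest_cols, colnames(X))
  if (nrow(X) == 0) return(numeric(0))
  predict(object$booster, X, outputmargin = (type == "margin"))
}

check_manifest <- function(expected, got) {
  if (identical(expected, got)) return(invisible(TRUE))
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  msg <- "feature manifest mismatch"
  if (length(missing)) msg <- paste0(msg, "; missing: ",
                                     paste(head(missing, 10), collapse = ", "))
  if (length(extra)) msg <- paste0(msg, "; extra: ",
                                   paste(head(extra, 10), collapse = ", "))
  if (!length(missing) && !length(extra)) msg <- paste0(msg, " (column order differs)")
  abort(msg, class = "ventwatch_manifest_error")
}

#' Adaptation configuration
#'
#' @param fit_fraction Fraction of target-cohort patients used for fitting
#'   the adaptation (the remainder evaluates it); default 0.7.
#' @param rounds Integer range of additional boosting rounds, searched.
#' @param learning_rate Range of adaptation learning rate, searched
#'   log-uniformly.
#' @param n_draws Random-search draws.
#' @param keep_source_baseline Include the unadapted source model as a
#'   zero-round candidate in the search, so adaptation is a no-op whenever
#'   no draw beats the source model on the target validation set. This is
#'   what guarantees the adaptation preserves the source model's strength
#'   when the domains already match.
#' @param freeze_source_trees Must be `TRUE`: adaptation appends new trees
#'   by continued boosting and never alters the source trees.
#' @return An `adapt_config` list.
#' @export
adapt_config <- function(fit_fraction = 0.7, rounds = c(10L, 150L),
                         learning_rate = c(0.02, 0.15), n_draws = 8L,
                         keep_source_baseline = TRUE,
                         freeze_source_trees = TRUE) {
  stopifnot(fit_fraction > 0, fit_fraction < 1, n_draws >= 1)
  if (!isTRUE(freeze_source_trees)) {
    abort("adapt_config: only freeze_source_trees = TRUE is supported")
  }
  structure(list(fit_fraction = fit_fraction, rounds = rounds,
                 learning_rate = learning_rate, n_draws = n_draws,
                 keep_source_baseline = isTRUE(keep_source_baseline),
                 freeze_source_trees = TRUE),
            class = "adapt_config")
}

#' Adapt a source-domain model to a target domain
#'
#' Transfer learning for the boosted ensemble: the source model's trees are
#' preserved verbatim and additional trees are fitted by continued boosting
#' on the target fit samples, so the new trees correct the source model's
#' raw score (which is exactly the starting margin of continued boosting).
#' The number of added rounds, the adaptation learning rate and the
#' positive-class weight are chosen by random search scored on
#' `target_valid`. The result is one ensemble: source trees followed by
#' target trees.
#'
#' @param source A source-domain `vw_model`.
#' @param target_fit,target_valid `vw_windows` built with the *source*
#'   model's standardization parameters and manifest, from disjoint target
#'   patients.
#' @param cfg An [adapt_config()].
#' @param seed Integer seed.
#' @return A `vw_model` with `kind = "adapted"` and `n_source_rounds`
#'   recording where the source ensemble ends.
#' @export
adapt_model <- function(source, target_fit, target_valid,
                        cfg = adapt_config(), seed = 1L) {
  stopifnot(inherits(source, "vw_model"))
  cls <- check_classes(target_fit$meta, "adapt_model (target fit set)")
  check_classes(target_valid$meta, "adapt_model (target validation set)")
  check_manifest(source$manifest_cols, colnames(target_fit$features))
  check_manifest(source$manifest_cols, colnames(target_valid$features))

  default_spw <- unname(cls["neg"] / cls["pos"])
  set.seed(seed)
  n <- cfg$n_draws
  draws <- tibble(
    draw = seq_len(n),
    rounds = as.integer(round(runif(n, cfg$rounds[1], cfg$rounds[2]))),
    learning_rate = exp(runif(n, log(cfg$learning_rate[1]),
                              log(cfg$learning_rate[2]))),
    scale_pos_weight = default_spw
  )
  if (cfg$keep_source_baseline) {
    draws <- bind_rows(
      tibble(draw = 0L, rounds = 0L,
             learning_rate = NA_real_, scale_pos_weight = NA_real_),
      draws)
  }
  dfit <- windows_dmatrix(target_fit)
  src_params <- source$hyperparams
  n_src <- xgboost::xgb.get.num.boosted.rounds(source$booster)

  fit_one <- function(i) {
    d <- draws[i, ]
    if (d$rounds == 0L) {
      booster <- source$booster
    } else {
      params <- xgboost::xgb.params(
        objective = "binary:logistic", tree_method = "hist", nthread = 1,
        seed = child_seed(seed, 1000L + i),
        max_depth = src_params$max_depth,
        learning_rate = d$learning_rate,
        subsample = src_params$subsample,
        colsample_bytree = src_params$colsample_bytree,
        min_child_weight = src_params$min_child_weight,
        scale_pos_weight = d$scale_pos_weight
      )
      booster <- xgboost::xgb.train(params, dfit, nrounds = d$rounds,
                                    verbose = 0, xgb_model = source$booster)
    }
    auc <- roc_auc(target_valid$meta$label,
                   predict(booster, target_valid$features))
    list(booster = booster, auc = auc)
  }

  fits <- purrr::map(seq_len(nrow(draws)), fit_one)
  draws$valid_auc <- purrr::map_dbl(fits, "auc")
  best <- which.max(draws$valid_auc)
  new_vw_model(
    booster = fits[[best]]$booster,
    manifest_cols = source$manifest_cols,
    manifest = source$manifest,
    feature_ids = source$feature_ids,
    config = source$config,
    standardization = source$standardization,
    hyperparams = modifyList(src_params, as.list(draws[best, ])),
    search_log = draws,
    seed = seed,
    kind = "adapted",
    n_source_rounds = n_src
  )
}

#' Feature importance from the tree dump
#'
#' Walks the ensemble's tree dump and scores every model column by the sum
#' over its splits of the squared split improvement (gain) — split count
#' weighted by squared improvement — normalized to sum to 1. Ties are
#' broken by manifest order. `aggregate_importance()` folds the per-column
#' scores (feature x channel x in-window hour) back onto base features.
#'
#' @param model A `vw_model`.
#' @return Tibble `column`, `importance` (descending). For
#'   `aggregate_importance()`: tibble `feature_id`, `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "vw_model"))
  dump <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- dump[dump$Feature != "Leaf", , drop = FALSE]
  if (nrow(splits) == 0) {
    return(tibble(column = character(), importance = numeric()))
  }
  raw <- tapply(splits$Gain^2, splits$Feature, sum)
  out <- tibble(column = names(raw), importance = as.numeric(raw)) %>%
    mutate(importance = .data$importance / sum(.data$importance))
  # descending importance, ties by manifest order
  ord <- order(-out$importance, match(out$column, model$manifest_cols))
  out[ord, , drop = FALSE]
}

#' @rdname feature_importance
#' @param importance Output of `feature_importance()`.
#' @param manifest The model's column manifest (`model$manifest`).
#' @export
aggregate_importance <- function(importance, manifest) {
  importance %>%
    left_join(manifest, by = "column") %>%
    group_by(.data$feature_id) %>%
    summarise(importance = sum(.data$importance), .groups = "drop") %>%
    arrange(dplyr::desc(.data$importance))
}

#' @export
tidy.vw_model <- function(x, ...) feature_importance(x)

#' @export
glance.vw_model <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_rounds = xgboost::xgb.get.num.boosted.rounds(x$booster),
    n_source_rounds = x$n_source_rounds %||% NA_integer_,
    n_features = length(x$manifest_cols),
    gap = x$config$gap,
    valid_auc = max(x$search_log$valid_auc),
    seed = x$seed
  )
}

VW_MODEL_FORMAT_VERSION <- 1L

#' Save and load a fitted model
#'
#' The booster is stored in the boosting library's canonical JSON tree
#' format; a JSON sidecar carries the format version, column manifest,
#' window config, standardization parameters, hyperparameters and seeds.
#' The round trip is lossless: reloaded models predict bit-identically.
#'
#' @param model A `vw_model`.
#' @param path Directory to write `model.json` and `meta.json` into.
#' @return `load_model()` returns the `vw_model`; a version mismatch or a
#'   corrupt booster file is an explicit error.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vw_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(path, "model.json"))
  meta <- list(
    format_version = VW_MODEL_FORMAT_VERSION,
    kind = model$kind,
    seed = model$seed,
    manifest_cols = model$manifest_cols,
    manifest = model$manifest,
    feature_ids = model$feature_ids,
    config = unclass(model$config),
    standardization = model$standardization,
    hyperparams = model$hyperparams,
    search_log = model$search_log,
    n_source_rounds = model$n_source_rounds
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("no model at %s", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), VW_MODEL_FORMAT_VERSION)) {
    abort(sprintf("model format version %s not supported (expected %d)",
                  meta$format_version, VW_MODEL_FORMAT_VERSION),
          class = "ventwatch_format_error")
  }
  booster <- tryCatch(
    xgboost::xgb.load(file.path(path, "model.json")),
    error = function(e) abort(sprintf("corrupt model file: %s", conditionMessage(e)),
                              class = "ventwatch_format_error")
  )
  new_vw_model(
    booster = booster,
    manifest_cols = meta$manifest_cols,
    manifest = as_tibble(meta$manifest),
    feature_ids = meta$feature_ids,
    config = do.call(window_config, meta$config),
    standardization = as_tibble(meta$standardization),
    hyperparams = meta$hyperparams,
    search_log = as_tibble(meta$search_log),
    seed = meta$seed,
    kind = meta$kind,
    n_source_rounds = meta$n_source_rounds
  )
}
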