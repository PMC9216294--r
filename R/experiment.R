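#' Featurize a cohort end to end
#'
#' Convenience pipeline: outlier filtering, hourly triplet aggregation,
#' derived respiratory indices, standardization (fitted on the given
#' training stays, or reused from a source model), rare-feature exclusion,
#' imputation and window enumeration.
#'
#' @param cohort An `icu_cohort` (already cohort-filtered).
#' @param registry Feature registry.
#' @param cfg A [window_config()].
#' @param params Standardization parameters to reuse (e.g. a source
#'   model's); fitted on `train_ids` when `NULL`.
#' @param features Feature subset to keep (e.g. a source model's);
#'   rare-feature exclusion on `train_ids` when `NULL`.
#' @param train_ids Stay ids allowed to inform standardization and
#'   rare-feature counts (leakage guard); default all stays in `cohort`.
#' @param min_count Rare-feature threshold (see [exclude_rare_features()]).
#' @param operational Include clinician-set features?
#' @return A `vw_windows`.
#' @export
featurize_cohort <- function(cohort, registry = default_registry(),
                             cfg = window_config(), params = NULL,
                             features = NULL, train_ids = NULL,
                             min_count = 1000, operational = TRUE) {
  cohort <- apply_outlier_thresholds(cohort, registry, quiet = TRUE)
  hg <- aggregate_hourly(cohort, registry) %>% add_derived_indices()
  if (is.null(params)) params <- fit_standardization(hg, train_ids)
  if (is.null(features)) {
    kept <- exclude_rare_features(hg, min_count, train_ids)
    allowed <- c(toggle_operational_features(registry, operational),
                 "rox", "sf_ratio", "pf_ratio")
    features <- intersect(kept, allowed)
  }
  hgi <- impute_hourly(hg, params)
  states <- derive_vent_states(cohort)
  enumerate_windows(hgi, states, cfg, features)
}

# Column-subset a vw_windows to the given base features (statics kept).
select_window_features <- function(w, feature_ids) {
  man <- w$manifest
  keep_man <- man[man$channel == "static" | man$feature_id %in% feature_ids, ,
                  drop = FALSE]
  new_vw_windows(w$features[, keep_man$column, drop = FALSE], w$meta,
                 keep_man, w$config, w$standardization,
                 intersect(w$feature_ids, feature_ids))
}

#' Run the full experiment grid
#'
#' Orchestrates the study's regimes over gap horizons and the
#' operational-features toggle:
#' \describe{
#'   \item{source}{train on the source cohort's training split (random
#'     hyperparameter search on a patient-level validation carve-out),
#'     evaluate on the held-out source test split.}
#'   \item{as-is}{apply the source model unchanged to the target cohort's
#'     evaluation split.}
#'   \item{adapt}{two-step model: continue boosting the source model on the
#'     target fit split, evaluate on the target evaluation split.}
#'   \item{target-only}{one-step model: train from scratch on the target
#'     fit portion using the source model's feature list, evaluate on the
#'     same target evaluation split.}
#' }
#' Target windows for as-is and adapt are featurized with the source
#' model's standardization parameters and manifest. All splits are at the
#' patient level and every regime for a given (gap, operational) cell
#' shares them, so the comparisons are paired.
#'
#' @param source Source `icu_cohort` (pre-filtering is applied here).
#' @param target Optional target `icu_cohort`; required for the target
#'   regimes.
#' @param regimes Subset of `c("source", "as-is", "adapt", "target-only")`.
#' @param gaps Gap horizons in hours (default 6).
#' @param operational Logical vector of operational-feature settings to
#'   run (default both).
#' @param space [hyper_space()] for source and target-only training.
#' @param acfg [adapt_config()] for adaptation.
#' @param ecfg [eval_config()].
#' @param cspec [cohort_spec()] applied to both cohorts.
#' @param source_split,target_split Named fractions: source
#'   train/valid/test (default 0.72/0.08/0.20, i.e. a 10% validation
#'   carve-out of the 80% development portion) and target fit/valid/eval
#'   (default 0.56/0.14/0.30, i.e. 70% for fitting of which a fifth
#'   validates the adaptation search, 30% held out).
#' @param min_count Rare-feature threshold for the source cohort.
#' @param seed Master seed.
#' @return A tibble with one row per (regime, operational, gap):
#'   summary metrics plus list columns `eval` (`vw_eval`) and `model`
#'   (`vw_model`, where applicable).
#' @export
run_experiment <- function(source, target = NULL,
                           regimes = c("source", "as-is", "adapt", "target-only"),
                           gaps = 6L, operational = c(TRUE, FALSE),
                           space = hyper_space(), acfg = adapt_config(),
                           ecfg = eval_config(), cspec = cohort_spec(),
                           source_split = c(train = 0.72, valid = 0.08, test = 0.20),
                           target_split = c(fit = 0.56, valid = 0.14, eval = 0.30),
                           min_count = 1000, seed = 1L) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  need_target <- any(regimes %in% c("as-is", "adapt", "target-only"))
  if (need_target && is.null(target)) {
    abort("run_experiment: target cohort required for target regimes")
  }
  registry <- source$registry %||% default_registry()

  src <- filter_cohort(apply_outlier_thresholds(source, registry, quiet = TRUE),
                       cspec, quiet = TRUE)
  s_ids <- split_patients(src, source_split, seed = child_seed(seed, 11L))
  hg_src <- aggregate_hourly(src, registry) %>% add_derived_indices()
  dev_ids <- c(s_ids$train, s_ids$valid)
  params_src <- fit_standardization(hg_src, dev_ids)
  kept_src <- exclude_rare_features(hg_src, min_count, dev_ids)
  hgi_src <- impute_hourly(hg_src, params_src)
  states_src <- derive_vent_states(src)

  if (need_target) {
    tgt <- filter_cohort(apply_outlier_thresholds(target, registry, quiet = TRUE),
                         cspec, quiet = TRUE)
    t_ids <- split_patients(tgt, target_split, seed = child_seed(seed, 13L))
    hg_tgt <- aggregate_hourly(tgt, registry) %>% add_derived_indices()
    hgi_tgt <- impute_hourly(hg_tgt, params_src)
    states_tgt <- derive_vent_states(tgt)
  }

  results <- list()
  for (gap in gaps) {
    cfg <- window_config(gap = gap)
    w_src <- enumerate_windows(hgi_src, states_src, cfg, kept_src)
    w_tgt <- if (need_target) enumerate_windows(hgi_tgt, states_tgt, cfg, kept_src)
    for (op in operational) {
      allowed <- c(toggle_operational_features(registry, op),
                   "rox", "sf_ratio", "pf_ratio")
      feats <- intersect(kept_src, allowed)
      ws <- select_window_features(w_src, feats)
      cell_seed <- child_seed(seed, 100L * gap + as.integer(op))

      src_model <- NULL
      if (any(regimes %in% c("source", "as-is", "adapt"))) {
        src_model <- train_onset_model(
          windows_for_stays(ws, s_ids$train),
          windows_for_stays(ws, s_ids$valid),
          space, seed = cell_seed
        )
      }
      add_row <- function(regime, ev, model) {
        results[[length(results) + 1]] <<- bind_cols(
          tibble(regime = regime, operational = op, gap = gap),
          glance(ev),
          tibble(eval = list(ev), model = list(model))
        )
      }
      if ("source" %in% regimes) {
        wt <- windows_for_stays(ws, s_ids$test)
        ev <- evaluate_predictions(wt$meta$label, predict(src_model, wt), ecfg)
        add_row("source", ev, src_model)
      }
      if (need_target) {
        wt_all <- select_window_features(w_tgt, feats)
        w_eval <- windows_for_stays(wt_all, t_ids$eval)
        if ("as-is" %in% regimes) {
          ev <- evaluate_predictions(w_eval$meta$label,
                                     predict(src_model, w_eval), ecfg)
          add_row("as-is", ev, src_model)
        }
        if ("adapt" %in% regimes) {
          adapted <- adapt_model(src_model,
                                 windows_for_stays(wt_all, t_ids$fit),
                                 windows_for_stays(wt_all, t_ids$valid),
                                 acfg, seed = cell_seed)
          ev <- evaluate_predictions(w_eval$meta$label,
                                     predict(adapted, w_eval), ecfg)
          add_row("adapt", ev, adapted)
        }
        if ("target-only" %in% regimes) {
          # one-step model: same feature list, target-fitted standardization
          params_tgt <- fit_standardization(hg_tgt, c(t_ids$fit, t_ids$valid))
          hgi_own <- impute_hourly(hg_tgt, params_tgt)
          w_own <- select_window_features(
            enumerate_windows(hgi_own, states_tgt, cfg, kept_src), feats)
          tgt_model <- train_onset_model(
            windows_for_stays(w_own, t_ids$fit),
            windows_for_stays(w_own, t_ids$valid),
            space, seed = cell_seed + 1L
          )
          w_eval_own <- windows_for_stays(w_own, t_ids$eval)
          ev <- evaluate_predictions(w_eval_own$meta$label,
                                     predict(tgt_model, w_eval_own), ecfg)
          add_row("target-only", ev, tgt_model)
        }
      }
    }
  }
  out <- bind_rows(results)
  attr(out, "provenance") <- list(seed = seed, gaps = gaps,
                                  operational = operational,
                                  regimes = regimes,
                                  source_split = source_split,
                                  target_split = target_split)
  out
}
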