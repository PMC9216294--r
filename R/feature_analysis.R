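#' Lagged Pearson correlation matrix
#'
#' Builds a Pearson correlation matrix over window samples. In the lagged
#' (time-driven, "autoregressive") variant the variables are every
#' feature's value channel at each of the in-window hours `w0..w(fw-1)`
#' plus the statics and the binary onset outcome (correlation with a 0/1
#' outcome is the point-biserial Pearson r). In the unlagged
#' (pathophysiological) variant each feature's six in-window hours are
#' first averaged, collapsing the time axis.
#'
#' Constant variables have undefined correlations; these are set to 0 and
#' the variables recorded in the `constant_vars` attribute. The returned
#' matrix carries a `var_info` attribute mapping each variable to its
#' feature and in-window hour (statics: hour -1, i.e. earliest; outcome:
#' one past the window, i.e. latest).
#'
#' @param windows A `vw_windows` with at least 3 samples.
#' @param lagged Keep per-hour variables (`TRUE`) or average the window
#'   (`FALSE`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
lagged_cor_matrix <- function(windows, lagged = TRUE) {
  stopifnot(inherits(windows, "vw_windows"))
  if (nrow(windows$features) < 3) abort("lagged_cor_matrix: need >= 3 samples")
  man <- windows$manifest
  vals <- man[man$channel == "value", , drop = FALSE]
  statics <- man[man$channel == "static", , drop = FALSE]
  fw <- windows$config$feature_window
  X <- windows$features
  if (lagged) {
    V <- X[, vals$column, drop = FALSE]
    info <- tibble(var = vals$column, feature_id = vals$feature_id,
                   lag = vals$win_hour)
  } else {
    V <- vapply(unique(vals$feature_id), function(f) {
      rowMeans(X[, vals$column[vals$feature_id == f], drop = FALSE])
    }, numeric(nrow(X)))
    info <- tibble(var = unique(vals$feature_id),
                   feature_id = unique(vals$feature_id), lag = 0L)
  }
  M <- cbind(V, X[, statics$column, drop = FALSE],
             outcome = as.numeric(windows$meta$label))
  info <- bind_rows(
    info,
    tibble(var = statics$column, feature_id = statics$column, lag = -1L),
    tibble(var = "outcome", feature_id = "outcome", lag = as.integer(fw))
  )
  sds <- apply(M, 2, sd)
  constant <- colnames(M)[is.na(sds) | sds == 0]
  cm <- suppressWarnings(cor(M))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  attr(cm, "var_info") <- info
  attr(cm, "constant_vars") <- constant
  cm
}

#' Time-ordered DAG from a lagged correlation matrix
#'
#' Emits a directed edge `u -> v` whenever `u`'s lag precedes `v`'s (the
#' outcome is the latest node, statics the earliest) and `|r(u, v)|` meets
#' the threshold. Acyclic by construction: edges only run forward in lag.
#'
#' @param cmat Output of [lagged_cor_matrix()] (lagged variant).
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return Tibble `from`, `to`, `r`, `weight` (`abs(r)`).
#' @export
build_dag <- function(cmat, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  info <- attr(cmat, "var_info")
  if (is.null(info)) abort("build_dag: matrix lacks var_info (use lagged_cor_matrix)")
  lag <- set_names(info$lag, info$var)
  vars <- rownames(cmat)
  idx <- which(abs(cmat) >= threshold, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  from <- vars[idx[, 1]]; to <- vars[idx[, 2]]
  keep <- lag[from] < lag[to]
  tibble(
    from = from[keep], to = to[keep],
    r = cmat[idx[keep, , drop = FALSE]],
    weight = abs(cmat[idx[keep, , drop = FALSE]])
  ) %>% arrange(dplyr::desc(.data$weight))
}

#' GraphViz DOT export of a DAG edge list
#'
#' @param edges Output of [build_dag()].
#' @param path Output `.dot` file.
#' @export
export_dag_dot <- function(edges, path) {
  lines <- c("digraph ventwatch_dag {",
             sprintf('  "%s" -> "%s" [weight=%.3f];',
                     edges$from, edges$to, edges$weight),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Importance-guided tier clustering
#'
#' Iterates features in descending model importance while the importance is
#' at or above `importance_floor`; each not-yet-assigned iterated feature
#' seeds a new tier, and every unassigned feature whose absolute
#' correlation with the seed reaches `corr_cutoff` joins that tier.
#' Features left over when the importance floor is reached form a final
#' residual tier. Tiers are thus clusters of mutually correlated features
#' ordered by the importance of their seeds; deterministic given the
#' ranking's tie-break.
#'
#' @param importance Tibble `feature_id`, `importance` (descending), e.g.
#'   from [aggregate_importance()].
#' @param cmat Correlation matrix over the same feature ids (unlagged
#'   [lagged_cor_matrix()]).
#' @param importance_floor Stop seeding below this importance (default
#'   0.01).
#' @param corr_cutoff Absolute correlation to join a seed's tier (default
#'   0.5).
#' @return Tibble `feature_id`, `tier` (1 = highest), `is_seed`.
#' @export
assign_tiers <- function(importance, cmat, importance_floor = 0.01,
                         corr_cutoff = 0.5) {
  if (nrow(importance) == 0) abort("assign_tiers: empty ranking")
  feats <- importance$feature_id[importance$feature_id %in% rownames(cmat)]
  imp <- set_names(importance$importance, importance$feature_id)[feats]
  tier <- set_names(rep(NA_integer_, length(feats)), feats)
  seed <- set_names(rep(FALSE, length(feats)), feats)
  k <- 0L
  for (f in feats) {
    if (imp[f] < importance_floor) break
    if (!is.na(tier[f])) next
    k <- k + 1L
    tier[f] <- k
    seed[f] <- TRUE
    mates <- feats[is.na(tier) & abs(cmat[f, feats]) >= corr_cutoff]
    tier[mates] <- k
  }
  if (any(is.na(tier))) tier[is.na(tier)] <- k + 1L
  tibble(feature_id = feats, tier = unname(tier), is_seed = unname(seed)) %>%
    arrange(.data$tier, dplyr::desc(imp[.data$feature_id]))
}

#' Association between importance and outcome-correlation rankings
#'
#' Median-splits two rankings of the same `n` features into a top half
#' (size `ceiling(n/2)`) and bottom half, cross-tabulates joint membership
#' and reports the odds ratio `(a*d)/(b*c)`. When any cell is 0 the
#' Haldane-Anscombe correction adds 0.5 to every cell.
#'
#' @param importance_ranking,correlation_ranking Character vectors of the
#'   same feature set, most important / most outcome-correlated first;
#'   `n >= 4`.
#' @return One-row tibble `odds_ratio`, `a`, `b`, `c`, `d`, `corrected`.
#' @export
importance_correlation_odds_ratio <- function(importance_ranking,
                                              correlation_ranking) {
  n <- length(importance_ranking)
  if (n < 4) abort("importance_correlation_odds_ratio: need >= 4 features")
  if (!setequal(importance_ranking, correlation_ranking) ||
      length(correlation_ranking) != n) {
    abort("rankings must cover the identical feature set")
  }
  k <- ceiling(n / 2)
  top_imp <- importance_ranking[seq_len(k)]
  top_cor <- correlation_ranking[seq_len(k)]
  a <- sum(top_imp %in% top_cor)
  b <- k - a
  c_ <- sum(!(top_cor %in% top_imp))
  d <- (n - k) - c_
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  tibble(odds_ratio = (a * d) / (b * c_), a = a, b = b, c = c_, d = d,
         corrected = corrected)
}

#' Rank features by absolute correlation with the outcome
#'
#' Convenience for the odds-ratio analysis: point-biserial Pearson r of
#' each base feature's window-mean value with the onset label, ranked by
#' absolute value.
#'
#' @param windows A `vw_windows`.
#' @return Tibble `feature_id`, `abs_r` (descending).
#' @export
outcome_correlation_ranking <- function(windows) {
  cm <- lagged_cor_matrix(windows, lagged = FALSE)
  info <- attr(cm, "var_info")
  feats <- setdiff(rownames(cm), "outcome")
  tibble(feature_id = feats, abs_r = abs(cm[feats, "outcome"])) %>%
    arrange(dplyr::desc(.data$abs_r))
}
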