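#' Hourly triplet aggregation
#'
#' Converts a cohort's irregularly timed events to a regular hourly grid in
#' which every (stay, hour, dynamic feature) carries a triplet: the hourly
#' mean `value` (NA when nothing was measured that hour), a presence `mask`
#' (1 iff at least one raw measurement fell in the half-open hour bin
#' `[h, h+1)`), and `tsl`, the hours since the most recent measured hour
#' (0 on a measured hour; for hours before any measurement it is `h + 1`,
#' which stays monotone and distinguishes "never measured" from "measured
#' at admission").
#'
#' @param cohort An `icu_cohort`, outlier-filtered.
#' @param registry Feature registry; all registered dynamic and operational
#'   features appear in the grid, measured or not.
#' @return An `hourly_grid`: a list with `grid` (long tibble `stay_id`,
#'   `hour`, `feature_id`, `value`, `mask`, `tsl`), `stays` (statics),
#'   `features` (dynamic feature ids), and a `standardized` flag.
#' @export
aggregate_hourly <- function(cohort, registry = default_registry()) {
  stopifnot(inherits(cohort, "icu_cohort"))
  feats <- dynamic_features(registry, operational = TRUE)
  st <- cohort$stays
  n_hours <- as.integer(floor(st$los_hours))
  if (any(n_hours < 1)) abort("aggregate_hourly: stay shorter than one hour")

  means <- cohort$events %>%
    filter(.data$feature_id %in% feats) %>%
    mutate(hour = as.integer(floor(.data$time_hours))) %>%
    group_by(.data$stay_id, .data$feature_id, .data$hour) %>%
    summarise(value = mean(.data$value), .groups = "drop")

  # full rectangular grid, sorted stay > feature > hour so that per-series
  # scans work on contiguous runs
  grid <- tibble(
    stay_id = rep(rep(st$stay_id, each = length(feats)), rep(n_hours, each = length(feats))),
    feature_id = rep(rep(feats, length(st$stay_id)), rep(n_hours, each = length(feats))),
    hour = unlist(lapply(n_hours, function(h) rep(seq_len(h) - 1L, length(feats))),
                  use.names = FALSE)
  ) %>%
    arrange(.data$stay_id, .data$feature_id, .data$hour) %>%
    left_join(means, by = c("stay_id", "feature_id", "hour")) %>%
    mutate(mask = as.integer(!is.na(.data$value)))

  grid$tsl <- compute_tsl(grid$hour, grid$mask)
  new_hourly_grid(grid, st, feats)
}

new_hourly_grid <- function(grid, stays, features, standardized = FALSE,
                            params = NULL) {
  structure(list(grid = grid, stays = stays, features = features,
                 standardized = standardized, params = params),
            class = "hourly_grid")
}

#' @export
print.hourly_grid <- function(x, ...) {
  cat(sprintf("<hourly_grid> %d stays x %d features, %d stay-hours%s\n",
              nrow(x$stays), length(x$features),
              nrow(x$grid) / max(length(x$features), 1L),
              if (x$standardized) " (standardized, imputed)" else ""))
  invisible(x)
}

# tsl over contiguous (stay, feature) runs: runs restart whenever hour == 0,
# so a single global scan suffices. tsl = hour + 1 - (hour+1 of the last
# measured hour, 0 if none yet).
compute_tsl <- function(hour, mask) {
  v <- ifelse(mask == 1L, hour + 1, NA_real_)
  starts <- hour == 0L
  v[starts & mask == 0L] <- 0
  as.integer(hour + 1 - locf(v))
}

#' Derived respiratory indices
#'
#' Adds three derived dynamic features computed from the raw (pre-
#' standardization) hourly means: the ROX index `(SpO2/FiO2) / resp_rate`,
#' the `SpO2/FiO2` ratio (`sf_ratio`) and the `PaO2/FiO2` ratio
#' (`pf_ratio`). A derived hour counts as measured only when every
#' constituent is measured that hour and strictly positive; otherwise the
#' hour is unmeasured (guarding the divisions). Ratios are taken before
#' standardization because ratios of standardized values have no physical
#' meaning; the derived features are then standardized like any other.
#'
#' @param hg An `hourly_grid` (not yet standardized).
#' @return The `hourly_grid` with features `rox`, `sf_ratio`, `pf_ratio`
#'   appended.
#' @export
add_derived_indices <- function(hg) {
  stopifnot(inherits(hg, "hourly_grid"))
  if (hg$standardized) abort("add_derived_indices: grid already standardized")
  need <- c("spo2", "fio2", "resp_rate", "pao2")
  wide <- hg$grid %>%
    filter(.data$feature_id %in% need) %>%
    select("stay_id", "hour", "feature_id", "value") %>%
    tidyr::pivot_wider(names_from = "feature_id", values_from = "value")
  for (f in setdiff(need, names(wide))) wide[[f]] <- NA_real_
  pos <- function(x) ifelse(!is.na(x) & x > 0, x, NA_real_)
  wide <- wide %>%
    mutate(
      rox = pos(.data$spo2) / pos(.data$fio2) / pos(.data$resp_rate),
      sf_ratio = pos(.data$spo2) / pos(.data$fio2),
      pf_ratio = pos(.data$pao2) / pos(.data$fio2)
    )
  derived <- wide %>%
    select("stay_id", "hour", "rox", "sf_ratio", "pf_ratio") %>%
    tidyr::pivot_longer(c("rox", "sf_ratio", "pf_ratio"),
                        names_to = "feature_id", values_to = "value") %>%
    mutate(mask = as.integer(!is.na(.data$value))) %>%
    arrange(.data$stay_id, .data$feature_id, .data$hour)
  derived$tsl <- compute_tsl(derived$hour, derived$mask)
  grid <- bind_rows(hg$grid, derived) %>%
    arrange(.data$stay_id, .data$feature_id, .data$hour)
  new_hourly_grid(grid, hg$stays, c(hg$features, "rox", "sf_ratio", "pf_ratio"))
}

#' Standardization parameters
#'
#' Per-feature mean and standard deviation over measured (`mask == 1`)
#' stay-hours of the training split only. Features with fewer than two
#' measured hours or zero variance are flagged `constant`; their
#' standardized value is defined as 0.
#'
#' @param hg An `hourly_grid`.
#' @param stay_ids Training stay ids (leakage guard: never fit on
#'   evaluation stays). Default: all stays in `hg`.
#' @return Tibble `feature_id`, `mean`, `sd`, `n_measured`, `constant`.
#' @export
fit_standardization <- function(hg, stay_ids = NULL) {
  stopifnot(inherits(hg, "hourly_grid"))
  g <- hg$grid
  if (!is.null(stay_ids)) g <- g[g$stay_id %in% stay_ids, , drop = FALSE]
  params <- g %>%
    filter(.data$mask == 1L) %>%
    group_by(.data$feature_id) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_measured = dplyr::n(), .groups = "drop")
  params <- tibble(feature_id = hg$features) %>%
    left_join(params, by = "feature_id") %>%
    mutate(
      n_measured = ifelse(is.na(.data$n_measured), 0L, .data$n_measured),
      constant = .data$n_measured < 2 | is.na(.data$sd) | .data$sd <= 0,
      mean = ifelse(is.na(.data$mean), 0, .data$mean),
      sd = ifelse(.data$constant, 1, .data$sd)
    )
  params
}

#' Standardize and impute the hourly grid
#'
#' Measured hours carry the standardized measurement `(x - mean) / sd`;
#' unmeasured hours carry the last standardized observation carried
#' forward; hours before any observation carry 0, the standardized
#' training mean (standardizing first makes that fallback scale-free).
#' The mask and tsl channels are untouched. Idempotent: re-imputing an
#' already-imputed grid returns it unchanged.
#'
#' @param hg An `hourly_grid`.
#' @param params Output of [fit_standardization()] on the training split.
#' @return The imputed `hourly_grid` (flagged `standardized`).
#' @export
impute_hourly <- function(hg, params) {
  stopifnot(inherits(hg, "hourly_grid"))
  if (hg$standardized) return(hg)
  missing <- setdiff(hg$features, params$feature_id)
  if (length(missing) > 0) {
    abort(sprintf("impute_hourly: no standardization params for: %s",
                  paste(missing, collapse = ", ")))
  }
  g <- hg$grid %>%
    left_join(params %>% select("feature_id", "mean", "sd", "constant"),
              by = "feature_id")
  raw <- ifelse(g$mask == 1L, g$value, NA_real_)
  # carry the index of the last measurement forward; a 0 sentinel at every
  # series start (hour 0) keeps the carry from crossing series boundaries
  pos <- ifelse(is.na(raw), NA_real_, as.numeric(seq_along(raw)))
  pos[g$hour == 0L & is.na(raw)] <- 0
  posf <- locf(pos)
  filled <- raw[pmax(posf, 1)]
  filled[posf == 0] <- NA_real_
  z <- (filled - g$mean) / g$sd
  z[g$constant & !is.na(z)] <- 0
  z[is.na(z)] <- 0
  out <- hg$grid
  out$value <- z
  new_hourly_grid(out, hg$stays, hg$features, standardized = TRUE,
                  params = params)
}

#' Exclude rarely measured features
#'
#' Dynamic features with fewer than `min_count` measured stay-hours on the
#' training split are dropped from the model feature list (their mask and
#' tsl channels go with them). Rarely measured features are statistically
#' unreliable split candidates.
#'
#' @param hg An `hourly_grid` (pre- or post-imputation; counts use masks).
#' @param min_count Minimum measured stay-hours to keep a feature
#'   (default 1000).
#' @param stay_ids Training stay ids; default all.
#' @return Character vector of retained feature ids (registry order).
#' @export
exclude_rare_features <- function(hg, min_count = 1000, stay_ids = NULL) {
  stopifnot(inherits(hg, "hourly_grid"))
  if (min_count <= 0) return(hg$features)
  g <- hg$grid
  if (!is.null(stay_ids)) g <- g[g$stay_id %in% stay_ids, , drop = FALSE]
  counts <- g %>%
    group_by(.data$feature_id) %>%
    summarise(n_measured = sum(.data$mask), .groups = "drop")
  counts <- tibble(feature_id = hg$features) %>%
    left_join(counts, by = "feature_id") %>%
    mutate(n_measured = ifelse(is.na(.data$n_measured), 0L, .data$n_measured))
  dropped <- counts$feature_id[counts$n_measured < min_count]
  if (length(dropped) > 0) {
    vw_log("features", "excluded %d rarely measured feature(s): %s",
           length(dropped), paste(dropped, collapse = ", "))
  }
  setdiff(hg$features, dropped)
}

#' Sliding-window configuration
#'
#' @param feature_window Hours of history forming a sample's inputs
#'   (default 6).
#' @param gap Hours between the feature window and the target window;
#'   the study horizons are 6, 12, 18 and 24 but any positive value is
#'   accepted.
#' @param target_window Hours after the gap within which an IMV onset makes
#'   the sample positive (default 4).
#' @param stride Hours between consecutive reference times (default 1, i.e.
#'   the window slides once every hour).
#' @return A `window_config` list.
#' @export
window_config <- function(feature_window = 6, gap = 6, target_window = 4,
                          stride = 1) {
  stopifnot(feature_window >= 1, gap >= 1, target_window >= 1, stride >= 1)
  structure(list(feature_window = as.integer(feature_window),
                 gap = as.integer(gap),
                 target_window = as.integer(target_window),
                 stride = as.integer(stride)),
            class = "window_config")
}

#' Enumerate labeled sliding-window samples
#'
#' One candidate per `stride` hours at each reference time `t` from
#' `feature_window` to `floor(los) - gap - target_window` (so the full
#' target window fits inside the stay). A candidate is emitted iff every
#' hour of `[t - feature_window, t + gap)` is IMV-inactive — stays already
#' on the ventilator, through feature or gap windows, never contribute —
#' and labeled 1 iff an ONSET hour lies in `[t + gap, t + gap +
#' target_window)`. One true onset can therefore label up to
#' `target_window` positives.
#'
#' @param hg A standardized, imputed `hourly_grid`.
#' @param states Output of [derive_vent_states()] for the same cohort.
#' @param cfg A [window_config()].
#' @param features Model feature subset (default: all grid features), e.g.
#'   after [exclude_rare_features()] / [toggle_operational_features()].
#' @return A `vw_windows` object: feature matrix (rows = samples, columns =
#'   `feature__channel__w<k>` for in-window hours `w0..w5` plus statics),
#'   sample metadata (`stay_id`, `t`, `label`), the column manifest, the
#'   window config and standardization parameters.
#' @export
enumerate_windows <- function(hg, states, cfg = window_config(),
                              features = NULL) {
  stopifnot(inherits(hg, "hourly_grid"))
  if (!hg$standardized) abort("enumerate_windows: impute_hourly() first")
  features <- features %||% hg$features
  stopifnot(all(features %in% hg$features))
  fw <- cfg$feature_window; gap <- cfg$gap; tw <- cfg$target_window

  st <- hg$stays
  manifest <- build_manifest(features, fw)
  # the grid is sorted by feature_id, so per-stay matrices come out in
  # sorted-feature order; permute back to the manifest's feature order
  perm <- match(features, sort(features))

  g <- hg$grid[hg$grid$feature_id %in% features, , drop = FALSE]
  g_split <- split(g, g$stay_id)
  states_split <- split(states, states$stay_id)

  per_stay <- function(sid) {
    gi <- g_split[[sid]]
    si <- states_split[[sid]]
    H <- nrow(si)
    t_max <- H - gap - tw
    if (t_max < fw) return(NULL)
    ts <- seq.int(fw, t_max, by = cfg$stride)
    active <- si$active
    cs <- c(0L, cumsum(active))
    ok <- (cs[ts + gap + 1] - cs[ts - fw + 1]) == 0L
    ts <- ts[ok]
    if (length(ts) == 0) return(NULL)
    onset <- which(si$state == "ONSET") - 1L        # 0-based onset hours
    oflag <- logical(H + 1L)
    oflag[onset + 1L] <- TRUE
    ocs <- c(0L, cumsum(oflag))
    label <- (ocs[pmin(ts + gap + tw, H) + 1L] - ocs[ts + gap + 1L]) > 0L
    # gi is sorted feature-major then hour; one H x F matrix per channel
    F <- length(features)
    mval <- matrix(gi$value, nrow = H)[, perm, drop = FALSE]
    mmask <- matrix(as.numeric(gi$mask), nrow = H)[, perm, drop = FALSE]
    mtsl <- matrix(as.numeric(gi$tsl), nrow = H)[, perm, drop = FALSE]
    M <- cbind(mval, mmask, mtsl)[, rep(seq_len(F), each = 3) +
                                    c(0L, F, 2L * F), drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(fw) - 1L, function(w) {
      M[ts - fw + w + 1L, , drop = FALSE]
    }))
    list(X = X, label = as.integer(label), t = ts, stay_id = sid)
  }

  parts <- purrr::compact(purrr::map(st$stay_id, per_stay))
  if (length(parts) == 0) {
    X <- matrix(numeric(0), nrow = 0, ncol = nrow(manifest))
    meta <- tibble(stay_id = character(), t = integer(), label = integer())
  } else {
    X <- do.call(rbind, purrr::map(parts, "X"))
    meta <- tibble(
      stay_id = unlist(purrr::map(parts, function(p) rep(p$stay_id, length(p$t)))),
      t = unlist(purrr::map(parts, "t")),
      label = unlist(purrr::map(parts, "label"))
    )
    statics <- st[match(meta$stay_id, st$stay_id), , drop = FALSE]
    X <- cbind(X, age = statics$age,
               sex_male = as.numeric(statics$sex == "male"),
               weight = statics$weight, height = statics$height)
  }
  colnames(X) <- c(manifest$column[manifest$channel != "static"],
                   "age", "sex_male", "weight", "height")
  new_vw_windows(X, meta, manifest, cfg, hg$params, features)
}

build_manifest <- function(features, fw) {
  chans <- c("value", "mask", "tsl")
  dyn <- tidyr::expand_grid(win_hour = seq_len(fw) - 1L,
                            feature_id = features, channel = chans) %>%
    mutate(column = sprintf("%s__%s__w%d", .data$feature_id, .data$channel,
                            .data$win_hour))
  statics <- tibble(win_hour = NA_integer_,
                    feature_id = c("age", "sex_male", "weight", "height"),
                    channel = "static",
                    column = c("age", "sex_male", "weight", "height"))
  bind_rows(dyn, statics) %>%
    select("column", "feature_id", "channel", "win_hour")
}

new_vw_windows <- function(X, meta, manifest, cfg, params, features) {
  structure(list(features = X, meta = meta, manifest = manifest,
                 config = cfg, standardization = params,
                 feature_ids = features),
            class = "vw_windows")
}

#' @export
print.vw_windows <- function(x, ...) {
  cat(sprintf(
    "<vw_windows> %d samples (%d positive, %.1f%%), %d columns, gap %d h\n",
    nrow(x$features), sum(x$meta$label),
    if (nrow(x$meta) > 0) 100 * mean(x$meta$label) else NA_real_,
    ncol(x$features), x$config$gap))
  invisible(x)
}

#' @export
tidy.vw_windows <- function(x, ...) x$meta

# Subset sample rows of a vw_windows by stay ids.
windows_for_stays <- function(w, stay_ids) {
  keep <- w$meta$stay_id %in% stay_ids
  new_vw_windows(w$features[keep, , drop = FALSE], w$meta[keep, , drop = FALSE],
                 w$manifest, w$config, w$standardization, w$feature_ids)
}

#' Patient-level random split
#'
#' Partitions stay ids into disjoint named sets by the given fractions, at
#' the patient level so no stay's windows cross between sets.
#' Reproducible given `seed`.
#'
#' @param stays An `icu_cohort`, a stays tibble, or a vector of stay ids.
#' @param fractions Named numeric vector summing to 1,
#'   e.g. `c(train = 0.8, test = 0.2)`.
#' @param seed Integer seed.
#' @return Named list of disjoint character vectors of stay ids whose union
#'   is the input.
#' @export
split_patients <- function(stays, fractions = c(train = 0.8, test = 0.2),
                           seed = 1L) {
  ids <- if (inherits(stays, "icu_cohort")) stays$stays$stay_id
         else if (is.data.frame(stays)) stays$stay_id
         else as.character(stays)
  if (length(ids) == 0) abort("split_patients: empty cohort")
  if (abs(sum(fractions) - 1) > 1e-8) abort("split_patients: fractions must sum to 1")
  n <- length(ids)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  set.seed(seed)
  shuffled <- sample(ids)
  idx_end <- cumsum(sizes)
  idx_start <- c(1, head(idx_end, -1) + 1)
  out <- purrr::map2(idx_start, idx_end, function(a, b) {
    if (b < a) character(0) else shuffled[a:b]
  })
  names(out) <- names(fractions)
  out
}

#' Persist window samples
#'
#' Writes the flattened feature matrix as CSV together with a JSON sidecar
#' recording the window configuration, standardization parameters and the
#' column manifest, so a target cohort can later be featurized bit-exactly
#' against a source model's parameters.
#'
#' @param windows A `vw_windows`.
#' @param path Output directory.
#' @export
write_windows <- function(windows, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mat <- as_tibble(windows$features)
  readr::write_csv(bind_cols(windows$meta, mat),
                   file.path(path, "windows.csv"), progress = FALSE)
  sidecar <- list(
    version = 1L,
    config = unclass(windows$config),
    feature_ids = windows$feature_ids,
    manifest = windows$manifest,
    standardization = windows$standardization
  )
  jsonlite::write_json(sidecar, file.path(path, "windows.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  tab <- readr::read_csv(file.path(path, "windows.csv"),
                         col_types = readr::cols(stay_id = readr::col_character(),
                                                 .default = readr::col_double()),
                         progress = FALSE)
  side <- jsonlite::read_json(file.path(path, "windows.json"),
                              simplifyVector = TRUE)
  meta <- tab %>% select("stay_id", "t", "label") %>%
    mutate(t = as.integer(.data$t), label = as.integer(.data$label))
  X <- as.matrix(tab %>% select(-c("stay_id", "t", "label")))
  cfg <- do.call(window_config, side$config)
  new_vw_windows(X, meta, as_tibble(side$manifest), cfg,
                 as_tibble(side$standardization), side$feature_ids)
}
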