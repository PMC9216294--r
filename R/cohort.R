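#' ICU cohort container
#'
#' An `icu_cohort` bundles the three stay-level tables the pipeline works
#' from: per-stay statics, timestamped measurements (chart events), and
#' invasive-mechanical-ventilation (IMV) on/off intervals. All times are
#' hours since ICU admission; hour bins downstream are half-open `[h, h+1)`
#' and 0-based, so an event at exactly time `h` belongs to bin `h`.
#'
#' @param stays Tibble with columns `stay_id`, `los_hours`, `age`, `sex`
#'   (`"male"`/`"female"`), `weight`, `height`.
#' @param events Tibble with columns `stay_id`, `feature_id`, `time_hours`,
#'   `value`.
#' @param vent Tibble with columns `stay_id`, `start_hours`, `end_hours`;
#'   intervals are half-open `[start, end)` and are normalized (sorted,
#'   overlapping or touching intervals merged) on construction.
#' @param truth Optional generator ground-truth table (see
#'   [simulate_cohort()]); carried along and subset with the cohort.
#' @return An object of class `icu_cohort`.
#' @export
icu_cohort <- function(stays, events, vent, truth = NULL) {
  assert_cols(stays, c("stay_id", "los_hours", "age", "sex", "weight", "height"),
              "stays")
  assert_cols(events, c("stay_id", "feature_id", "time_hours", "value"), "events")
  assert_cols(vent, c("stay_id", "start_hours", "end_hours"), "vent")
  stays <- as_tibble(stays)
  events <- as_tibble(events) %>%
    mutate(stay_id = as.character(.data$stay_id)) %>%
    arrange(.data$stay_id, .data$time_hours, .data$feature_id)
  stays$stay_id <- as.character(stays$stay_id)
  vent <- normalize_intervals(as_tibble(vent) %>%
                                mutate(stay_id = as.character(.data$stay_id)))
  if (any(!is.finite(events$value))) abort("events: non-finite values")
  if (any(events$time_hours < 0)) abort("events: negative time_hours")
  los <- set_names(stays$los_hours, stays$stay_id)
  bad_ev <- events$time_hours > los[events$stay_id]
  if (any(bad_ev, na.rm = TRUE)) abort("events: time beyond length of stay")
  if (nrow(vent) > 0) {
    bad_v <- vent$start_hours < 0 | vent$end_hours > los[vent$stay_id]
    if (any(bad_v, na.rm = TRUE)) abort("vent: interval outside [0, length of stay]")
  }
  structure(list(stays = stays, events = events, vent = vent, truth = truth),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("<icu_cohort> %d stays, %d events, %d IMV intervals\n",
              nrow(x$stays), nrow(x$events), nrow(x$vent)))
  invisible(x)
}

# Merge overlapping or touching IMV intervals within each stay.
normalize_intervals <- function(vent) {
  if (nrow(vent) == 0) return(vent)
  if (any(vent$start_hours >= vent$end_hours)) {
    abort("vent: start_hours must be < end_hours")
  }
  vent %>%
    arrange(.data$stay_id, .data$start_hours) %>%
    group_by(.data$stay_id) %>%
    mutate(grp = cumsum(.data$start_hours > lag(cummax(.data$end_hours),
                                                default = -Inf))) %>%
    group_by(.data$stay_id, .data$grp) %>%
    summarise(start_hours = min(.data$start_hours),
              end_hours = max(.data$end_hours), .groups = "drop") %>%
    select(-"grp") %>%
    arrange(.data$stay_id, .data$start_hours)
}

#' Read and write stay-level cohorts
#'
#' `load_stays()` reads a cohort from disk; `write_stays()` writes one.
#' Two layouts are supported:
#' \describe{
#'   \item{`csv-bundle`}{a directory holding `stays.csv`
#'     (stay_id, los_hours, age, sex, weight, height), `events.csv`
#'     (stay_id, feature_id, time_hours, value) and `vent.csv`
#'     (stay_id, start_hours, end_hours). Lossless; the round trip
#'     preserves every event.}
#'   \item{`hourly-csv`}{a directory holding `stays.csv`, `vent.csv` and a
#'     wide `hourly.csv` with one row per (stay_id, hour) and one column
#'     per dynamic feature carrying the hourly mean. This mirrors the
#'     hourly wide-table layout common in EHR extraction pipelines and is
#'     hourly-aggregated by design: reloading yields one event per
#'     measured hour, stamped at the start of the hour.}
#' }
#'
#' @param path Directory of the bundle.
#' @param format `"csv-bundle"` or `"hourly-csv"`.
#' @param registry Feature registry; unknown `feature_id`s in the events
#'   table are an error listing the offenders.
#' @param cohort An `icu_cohort`.
#' @return `load_stays()` returns an `icu_cohort`; `write_stays()` returns
#'   `path` invisibly.
#' @export
load_stays <- function(path, format = c("csv-bundle", "hourly-csv"),
                       registry = default_registry()) {
  format <- match.arg(format)
  if (!dir.exists(path)) abort(sprintf("cohort path not found: %s", path))
  read1 <- function(f, types) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) abort(sprintf("missing cohort file: %s", fp),
                                class = "ventwatch_schema_error")
    readr::read_csv(fp, col_types = types, progress = FALSE)
  }
  stays <- read1("stays.csv", readr::cols(
    stay_id = readr::col_character(), los_hours = readr::col_double(),
    age = readr::col_double(), sex = readr::col_character(),
    weight = readr::col_double(), height = readr::col_double()))
  vent <- read1("vent.csv", readr::cols(
    stay_id = readr::col_character(), start_hours = readr::col_double(),
    end_hours = readr::col_double()))
  if (format == "csv-bundle") {
    events <- read1("events.csv", readr::cols(
      stay_id = readr::col_character(), feature_id = readr::col_character(),
      time_hours = readr::col_double(), value = readr::col_double()))
  } else {
    wide <- readr::read_csv(file.path(path, "hourly.csv"),
                            col_types = readr::cols(
                              stay_id = readr::col_character(),
                              .default = readr::col_double()),
                            progress = FALSE)
    events <- wide %>%
      tidyr::pivot_longer(-c("stay_id", "hour"), names_to = "feature_id",
                          values_to = "value") %>%
      filter(!is.na(.data$value)) %>%
      mutate(time_hours = as.numeric(.data$hour)) %>%
      select("stay_id", "feature_id", "time_hours", "value")
  }
  unknown <- setdiff(unique(events$feature_id), registry$feature_id)
  if (length(unknown) > 0) {
    abort(sprintf("events reference feature_id(s) absent from the registry: %s",
                  paste(unknown, collapse = ", ")),
          class = "ventwatch_registry_error")
  }
  icu_cohort(stays, events, vent)
}

#' @rdname load_stays
#' @export
write_stays <- function(cohort, path, format = c("csv-bundle", "hourly-csv"),
                        registry = default_registry()) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$stays, file.path(path, "stays.csv"), progress = FALSE)
  readr::write_csv(cohort$vent, file.path(path, "vent.csv"), progress = FALSE)
  if (format == "csv-bundle") {
    readr::write_csv(cohort$events, file.path(path, "events.csv"),
                     progress = FALSE)
  } else {
    wide <- cohort$events %>%
      mutate(hour = floor(.data$time_hours)) %>%
      group_by(.data$stay_id, .data$hour, .data$feature_id) %>%
      summarise(value = mean(.data$value), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "feature_id", values_from = "value")
    readr::write_csv(wide, file.path(path, "hourly.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Remove physiologically implausible measurements
#'
#' Events whose value lies outside the registry's per-feature plausibility
#' bounds (`outlier_low`, `outlier_high`, both inclusive) are removed, not
#' clipped: clipping would fabricate plausible-looking measurements.
#' Features without registered bounds pass through untouched. Removal
#' counts are reported per feature.
#'
#' @param events An events tibble, or an `icu_cohort` (whose events are
#'   filtered in place).
#' @inheritParams load_stays
#' @param quiet Suppress the per-feature removal log.
#' @return Same type as `events`.
#' @export
apply_outlier_thresholds <- function(events, registry = default_registry(),
                                     quiet = FALSE) {
  if (inherits(events, "icu_cohort")) {
    events$events <- apply_outlier_thresholds(events$events, registry, quiet)
    return(events)
  }
  bounds <- registry %>% select("feature_id", "outlier_low", "outlier_high")
  ev <- events %>% left_join(bounds, by = "feature_id")
  keep <- is.na(ev$outlier_low) | is.na(ev$outlier_high) |
    (ev$value >= ev$outlier_low & ev$value <= ev$outlier_high)
  if (!quiet) {
    removed <- ev[!keep, , drop = FALSE] %>% count(.data$feature_id)
    for (i in seq_len(nrow(removed))) {
      vw_log("outliers", "%s: removed %d out-of-range value(s)",
             removed$feature_id[i], removed$n[i])
    }
  }
  events[keep, , drop = FALSE]
}

#' Cohort inclusion criteria
#'
#' Defaults mirror the standard hypoxemic-ICU selection: age strictly
#' greater than 15 years, length of stay between 12 hours and 10 days
#' (inclusive), and at least one hypoxemic measurement at any time during
#' the stay — PaO2 below 60 mmHg or SpO2 below 90% (both strict).
#'
#' @param age_min Years (exclusive lower bound).
#' @param los_min,los_max Hours (inclusive bounds).
#' @param pao2_hypox_mmHg,spo2_hypox_pct Hypoxemia thresholds (a value
#'   strictly below either qualifies).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(age_min = 15, los_min = 12, los_max = 240,
                        pao2_hypox_mmHg = 60, spo2_hypox_pct = 90) {
  stopifnot(los_min < los_max, pao2_hypox_mmHg > 0, spo2_hypox_pct > 0)
  structure(list(age_min = age_min, los_min = los_min, los_max = los_max,
                 pao2_hypox_mmHg = pao2_hypox_mmHg,
                 spo2_hypox_pct = spo2_hypox_pct),
            class = "cohort_spec")
}

#' Apply cohort inclusion filters
#'
#' Retains stays satisfying all of: `age > age_min`,
#' `los_min <= los_hours <= los_max`, and at least one qualifying
#' hypoxemic measurement (PaO2 or SpO2 strictly below threshold) at any
#' time in the stay. Stays with missing age are excluded and logged.
#' Idempotent.
#'
#' @param cohort An `icu_cohort` (outlier-filtered).
#' @param spec A [cohort_spec()].
#' @param quiet Suppress exclusion logging.
#' @return The filtered `icu_cohort`.
#' @export
filter_cohort <- function(cohort, spec = cohort_spec(), quiet = FALSE) {
  stopifnot(inherits(cohort, "icu_cohort"))
  st <- cohort$stays
  no_age <- is.na(st$age)
  if (any(no_age) && !quiet) {
    vw_log("cohort", "excluded %d stay(s) with missing age", sum(no_age))
  }
  hypox_ids <- cohort$events %>%
    filter((.data$feature_id == "pao2" & .data$value < spec$pao2_hypox_mmHg) |
             (.data$feature_id == "spo2" & .data$value < spec$spo2_hypox_pct)) %>%
    pull("stay_id") %>%
    unique()
  keep <- !no_age &
    st$age > spec$age_min &
    st$los_hours >= spec$los_min & st$los_hours <= spec$los_max &
    st$stay_id %in% hypox_ids
  subset_cohort(cohort, st$stay_id[keep])
}

# Restrict a cohort (and its truth table, if any) to the given stay ids.
subset_cohort <- function(cohort, stay_ids) {
  truth <- cohort$truth
  if (!is.null(truth)) truth <- truth[truth$stay_id %in% stay_ids, , drop = FALSE]
  icu_cohort(
    cohort$stays[cohort$stays$stay_id %in% stay_ids, , drop = FALSE],
    cohort$events[cohort$events$stay_id %in% stay_ids, , drop = FALSE],
    cohort$vent[cohort$vent$stay_id %in% stay_ids, , drop = FALSE],
    truth = truth
  )
}

#' Per-hour ventilation state sequence
#'
#' For every stay, hours `0 .. floor(los) - 1` are classified into the four
#' ventilation states: `ONSET` (IMV active this hour but not the previous
#' one, or the first hour of the stay's first episode), `STAY_ON` (active
#' this hour and the previous), `WEAN` (inactive this hour, active the
#' previous) and `STAY_OFF` (inactive both). Hour `h` counts as IMV-active
#' iff `[h, h+1)` overlaps any ventilation interval.
#'
#' @param cohort An `icu_cohort`.
#' @return Tibble with columns `stay_id`, `hour`, `active` (logical),
#'   `state` (factor with the four levels).
#' @export
derive_vent_states <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  st <- cohort$stays
  n_hours <- floor(st$los_hours)
  grid <- tibble(
    stay_id = rep(st$stay_id, n_hours),
    hour = unlist(lapply(n_hours, function(h) seq_len(h) - 1L), use.names = FALSE)
  )
  active_tbl <- active_hours(cohort$vent)
  grid <- grid %>%
    left_join(active_tbl, by = c("stay_id", "hour")) %>%
    mutate(active = !is.na(.data$active_flag)) %>%
    select(-"active_flag") %>%
    group_by(.data$stay_id) %>%
    mutate(prev = lag(.data$active, default = FALSE),
           state = case_when(
             .data$active & !.data$prev ~ "ONSET",
             .data$active & .data$prev ~ "STAY_ON",
             !.data$active & .data$prev ~ "WEAN",
             TRUE ~ "STAY_OFF"
           )) %>%
    ungroup() %>%
    select(-"prev") %>%
    mutate(state = factor(.data$state,
                          levels = c("ONSET", "STAY_ON", "WEAN", "STAY_OFF")))
  grid
}

# Hours h whose [h, h+1) bin overlaps a ventilation interval.
active_hours <- function(vent) {
  if (nrow(vent) == 0) {
    return(tibble(stay_id = character(), hour = integer(), active_flag = logical()))
  }
  lo <- floor(vent$start_hours)
  hi <- ceiling(vent$end_hours) - 1
  n <- pmax(hi - lo + 1, 0)
  tibble(
    stay_id = rep(vent$stay_id, n),
    hour = as.integer(unlist(purrr::map2(lo, hi, seq), use.names = FALSE)),
    active_flag = TRUE
  ) %>% distinct(.data$stay_id, .data$hour, .keep_all = TRUE)
}
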