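#' Feature registry
#'
#' Every dynamic or static variable that can appear in a cohort is declared
#' in a registry: its identifier, display name, measurement unit,
#' physiologic plausibility bounds used for outlier removal, and its kind.
#' `kind` is one of `"dynamic"` (measured vitals/labs), `"operational"`
#' (clinician-set parameters, mainly ventilator settings, which can be
#' toggled out of a model so it remains usable before any ventilator data
#' exist), or `"static"` (per-stay demographics).
#'
#' @param registry A registry tibble, as returned by [default_registry()] or
#'   [read_registry()].
#' @return `default_registry()` returns a tibble with columns `feature_id`,
#'   `name`, `unit`, `outlier_low`, `outlier_high`, `kind`.
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  tribble_reg <- function(...) {
    m <- matrix(c(...), ncol = 6, byrow = TRUE)
    tibble(
      feature_id   = m[, 1],
      name         = m[, 2],
      unit         = m[, 3],
      outlier_low  = as.numeric(m[, 4]),
      outlier_high = as.numeric(m[, 5]),
      kind         = m[, 6]
    )
  }
  tribble_reg(
    "heart_rate",  "Heart rate",                 "beats/min",   "20",  "300", "dynamic",
    "resp_rate",   "Respiratory rate",           "breaths/min", "2",   "80",  "dynamic",
    "spo2",        "Oxygen saturation (SpO2)",   "%",           "50",  "100", "dynamic",
    "fio2",        "Fraction inspired oxygen",   "fraction",    "0.15","1",   "dynamic",
    "pao2",        "Arterial oxygen tension",    "mmHg",        "20",  "600", "dynamic",
    "mean_bp",     "Mean arterial pressure",     "mmHg",        "20",  "200", "dynamic",
    "temperature", "Body temperature",           "degC",        "30",  "43",  "dynamic",
    "lactate",     "Lactate",                    "mmol/L",      "0.1", "25",  "dynamic",
    "wbc",         "White blood cell count",     "10^3/uL",     "0.1", "100", "dynamic",
    "creatinine",  "Creatinine",                 "mg/dL",       "0.1", "25",  "dynamic",
    "peep_set",    "PEEP set",                   "cmH2O",       "0",   "30",  "operational",
    "fio2_set",    "Fraction inspired oxygen set","fraction",   "0.15","1",   "operational",
    "age",         "Age",                        "years",       "0",   "120", "static",
    "sex",         "Sex",                        "male/female", NA,    NA,    "static",
    "weight",      "Weight",                     "kg",          "20",  "400", "static",
    "height",      "Height",                     "cm",          "100", "250", "static"
  )
}

#' @rdname default_registry
#' @param path Path of a YAML registry file.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(x) {
    tibble(
      feature_id   = x$feature_id,
      name         = x$name %||% x$feature_id,
      unit         = x$unit %||% NA_character_,
      outlier_low  = as.numeric(x$outlier_low %||% NA),
      outlier_high = as.numeric(x$outlier_high %||% NA),
      kind         = x$kind %||% "dynamic"
    )
  })
  validate_registry(out)
}

#' @rdname default_registry
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  recs <- purrr::pmap(registry, function(...) {
    x <- list(...)
    x[!vapply(x, function(v) is.atomic(v) && length(v) == 1 && is.na(v), logical(1))]
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

validate_registry <- function(registry) {
  assert_cols(registry, c("feature_id", "kind"), "registry")
  if (anyDuplicated(registry$feature_id)) {
    abort("registry: duplicated feature_id")
  }
  bad <- !registry$kind %in% c("dynamic", "operational", "static")
  if (any(bad)) {
    abort(sprintf("registry: unknown kind for %s",
                  paste(registry$feature_id[bad], collapse = ", ")))
  }
  ok <- is.na(registry$outlier_low) | is.na(registry$outlier_high) |
    registry$outlier_low < registry$outlier_high
  if (!all(ok)) abort("registry: outlier_low must be < outlier_high")
  registry
}

dynamic_features <- function(registry, operational = TRUE) {
  kinds <- if (operational) c("dynamic", "operational") else "dynamic"
  registry$feature_id[registry$kind %in% kinds]
}

#' Toggle operational (clinician-set) features
#'
#' Returns the dynamic feature subset of a registry with or without the
#' operational features. Models trained without them can score patients
#' before any ventilator settings have been charted.
#'
#' @inheritParams default_registry
#' @param include Logical; keep operational features?
#' @return Character vector of dynamic `feature_id`s.
#' @export
toggle_operational_features <- function(registry, include = TRUE) {
  validate_registry(registry)
  dynamic_features(registry, operational = include)
}
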