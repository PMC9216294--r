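#' Default synthetic feature specifications
#'
#' Per-feature generative parameters for [simulate_cohort()]: baseline mean
#' in the feature's registry unit, AR(1) noise coefficient and innovation
#' SD, expected measurements per hour (Poisson sampling), and the loading
#' on the latent severity process. The respiratory rate carries the
#' dominant loading — deterioration toward ventilation is respiratory-led —
#' SpO2 loads negatively (so deteriorating stays become hypoxemic and
#' qualify for the cohort filter), and the two clinician-set features
#' (`peep_set`, `fio2_set`) track severity because staff escalate support
#' as patients worsen.
#'
#' @return Tibble `feature_id`, `baseline`, `noise_sd`, `ar1`, `rate`,
#'   `loading`, `operational`.
#' @export
sim_feature_defaults <- function() {
  m <- matrix(c(
    "heart_rate",  80,   8,    0.7, 1.0,  5,     0,
    "resp_rate",   18,   2.5,  0.7, 1.0,  8,     0,
    "spo2",        96.5, 1.5,  0.6, 1.0,  -3.5,  0,
    "fio2",        0.35, 0.06, 0.6, 0.5,  0.12,  0,
    "pao2",        90,   12,   0.5, 0.15, -12,   0,
    "mean_bp",     78,   9,    0.7, 1.0,  -4,    0,
    "temperature", 37,   0.4,  0.8, 0.4,  0.2,   0,
    "lactate",     1.6,  0.5,  0.8, 0.12, 0.7,   0,
    "wbc",         9,    2.5,  0.9, 0.08, 1.2,   0,
    "creatinine",  1.1,  0.4,  0.95,0.06, 0.25,  0,
    "peep_set",    5,    1,    0.8, 0.5,  1.8,   1,
    "fio2_set",    0.35, 0.05, 0.8, 0.5,  0.15,  1
  ), ncol = 7, byrow = TRUE)
  tibble(
    feature_id = m[, 1],
    baseline = as.numeric(m[, 2]), noise_sd = as.numeric(m[, 3]),
    ar1 = as.numeric(m[, 4]), rate = as.numeric(m[, 5]),
    loading = as.numeric(m[, 6]), operational = as.numeric(m[, 7]) == 1
  )
}

#' Synthetic-cohort configuration
#'
#' Defines the generative model behind a synthetic ICU cohort: a latent
#' per-stay severity process (per-stay frailty plus an AR(1) fluctuation,
#' optionally drifting), features loading linearly on severity with AR(1)
#' noise and feature-specific Poisson measurement rates, and a per-hour
#' logistic onset hazard in current severity. The defaults target roughly
#' 10% of stays reaching IMV onset and lengths of stay of 1 to 4 days.
#'
#' @param n_stays Number of stays.
#' @param los_range Hours; length of stay drawn uniformly in this range.
#' @param features Feature spec tibble (see [sim_feature_defaults()]).
#' @param n_noise_features Severity-independent nuisance features appended
#'   as `noise_1 ...` (zero loading).
#' @param severity List: `ar1` coefficient and innovation `noise_sd` of the
#'   fast fluctuation, per-stay `frailty_sd` (time-constant sickness level),
#'   and a per-stay linear deterioration trend drawn from
#'   `N(drift_mean, drift_sd)` per hour. The persistent components (frailty
#'   and drift) dominate the fast noise, making deterioration trend-like
#'   and onsets anticipatable many hours ahead, as observed clinically.
#' @param hazard Named vector `c(intercept, slope)` of the per-hour
#'   logistic onset hazard in current severity.
#' @param imv_duration `c(meanlog, sdlog)` of the lognormal ventilation
#'   duration (hours).
#' @param frac_nonhypoxemic Fraction of stays forced to stay non-hypoxemic
#'   (SpO2/PaO2 floored above the hypoxemia thresholds, no onset), to
#'   exercise the cohort filter.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_stays = 500L,
                       los_range = c(24, 96),
                       features = sim_feature_defaults(),
                       n_noise_features = 3L,
                       severity = list(ar1 = 0.9, noise_sd = 0.08,
                                       frailty_sd = 0.9, drift_mean = 0,
                                       drift_sd = 0.03),
                       hazard = c(intercept = -15, slope = 5),
                       imv_duration = c(meanlog = 3.4, sdlog = 0.8),
                       frac_nonhypoxemic = 0.12,
                       seed = 1L) {
  stopifnot(n_stays >= 1, los_range[1] >= 2, los_range[1] <= los_range[2],
            all(features$rate >= 0), all(features$ar1 >= 0 & features$ar1 < 1),
            severity$ar1 >= 0, severity$ar1 < 1, is.finite(hazard[["slope"]]),
            frac_nonhypoxemic >= 0, frac_nonhypoxemic < 1)
  if (n_noise_features > 0) {
    noise <- tibble(
      feature_id = paste0("noise_", seq_len(n_noise_features)),
      baseline = 0, noise_sd = 1, ar1 = 0.5, rate = 0.5, loading = 0,
      operational = FALSE
    )
    features <- bind_rows(features, noise)
  }
  structure(list(n_stays = as.integer(n_stays), los_range = los_range,
                 features = features, severity = severity, hazard = hazard,
                 imv_duration = imv_duration,
                 frac_nonhypoxemic = frac_nonhypoxemic, seed = seed),
            class = "sim_config")
}

#' Registry matching a simulation config
#'
#' The default registry plus a row per synthetic noise feature (no
#' plausibility bounds) with operational flags taken from the feature spec.
#'
#' @param config A [sim_config()].
#' @export
sim_registry <- function(config) {
  reg <- default_registry()
  extra <- setdiff(config$features$feature_id, reg$feature_id)
  if (length(extra) > 0) {
    op <- config$features$operational[match(extra, config$features$feature_id)]
    reg <- bind_rows(reg, tibble(
      feature_id = extra, name = extra, unit = "arbitrary",
      outlier_low = NA_real_, outlier_high = NA_real_,
      kind = ifelse(op, "operational", "dynamic")
    ))
  }
  reg
}

#' Shift a simulation config to a target domain
#'
#' Returns a new config with additive feature-mean shifts, additive
#' severity-loading shifts and additive hazard-coefficient deltas applied —
#' the generative analogue of moving from a general-ICU source population
#' to a clinically different target population. A zero/empty shift returns
#' an identical config.
#'
#' @param config A [sim_config()].
#' @param shift List with optional elements `mean` (named vector of
#'   baseline deltas), `loading` (named vector of loading deltas), `hazard`
#'   (named vector with `intercept` and/or `slope` deltas). Unknown feature
#'   names are an error.
#' @return The shifted `sim_config`.
#' @export
shift_domain <- function(config, shift) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(shift) || length(shift) == 0) return(config)
  feats <- config$features
  for (what in c("mean", "loading")) {
    v <- shift[[what]]
    if (is.null(v)) next
    unknown <- setdiff(names(v), feats$feature_id)
    if (length(unknown) > 0) {
      abort(sprintf("shift_domain: unknown feature(s) in %s shift: %s",
                    what, paste(unknown, collapse = ", ")))
    }
    i <- match(names(v), feats$feature_id)
    col <- if (what == "mean") "baseline" else "loading"
    feats[[col]][i] <- feats[[col]][i] + unname(v)
  }
  config$features <- feats
  hz <- shift$hazard
  if (!is.null(hz)) {
    unknown <- setdiff(names(hz), c("intercept", "slope"))
    if (length(unknown) > 0) {
      abort(sprintf("shift_domain: unknown hazard coefficient(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (nm in names(hz)) config$hazard[[nm]] <- config$hazard[[nm]] + hz[[nm]]
  }
  config
}

#' The canonical source-to-target domain shift
#'
#' The default shift used by the transfer experiments, emulating the move
#' from a general hypoxemic-ICU population to a respiratory-virus cohort:
#' deterioration becomes respiratory-dominant (respiratory rate gains
#' loading and runs higher; heart rate, white cells and lactate lose
#' predictive coupling), oxygen support runs higher for the same arterial
#' oxygenation (FiO2 up, hence lower PaO2/FiO2), blood pressure runs a
#' little higher, white counts lower, and the baseline onset hazard is
#' somewhat higher among the hypoxemic.
#'
#' @export
default_shift <- function() {
  list(
    mean = c(resp_rate = 4, heart_rate = -5.6, mean_bp = 5.9, wbc = -5.9,
             fio2 = 0.15, fio2_set = 0.15),
    loading = c(resp_rate = 3, heart_rate = -3.5, lactate = -0.4,
                wbc = -0.8),
    hazard = c(intercept = 0.5)
  )
}

#' Simulate a synthetic ICU cohort
#'
#' Generates `config$n_stays` stays: a latent severity trajectory per stay
#' (per-stay frailty + AR(1) fluctuation), irregularly sampled dynamic
#' features loading on that severity, statics, and IMV intervals whose
#' onsets fire from the per-hour logistic hazard in current severity.
#' Exactly the stays whose hazard fired carry an onset; the IMV interval
#' runs from the onset hour to a sampled extubation or discharge,
#' whichever is earlier. Values are clamped to the registry's plausibility
#' bounds (measurements outside physiology are not generated). Byte-
#' reproducible given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An `icu_cohort` whose `truth` element records, per stay, the
#'   true onset hour (`NA` if none), the design hypoxemia flag, the frailty
#'   and the severity trajectory (list column); the informative feature ids
#'   are in `attr(truth, "informative_features")`. The matching registry is
#'   attached as `$registry`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_stays
  H_i <- as.integer(floor(runif(n, config$los_range[1], config$los_range[2])))
  los <- H_i + round(runif(n, 0, 0.99), 2)
  maxH <- max(H_i)
  ids <- sprintf("stay_%05d", seq_len(n))

  sv <- config$severity
  stat_sd <- sv$noise_sd / sqrt(1 - sv$ar1^2)
  frailty <- rnorm(n, 0, sv$frailty_sd)
  drift <- rnorm(n, sv$drift_mean %||% 0, sv$drift_sd %||% 0)
  S <- matrix(0, maxH, n)
  S[1, ] <- rnorm(n, 0, stat_sd)
  for (h in seq_len(maxH - 1)) {
    S[h + 1, ] <- sv$ar1 * S[h, ] + rnorm(n, 0, sv$noise_sd)
  }
  sev <- sweep(S, 2, frailty, "+") + outer(seq_len(maxH) - 1, drift)

  nonhypox <- rbinom(n, 1, config$frac_nonhypoxemic) == 1
  valid <- outer(seq_len(maxH), H_i, "<=")

  # per-hour logistic hazard; onset = first firing hour (0-based)
  p <- plogis(config$hazard[["intercept"]] + config$hazard[["slope"]] * sev)
  fired <- matrix(runif(maxH * n), maxH, n) < p & valid
  fired[, nonhypox] <- FALSE
  onset0 <- suppressWarnings(apply(fired, 2, function(x) which(x)[1])) - 1L

  dur <- rlnorm(n, config$imv_duration[["meanlog"]],
                config$imv_duration[["sdlog"]])
  has_onset <- !is.na(onset0)
  vent <- tibble(
    stay_id = ids[has_onset],
    start_hours = as.numeric(onset0[has_onset]),
    end_hours = pmin(onset0[has_onset] + dur[has_onset], los[has_onset])
  )

  stays <- tibble(
    stay_id = ids,
    los_hours = los,
    age = pmin(pmax(round(rnorm(n, 67, 16)), 18), 95),
    sex = ifelse(runif(n) < 0.55, "male", "female"),
    weight = round(pmin(pmax(rnorm(n, 82, 24), 40), 200), 1),
    height = round(pmin(pmax(rnorm(n, 168, 12), 140), 210), 1)
  )

  registry <- sim_registry(config)
  bounds <- registry[match(config$features$feature_id, registry$feature_id), ]
  events <- purrr::map_dfr(seq_len(nrow(config$features)), function(j) {
    f <- config$features[j, ]
    E <- matrix(0, maxH, n)
    E[1, ] <- rnorm(n, 0, f$noise_sd / sqrt(1 - f$ar1^2))
    for (h in seq_len(maxH - 1)) {
      E[h + 1, ] <- f$ar1 * E[h, ] + rnorm(n, 0, f$noise_sd)
    }
    V <- f$baseline + f$loading * sev + E
    if (f$feature_id == "spo2") V[, nonhypox] <- pmax(V[, nonhypox], 91)
    if (f$feature_id == "pao2") V[, nonhypox] <- pmax(V[, nonhypox], 65)
    lo <- bounds$outlier_low[j]; hi <- bounds$outlier_high[j]
    if (!is.na(lo)) V <- pmax(V, lo)
    if (!is.na(hi)) V <- pmin(V, hi)
    cnt <- matrix(rpois(maxH * n, f$rate), maxH, n)
    cnt[!valid] <- 0L
    k <- as.vector(cnt)
    if (sum(k) == 0) return(NULL)
    hour0 <- rep(rep(seq_len(maxH) - 1L, n), k)
    val <- rep(as.vector(V), k) + rnorm(sum(k), 0, 0.05 * f$noise_sd)
    if (!is.na(lo)) val <- pmax(val, lo)
    if (!is.na(hi)) val <- pmin(val, hi)
    tibble(
      stay_id = rep(rep(ids, each = maxH), k),
      feature_id = f$feature_id,
      time_hours = hour0 + runif(sum(k), 0, 0.999),
      value = val
    )
  })

  truth <- tibble(
    stay_id = ids,
    onset_hour = onset0,
    hypoxemic_design = !nonhypox,
    frailty = frailty,
    drift = drift,
    severity = purrr::map(seq_len(n), function(i) sev[seq_len(H_i[i]), i])
  )
  attr(truth, "informative_features") <-
    config$features$feature_id[config$features$loading != 0]

  cohort <- icu_cohort(stays, events, vent, truth = truth)
  cohort$registry <- registry
  cohort
}
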