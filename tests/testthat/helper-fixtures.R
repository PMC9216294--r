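# Hand-built cohort fixtures, constructed in code.

make_stay_tbl <- function(stay_id = "s1", los_hours = 30, age = 60,
                          sex = "male", weight = 80, height = 170) {
  tibble::tibble(stay_id = stay_id, los_hours = los_hours, age = age,
                 sex = sex, weight = weight, height = height)
}

make_events <- function(stay_id, feature_id, time_hours, value) {
  tibble::tibble(stay_id = stay_id, feature_id = feature_id,
                 time_hours = time_hours, value = value)
}

empty_events <- function() {
  tibble::tibble(stay_id = character(), feature_id = character(),
                 time_hours = numeric(), value = numeric())
}

empty_vent <- function() {
  tibble::tibble(stay_id = character(), start_hours = numeric(),
                 end_hours = numeric())
}

# One-stay cohort with configurable vent intervals and events.
tiny_cohort <- function(los = 30, vent = empty_vent(), events = NULL,
                        stay_id = "s1", age = 60) {
  events <- events %||% make_events(stay_id, "spo2", c(1.5, 2.2), c(88, 92))
  icu_cohort(make_stay_tbl(stay_id, los_hours = los, age = age),
             events, vent)
}

# Random multi-stay cohort with arbitrary vent intervals, for oracle checks.
random_cohort <- function(n_stays, seed, los_range = c(14, 48),
                          p_vent = 0.5) {
  set.seed(seed)
  stays <- tibble::tibble(
    stay_id = sprintf("r%03d", seq_len(n_stays)),
    los_hours = round(runif(n_stays, los_range[1], los_range[2]), 2),
    age = sample(10:90, n_stays, replace = TRUE),
    sex = sample(c("male", "female"), n_stays, replace = TRUE),
    weight = runif(n_stays, 50, 120),
    height = runif(n_stays, 150, 200)
  )
  events <- purrr::map_dfr(seq_len(n_stays), function(i) {
    k <- sample(5:40, 1)
    make_events(stays$stay_id[i],
                sample(c("spo2", "heart_rate", "pao2"), k, replace = TRUE),
                round(runif(k, 0, stays$los_hours[i] - 0.01), 3),
                runif(k, 40, 120))
  })
  vent <- purrr::map_dfr(seq_len(n_stays), function(i) {
    if (runif(1) > p_vent) return(empty_vent())
    los <- stays$los_hours[i]
    n_iv <- sample(1:2, 1)
    starts <- sort(runif(n_iv, 0, los - 2))
    ends <- pmin(starts + runif(n_iv, 0.5, 12), los)
    tibble::tibble(stay_id = stays$stay_id[i], start_hours = starts,
                   end_hours = ends)
  })
  icu_cohort(stays, events, vent)
}
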