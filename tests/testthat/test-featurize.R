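test_that("hourly aggregation takes the in-hour mean and sets the triplet", {
  ev <- dplyr::bind_rows(
    make_events("s1", "spo2", c(3.1, 3.9), c(80, 90)),   # hour 3: mean 85
    make_events("s1", "heart_rate", 0.0, 70)             # boundary: bin 0
  )
  coh <- icu_cohort(make_stay_tbl(los_hours = 6), ev, empty_vent())
  hg <- aggregate_hourly(coh)
  g <- hg$grid
  spo2_3 <- g[g$feature_id == "spo2" & g$hour == 3, ]
  expect_equal(spo2_3$value, 85)
  expect_equal(spo2_3$mask, 1L)
  expect_equal(spo2_3$tsl, 0L)
  hr0 <- g[g$feature_id == "heart_rate" & g$hour == 0, ]
  expect_equal(hr0$mask, 1L)
  # a feature never measured: mask 0 everywhere, tsl = h + 1
  lac <- g[g$feature_id == "lactate", ]
  expect_true(all(lac$mask == 0L))
  expect_equal(lac$tsl, lac$hour + 1L)
})

test_that("triplets equal a per-hour brute-force recomputation on random streams", {
  coh <- random_cohort(15, seed = 55)
  hg <- aggregate_hourly(coh)
  for (sid in coh$stays$stay_id) {
    H <- floor(coh$stays$los_hours[coh$stays$stay_id == sid])
    for (f in c("spo2", "heart_rate", "pao2")) {
      ev <- coh$events[coh$events$stay_id == sid & coh$events$feature_id == f, ]
      want <- oracle_triplets(ev, H)
      got <- hg$grid[hg$grid$stay_id == sid & hg$grid$feature_id == f, ]
      expect_equal(got$value, want$value)
      expect_equal(got$mask, want$mask)
      expect_equal(got$tsl, want$tsl)
    }
  }
})

test_that("triplet channel consistency holds on simulated cohorts", {
  coh <- simulate_cohort(sim_config(n_stays = 40, seed = 9))
  hg <- aggregate_hourly(coh, coh$registry)
  g <- hg$grid
  expect_true(all((g$mask == 1L) == (g$tsl == 0L)))
  # tsl increments by exactly 1 per unmeasured hour
  inc <- g %>%
    dplyr::group_by(stay_id, feature_id) %>%
    dplyr::mutate(d = tsl - dplyr::lag(tsl)) %>%
    dplyr::filter(!is.na(d), mask == 0L)
  expect_true(all(inc$d == 1L))
})

test_that("standardization is fit on measured hours of the training split only", {
  ev <- dplyr::bind_rows(
    make_events("s1", "spo2", c(0.5, 1.5), c(0, 2)),
    make_events("s2", "spo2", c(0.5, 1.5), c(100, 100))
  )
  coh <- icu_cohort(
    dplyr::bind_rows(make_stay_tbl("s1", 4), make_stay_tbl("s2", 4)),
    ev, empty_vent())
  hg <- aggregate_hourly(coh)
  p <- fit_standardization(hg, stay_ids = "s1")
  spo2 <- p[p$feature_id == "spo2", ]
  expect_equal(spo2$mean, 1)           # {0, 2} -> mean 1
  expect_equal(spo2$sd, sqrt(2))       # sample sd over measured hours
  expect_equal(spo2$n_measured, 2L)
  # constant feature on the training split
  p2 <- fit_standardization(hg, stay_ids = "s2")
  expect_true(p2$constant[p2$feature_id == "spo2"])
  # never-measured features flagged constant with 0 fallback
  expect_true(p$constant[p$feature_id == "lactate"])
})

test_that("standardized measured values have mean 0, variance 1 on the training split", {
  coh <- simulate_cohort(sim_config(n_stays = 30, seed = 10))
  hg <- aggregate_hourly(coh, coh$registry)
  p <- fit_standardization(hg)
  z <- impute_hourly(hg, p)
  zz <- z$grid %>% dplyr::filter(mask == 1L, feature_id == "heart_rate")
  expect_equal(mean(zz$value), 0, tolerance = 1e-10)
  expect_equal(stats::var(zz$value), 1, tolerance = 1e-10)
})

test_that("imputation carries the last standardized observation forward", {
  ev <- make_events("s1", "spo2", 0.5, 92)
  coh <- icu_cohort(make_stay_tbl(los_hours = 3), ev, empty_vent())
  hg <- aggregate_hourly(coh)
  params <- tibble::tibble(
    feature_id = hg$features, mean = 90, sd = 2, n_measured = 10L,
    constant = FALSE)
  z <- impute_hourly(hg, params)
  g <- z$grid[z$grid$feature_id == "spo2", ]
  expect_equal(g$value, rep((92 - 90) / 2, 3))     # carried forward
  expect_equal(g$tsl, c(0L, 1L, 2L))
  # feature with no measurements: all zeros (the standardized mean)
  hr <- z$grid[z$grid$feature_id == "heart_rate", ]
  expect_true(all(hr$value == 0))
  expect_true(all(hr$mask == 0L))
  # pre-observation hours are 0, not back-filled
  ev2 <- make_events("s1", "spo2", 2.5, 92)
  hg2 <- aggregate_hourly(icu_cohort(make_stay_tbl(los_hours = 4), ev2,
                                     empty_vent()))
  z2 <- impute_hourly(hg2, params)
  g2 <- z2$grid[z2$grid$feature_id == "spo2", ]
  expect_equal(g2$value, c(0, 0, 1, 1))
  # idempotence
  expect_equal(impute_hourly(z, params), z)
})

test_that("derived respiratory indices follow their definitions and guard division", {
  ev <- dplyr::bind_rows(
    make_events("s1", "spo2", c(0.2, 1.2, 2.2), c(92, 92, 92)),
    make_events("s1", "fio2", c(0.5, 2.5), c(0.4, 0.4)),
    make_events("s1", "resp_rate", c(0.7, 1.7, 2.7), c(23, 23, 0)),
    make_events("s1", "pao2", 0.4, 80)
  )
  coh <- icu_cohort(make_stay_tbl(los_hours = 3), ev, empty_vent())
  hg <- add_derived_indices(aggregate_hourly(coh))
  g <- hg$grid
  rox <- g[g$feature_id == "rox", ]
  expect_equal(rox$value[rox$hour == 0], (92 / 0.4) / 23)  # = 10
  expect_equal(rox$mask[rox$hour == 1], 0L)                # fio2 missing
  expect_equal(rox$mask[rox$hour == 2], 0L)                # rr = 0 guarded
  pf <- g[g$feature_id == "pf_ratio", ]
  expect_equal(pf$value[pf$hour == 0], 80 / 0.4)
  sf <- g[g$feature_id == "sf_ratio", ]
  expect_equal(sf$value[sf$hour == 2], 92 / 0.4)
  # derived features go through standardization like any other
  expect_true(all(c("rox", "sf_ratio", "pf_ratio") %in%
                    fit_standardization(hg)$feature_id))
})

featurize_one <- function(coh, cfg = window_config()) {
  hg <- aggregate_hourly(coh)
  z <- impute_hourly(hg, fit_standardization(hg))
  enumerate_windows(z, derive_vent_states(coh), cfg)
}

test_that("window enumeration matches the counting argument and the exclusion rules", {
  # LOS 40, never ventilated, gap 6: 40 - 6 - 6 - 4 + 1 = 25 negatives
  coh <- tiny_cohort(los = 40)
  w <- featurize_one(coh)
  expect_equal(nrow(w$meta), 25)
  expect_true(all(w$meta$label == 0))
  expect_equal(w$meta$t, 6:30)

  # onset at hour 14, gap 6, 30-h stay: positives at t in {6,7,8}
  v <- tibble::tibble(stay_id = "s1", start_hours = 14, end_hours = 25)
  w2 <- featurize_one(tiny_cohort(los = 30, vent = v))
  expect_equal(w2$meta$t[w2$meta$label == 1], 6:8)
  # and no window overlaps IMV through its feature+gap span
  expect_true(max(w2$meta$t) <= 8)

  # stay entirely on IMV: zero samples
  vfull <- tibble::tibble(stay_id = "s1", start_hours = 0, end_hours = 30)
  w3 <- featurize_one(tiny_cohort(los = 30, vent = vfull))
  expect_equal(nrow(w3$meta), 0)

  # stay shorter than feature + gap + target: zero samples
  w4 <- featurize_one(tiny_cohort(los = 15))
  expect_equal(nrow(w4$meta), 0)
})

test_that("window enumeration equals the exhaustive oracle on random stays", {
  coh <- random_cohort(30, seed = 77, los_range = c(14, 60), p_vent = 0.6)
  w <- featurize_one(coh)
  for (sid in coh$stays$stay_id) {
    los <- coh$stays$los_hours[coh$stays$stay_id == sid]
    want <- oracle_windows(coh$vent[coh$vent$stay_id == sid, ], los)
    got <- w$meta[w$meta$stay_id == sid, c("t", "label")]
    expect_equal(got$t, want$t)
    expect_equal(got$label, want$label)
  }
})

test_that("larger gaps never increase the number of emitted samples", {
  coh <- random_cohort(20, seed = 78, los_range = c(40, 80), p_vent = 0.6)
  counts <- vapply(c(6, 12, 18, 24), function(g) {
    nrow(featurize_one(coh, window_config(gap = g))$meta)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("window features carry the right hours in the right columns", {
  # one feature with value = hour number makes block layout checkable
  ev <- make_events("s1", "heart_rate", (0:29) + 0.5, 100 + 0:29)
  coh <- icu_cohort(make_stay_tbl(los_hours = 30), ev, empty_vent())
  hg <- aggregate_hourly(coh)
  params <- fit_standardization(hg)
  w <- enumerate_windows(impute_hourly(hg, params),
                         derive_vent_states(coh), window_config(),
                         features = "heart_rate")
  m <- params[params$feature_id == "heart_rate", ]
  t1 <- w$meta$t[1]
  for (k in 0:5) {
    col <- sprintf("heart_rate__value__w%d", k)
    raw <- 100 + (t1 - 6 + k)
    expect_equal(w$features[1, col], (raw - m$mean) / m$sd,
                 ignore_attr = TRUE)
  }
  expect_equal(w$features[1, "age"], 60, ignore_attr = TRUE)
  expect_equal(w$features[1, "sex_male"], 1, ignore_attr = TRUE)
})

test_that("rare-feature exclusion drops features below the measured-hour count", {
  coh <- random_cohort(10, seed = 91)
  # plant a sparse feature: 4 measured hours across the cohort
  sparse <- make_events(coh$stays$stay_id[1:4], "lactate", 1.5, 2)
  coh$events <- dplyr::bind_rows(coh$events, sparse)
  hg <- aggregate_hourly(coh)
  kept <- suppressMessages(exclude_rare_features(hg, min_count = 5))
  expect_false("lactate" %in% kept)
  expect_true("spo2" %in% kept)
  # boundary: a feature with count just below the cutoff is dropped
  n_spo2 <- sum(hg$grid$mask[hg$grid$feature_id == "spo2"])
  kept2 <- suppressMessages(exclude_rare_features(hg, min_count = n_spo2 + 1))
  expect_false("spo2" %in% kept2)
  # min_count 0 is the identity
  expect_equal(exclude_rare_features(hg, min_count = 0), hg$features)
})

test_that("patient-level splits partition reproducibly", {
  ids <- sprintf("s%02d", 1:10)
  sp <- split_patients(ids, c(train = 0.8, test = 0.2), seed = 5)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$test), 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_equal(split_patients(ids, c(train = 0.8, test = 0.2), seed = 5), sp)
  expect_error(split_patients(character(0)), "empty")

  # all of a stay's windows land on one side of the split
  coh <- random_cohort(12, seed = 92, los_range = c(20, 40))
  w <- featurize_one(coh)
  sp2 <- split_patients(coh, c(a = 0.5, b = 0.5), seed = 9)
  wa <- ventwatch:::windows_for_stays(w, sp2$a)
  wb <- ventwatch:::windows_for_stays(w, sp2$b)
  expect_length(intersect(unique(wa$meta$stay_id), unique(wb$meta$stay_id)), 0)
  expect_equal(nrow(wa$meta) + nrow(wb$meta), nrow(w$meta))
})

test_that("window samples persist and reload bit-exactly", {
  coh <- random_cohort(5, seed = 93, los_range = c(20, 40))
  w <- featurize_one(coh)
  dir <- withr::local_tempdir()
  write_windows(w, dir)
  back <- read_windows(dir)
  expect_equal(back$features, w$features)
  expect_equal(back$meta, w$meta)
  expect_equal(back$manifest, w$manifest)
  expect_equal(unclass(back$config), unclass(w$config))
})
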