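test_that("peak detection is exact on clean beats and fails cleanly", {
  d <- clean_measurement()
  rec <- d$ppg[[1]][[1]]
  p1 <- detect_peaks(rec$samples, rec$fs)
  p2 <- detect_peaks(rec$samples, rec$fs)
  expect_identical(p1, p2)
  expect_identical(length(p1), rec$n_beats)
  expect_false(is.unsorted(p1))
  expect_true(all(diff(p1) >= 0.333 * rec$fs))
  expect_error(detect_peaks(rep(1, 500), 50), "peak")
})

test_that("PP intervals follow the arithmetic and the physiologic filter", {
  pp <- compute_pp_intervals(c(0, 50, 100), 50)
  expect_equal(pp$intervals_ms, c(1000, 1000))
  expect_length(pp$peak_times_s, 3L)
  # a 200 ms gap is filtered out, leaving one interval -> error
  expect_error(compute_pp_intervals(c(0, 10, 60), 50), "fewer than 2")
})

test_that("time-domain HRV features match hand arithmetic", {
  pp <- structure(list(intervals_ms = rep(800, 10),
                       peak_times_s = cumsum(c(0, rep(0.8, 10)))),
                  class = "pp_series")
  f <- hrv_time_features(pp)
  expect_equal(unname(f[c("sdnn", "rmssd", "nn50", "pnn50")]), c(0, 0, 0, 0))
  expect_equal(unname(f["meanPP"]), 800)

  iv <- c(800, 850, 790, 900)   # diffs 50, -60, 110; strict > 50 counts 2
  pp2 <- structure(list(intervals_ms = iv,
                        peak_times_s = cumsum(c(0, iv)) / 1000),
                   class = "pp_series")
  f2 <- hrv_time_features(pp2)
  expect_equal(unname(f2["meanPP"]), 835)
  expect_equal(unname(f2["nn50"]), 2)
  expect_equal(unname(f2["pnn50"]), 100 * 2 / 3, tolerance = 1e-10)

  # translation: meanPP shifts, dispersion statistics unchanged
  pp3 <- structure(list(intervals_ms = iv + 100,
                        peak_times_s = cumsum(c(0, iv + 100)) / 1000),
                   class = "pp_series")
  f3 <- hrv_time_features(pp3)
  expect_equal(unname(f3["meanPP"]), unname(f2["meanPP"]) + 100)
  expect_equal(f3[c("sdnn", "rmssd", "sdsd")], f2[c("sdnn", "rmssd", "sdsd")])

  # RMSSD is invariant to reversing the interval sequence
  pp4 <- structure(list(intervals_ms = rev(iv),
                        peak_times_s = cumsum(c(0, rev(iv))) / 1000),
                   class = "pp_series")
  expect_equal(hrv_time_features(pp4)["rmssd"], f2["rmssd"])
})

test_that("frequency-domain HRV localises planted modulation", {
  # 0.25 Hz planted modulation on a 120 s tachogram -> HF dominates LF
  tm <- cumsum(rep(0.8, 150))
  iv <- 800 + 40 * sin(2 * pi * 0.25 * tm)
  pp <- structure(list(intervals_ms = iv, peak_times_s = c(0, tm)),
                  class = "pp_series")
  f <- hrv_freq_features(pp)
  expect_gt(f[["hf"]], f[["lf"]])
  expect_equal(f[["lfnu"]] + f[["hfnu"]], 100, tolerance = 1e-9)
  expect_lte(f[["vlf"]] + f[["lf"]] + f[["hf"]], f[["tp"]] + 1e-9)

  short <- structure(list(intervals_ms = rep(800, 10),
                          peak_times_s = cumsum(c(0, rep(0.8, 10)))),
                     class = "pp_series")
  expect_error(hrv_freq_features(short), "30 s")
})

test_that("heart-rate statistics follow the stated conventions", {
  const <- structure(list(intervals_ms = rep(800, 10),
                          peak_times_s = cumsum(c(0, rep(0.8, 10)))),
                     class = "pp_series")
  f <- hr_stats_features(const)
  expect_equal(unname(f["mean"]), 75)
  expect_equal(unname(f["median"]), 75)
  expect_equal(unname(f["mode"]), 75)
  expect_equal(unname(f[c("var", "sd", "range", "iqr", "mad",
                          "skew", "kurt")]),
               rep(0, 7))

  hr <- c(60, 60, 80)                    # intervals 1000, 1000, 750 ms
  pp <- structure(list(intervals_ms = 60000 / hr,
                       peak_times_s = cumsum(c(0, 60000 / hr)) / 1000),
                  class = "pp_series")
  f2 <- hr_stats_features(pp)
  expect_equal(unname(f2["mode"]), 60)
  expect_equal(unname(f2["range"]), 20)
  expect_gte(unname(f2["mean"]), min(hr))
  expect_lte(unname(f2["mean"]), max(hr))
})

test_that("absorption features are the sample mean and variance", {
  expect_equal(unname(absorption_features(rep(3, 10))), c(3, 0))
  expect_equal(unname(absorption_features(c(0, 1, 2))), c(1, 1))
  x <- rnorm(50)
  expect_equal(absorption_features(5 * x)[["var"]],
               25 * absorption_features(x)[["var"]])
})

test_that("meal timing wraps across midnight", {
  meals <- c(7.5, 12.5, 18.5)
  expect_equal(meal_time_feature(13.5, meals), 1.0)
  expect_equal(meal_time_feature(6.0, meals), 11.5)
  expect_equal(meal_time_feature(12.5, meals), 0.0)
  expect_error(meal_time_feature(10, numeric(0)), "empty")
})

test_that("the feature vector has the canonical 1/2/8/52/40 layout", {
  nm <- feature_names()
  expect_length(nm, 103L)
  expect_equal(sum(startsWith(nm, "cat1_")), 1L)
  expect_equal(sum(startsWith(nm, "cat2_")), 2L)
  expect_equal(sum(startsWith(nm, "cat3_")), 8L)
  expect_equal(sum(startsWith(nm, "cat4_")), 52L)
  expect_equal(sum(startsWith(nm, "cat5_")), 40L)

  fx <- small_cohort_features()
  fv <- measurement_features(as.list(fx$measurements[1, ]))
  expect_length(fv, 103L)
  expect_identical(names(fv), nm)
  expect_true(all(is.finite(fv)))
})

test_that("ground truth survives the extraction chain on constant beats", {
  cfg <- synth_config(n_subjects = 1, measurements_per_subject = 1,
                      duration_s = 40, noise_sd = 0, drift_amp = 0,
                      seed = 606L)
  d <- generate_dataset(cfg)
  rec <- d$ppg[[1]][[1]]
  # replace with exactly constant 800 ms beats
  const <- generate_ppg_record(rep(800, 60), 880, rec$fs, 40,
                               glucose = 6, cfg, seed = 1)
  pp <- compute_pp_intervals(detect_peaks(const$samples, const$fs), const$fs)
  expect_lt(abs(mean(pp$intervals_ms) - 800), 1000 / const$fs + 1e-9)
  hr <- hr_stats_features(pp)
  expect_lt(abs(hr[["mean"]] - 60000 / 800), 1)
})

test_that("feature tables carry one row per measurement", {
  fx <- small_cohort_features()
  ft <- fx$features
  expect_equal(nrow(ft), nrow(fx$measurements))
  expect_equal(ncol(ft), 103L + 3L)
  expect_true(all(feature_names() %in% names(ft)))
})
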