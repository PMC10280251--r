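test_that("gen_ecg produces beats at the requested rate, deterministically", {
  x <- gen_ecg(fs = 360, duration = 10, heart_rate = 72, seed = 1)
  expect_length(x, 3600)
  expect_lt(abs(mean(x)), 1e-8 * rms(x))
  # 72 bpm over 10 s -> 12 beats; independent peak finder
  n_peaks <- length(find_peaks(x, frac = 0.5, min_dist = 360 * 0.4))
  expect_gte(n_peaks, 11)
  expect_lte(n_peaks, 13)
  expect_identical(x, gen_ecg(fs = 360, duration = 10, heart_rate = 72, seed = 1))
  expect_false(identical(x, gen_ecg(fs = 360, duration = 10, heart_rate = 72,
                                    seed = 2)))
})

test_that("gen_ecg validates its arguments", {
  expect_error(gen_ecg(duration = 0), "duration")
  expect_error(gen_ecg(fs = 50), "fs")
  expect_error(gen_ecg(heart_rate = 300), "heart_rate")
  expect_error(gen_ecg(duration = 1, heart_rate = 40), "duration")
})

test_that("baseline wander is confined to low frequencies", {
  x <- gen_baseline_wander(fs = 360, duration = 60, seed = 2)
  expect_lt(abs(mean(x)), 1e-8 * rms(x))
  expect_gte(power_below(x, 360, 0.7), 0.9)
  # periodogram peak inside the respiration drift band
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  f_peak <- sp$freq[which.max(sp$spec)] * 360
  expect_gte(f_peak, 0.05)
  expect_lte(f_peak, 0.35)
  expect_identical(x, gen_baseline_wander(fs = 360, duration = 60, seed = 2))
  expect_identical(gen_baseline_wander(amplitude = 0, seed = 1),
                   rep(0, 3600))
  expect_error(gen_baseline_wander(drift_band = c(100, 200), fs = 360), "band")
})

test_that("muscle artifact is broadband and intermittent", {
  x <- gen_muscle_artifact(fs = 360, duration = 60, burst_rate = 0.2, seed = 3)
  expect_lt(abs(mean(x)), 1e-8 * rms(x))
  # positive excess kurtosis from burst intermittency
  kurt <- mean(x^4) / mean(x^2)^2 - 3
  expect_gt(kurt, 0)
  # most power above 5 Hz
  expect_lt(power_below(x, 360, 5), 0.5)
  expect_identical(gen_muscle_artifact(amplitude = 0, seed = 1), rep(0, 3600))
  expect_error(gen_muscle_artifact(burst_rate = -1), "burst_rate")
  expect_identical(x, gen_muscle_artifact(fs = 360, duration = 60,
                                          burst_rate = 0.2, seed = 3))
})

test_that("electrode movement produces a plausible Poisson event count", {
  x <- gen_electrode_movement(fs = 360, duration = 100, event_rate = 0.1,
                              crackle = 0, seed = 4)
  n_ev <- count_steps(x, 360)
  # Poisson(10) central 95% range
  expect_gte(n_ev, 4)
  expect_lte(n_ev, 16)
  expect_lt(abs(mean(x)), 1e-8 * rms(x))
  expect_identical(gen_electrode_movement(event_rate = 0, seed = 1),
                   rep(0, 3600))
  expect_identical(x, gen_electrode_movement(fs = 360, duration = 100,
                                             event_rate = 0.1, crackle = 0,
                                             seed = 4))
  expect_error(gen_electrode_movement(event_rate = -0.1), "event_rate")
})

test_that("generator RMS scales linearly with amplitude", {
  gens <- list(
    function(a) gen_ecg(fs = 360, duration = 5, amplitude = a, seed = 9),
    function(a) gen_baseline_wander(fs = 360, duration = 5, amplitude = a, seed = 9),
    function(a) gen_muscle_artifact(fs = 360, duration = 5, amplitude = a, seed = 9),
    function(a) gen_electrode_movement(fs = 360, duration = 5, amplitude = a,
                                       event_rate = 1, seed = 9)
  )
  for (g in gens) {
    r1 <- rms(g(1))
    r3 <- rms(g(3))
    expect_equal(r3 / r1, 3, tolerance = 1e-10)
    expect_equal(r1, 1, tolerance = 1e-10)
  }
})

test_that("spectral separation of BW and MA holds at fs = 360", {
  bw <- gen_baseline_wander(fs = 360, duration = 30, seed = 5)
  ma <- gen_muscle_artifact(fs = 360, duration = 30, burst_rate = 0.4, seed = 5)
  expect_lt(1 - power_below(bw, 360, 1), 0.05)  # < 5% of BW power above 1 Hz
  expect_gt(1 - power_below(ma, 360, 5), 0.5)   # > 50% of MA power above 5 Hz
})

test_that("gen_standard_sources returns a labelled, zero-mean source set", {
  s <- gen_standard_sources(fs = 360, duration = 5, seed = 7)
  expect_s3_class(s, "source_set")
  expect_identical(s$labels, c("ECG", "BW", "EM", "MA"))
  expect_identical(dim(s), c(4L, 1800L))
  expect_true(all(apply(s$signals, 1, stats::sd) > 0))
})
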