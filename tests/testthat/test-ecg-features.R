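test_that("ecg_record validates its invariants", {
  expect_s3_class(ecg_record(c(0, 1, 0), 100), "ecg_record")
  expect_error(ecg_record(numeric(0), 100), "samples")
  expect_error(ecg_record(c(1, NA), 100), "non-finite")
  expect_error(ecg_record(c(1, 2), 0), "positive")
})

test_that("zero-phase high-pass removes DC and baseline wander but keeps the signal band", {
  fs <- 500
  n <- 15000 # 30 s: a 0.5 Hz filter needs several seconds to settle
  trim <- 5001:10000 # central third, away from the edge transients

  # constant signal -> ~0 everywhere
  flat <- highpass_baseline(ecg_record(rep(1, n), fs), 0.5)
  expect_lt(max(abs(flat$samples[trim])), 1e-6)

  # 10 Hz sinusoid: amplitude preserved within 1% (passband)
  t <- (seq_len(n) - 1) / fs
  s10 <- highpass_baseline(ecg_record(sin(2 * pi * 10 * t), fs), 0.5)
  expect_equal(max(abs(s10$samples[trim])), 1, tolerance = 0.01)

  # 0.2 Hz, 0.5 mV wander knocked below 0.05 mV
  wander <- highpass_baseline(ecg_record(0.5 * sin(2 * pi * 0.2 * t), fs), 0.5)
  expect_lt(max(abs(wander$samples[trim])), 0.05)

  expect_error(highpass_baseline(ecg_record(rep(1, n), fs), 600),
               "sampling_rate")
})

test_that("R-peak detection finds every beat and nothing else", {
  sim <- gen_ecg(ecg_spec("mouse", n_beats = 10, seed = 11))
  peaks <- detect_r_peaks(sim$record)
  expect_length(peaks, 10)
  t_ms <- ecg_time_ms(sim$record)[peaks]
  expect_lt(max(abs(t_ms - sim$truth$r_peak_ms)), 2)

  # extra amplitude noise must not change the count
  noisy <- gen_ecg(ecg_spec("mouse", n_beats = 10, noise_sd_mV = 0.05,
                            seed = 11))
  expect_length(detect_r_peaks(noisy$record), 10)

  expect_warning(empty <- detect_r_peaks(ecg_record(rep(0, 1000), 1000)),
                 "no R peaks")
  expect_length(empty, 0)
})

test_that("a linear T-wave decline yields t_end90 at 90% of the decline", {
  # triangular T: peak 0.3 mV decaying linearly to 0 over 20 ms
  fs <- 10000
  t <- seq(0, 200, by = 1000 / fs)
  v <- numeric(length(t))
  r_at <- 80
  v <- v + 1.0 * exp(-(t - r_at)^2 / (2 * 0.8^2)) # narrow R for anchoring
  v <- v - 0.2 * exp(-(t - (r_at + 4))^2 / (2 * 0.8^2)) # S wave
  v <- v + 0.05 * exp(-(t - (r_at + 7))^2 / (2 * 0.8^2)) # J bump: iso recross
  tpk <- r_at + 25
  up <- t >= tpk - 4 & t <= tpk
  v[up] <- 0.3 * (t[up] - (tpk - 4)) / 4
  dn <- t > tpk & t <= tpk + 20
  v[dn] <- 0.3 * (1 - (t[dn] - tpk) / 20)
  rec <- ecg_record(v, fs, species_hint = "mouse")
  w <- delineation_windows("mouse", smooth_ms = 0.1, smooth_qrs_ms = 0.1)
  b <- delineate_beat(rec, which.max(v), windows = w)
  # 90% of a linear 20-ms decline is completed 18 ms after the peak
  expect_equal(b$t_end90_ms - b$t_peak_ms, 18, tolerance = 0.3)
})

test_that("generated ECGs round-trip through delineation within 2 ms (mouse)", {
  sim <- gen_ecg(ecg_spec("mouse", n_beats = 60, seed = 2))
  rec <- highpass_baseline(sim$record, 0.5)
  beats <- delineate_ecg(rec)
  iv <- average_intervals(beats)
  expect_lt(abs(iv$PR_ms - mean(sim$truth$pr_ms)), 2)
  expect_lt(abs(iv$QRS_ms - mean(sim$truth$qrs_ms)), 2)
  expect_lt(abs(iv$QT_ms - mean(sim$truth$qt_ms)), 2)
  expect_lt(abs(iv$RR_ms - sim$truth$rr_ms[1]), 1)
  expect_equal(iv$HR_bpm, 60000 / iv$RR_ms)
})

test_that("human delineation stays within 3 ms of the programmed intervals", {
  sim <- gen_ecg(ecg_spec("human", n_beats = 40, seed = 3))
  iv <- average_intervals(delineate_ecg(highpass_baseline(sim$record, 0.5)))
  expect_lt(abs(iv$PR_ms - mean(sim$truth$pr_ms)), 3)
  expect_lt(abs(iv$QRS_ms - mean(sim$truth$qrs_ms)), 3)
  expect_lt(abs(iv$QT_ms - mean(sim$truth$qt_ms)), 3)
})

test_that("delineated RR tracks heart rate across the mouse regime", {
  for (hr in c(300, 500, 700)) {
    sim <- gen_ecg(ecg_spec("mouse", hr_bpm = hr, n_beats = 25, seed = hr))
    iv <- average_intervals(delineate_ecg(highpass_baseline(sim$record, 0.5)))
    expect_lt(abs(iv$RR_ms - 60000 / hr) / (60000 / hr), 0.01)
  }
})

test_that("interval averaging is a per-fiducial mean and order invariant", {
  beats <- data.frame(
    p_onset_ms = c(10, 130, NA), r_peak_ms = c(50, 170, 290),
    q_onset_ms = c(45, 165, 285), s_end_ms = c(55, 175, 295),
    t_peak_ms = c(70, 190, 310), t_end90_ms = c(89, 211, 330),
    iso_mV = 0, iso_t_mV = 0, t_peak_mV = 0.25)
  iv <- average_intervals(beats)
  expect_equal(iv$QT_ms, mean(c(44, 46, 45)))
  expect_equal(iv$PR_ms, 40) # beat 3 has no P: averaged over two beats
  expect_identical(unname(iv$n_beats_averaged["PR"]), 2L)
  expect_identical(unname(iv$n_beats_averaged["QT"]), 3L)
  perm <- average_intervals(beats[c(3, 1, 2), ])
  expect_equal(iv[c("PR_ms", "QRS_ms", "QT_ms", "RR_ms")],
               perm[c("PR_ms", "QRS_ms", "QT_ms", "RR_ms")])
  # single beat: intervals equal that beat's values
  one <- average_intervals(beats[1, ])
  expect_equal(one$QT_ms, 44)
  expect_true(is.na(one$RR_ms))
  expect_error(average_intervals(beats[0, ]), "no delineated beats")
})

test_that("T-wave metrics recover programmed amplitude and obey the rectangle rule", {
  sim <- gen_ecg(ecg_spec("mouse", n_beats = 20, seed = 5))
  rec <- highpass_baseline(sim$record, 0.5)
  beats <- delineate_ecg(rec)
  tw <- t_wave_metrics(rec, beats)
  expect_equal(tw$n_area, 5)
  expect_false(tw$flagged)
  # programmed T amplitude 0.25 mV
  expect_equal(tw$amplitude_mV, 0.25, tolerance = 0.05)

  # rectangular T of height h and width w has area ~ h*w
  fs <- 10000
  t <- seq(0, 120, by = 1000 / fs)
  v <- numeric(length(t))
  beat <- data.frame(p_onset_ms = 5, r_peak_ms = 30, q_onset_ms = 25,
                     s_end_ms = 40, t_peak_ms = 55, t_end90_ms = 70,
                     iso_mV = 0, iso_t_mV = 0, t_peak_mV = 0.2)
  v[t >= 40 & t <= 70] <- 0.2
  rect <- ecg_record(v, fs, species_hint = "mouse")
  tw2 <- t_wave_metrics(rect, beat)
  expect_true(tw2$flagged) # fewer than 5 T waves available
  expect_equal(tw2$area_mV_ms, 0.2 * 30, tolerance = 0.01 * 0.2 * 30)

  # zero-amplitude T
  beat$t_peak_mV <- 0
  zero <- ecg_record(numeric(length(t)) , fs, species_hint = "mouse")
  tw3 <- t_wave_metrics(zero, beat)
  expect_equal(tw3$amplitude_mV, 0)
  expect_equal(tw3$area_mV_ms, 0)
})

test_that("ECG text round trip preserves samples and metadata", {
  sim <- gen_ecg(ecg_spec("mouse", n_beats = 3, seed = 1))
  f <- tempfile(fileext = ".txt")
  write_ecg(sim$record, f)
  back <- read_ecg(f)
  expect_equal(back$sampling_rate, sim$record$sampling_rate)
  expect_equal(back$species_hint, "mouse")
  expect_equal(back$samples, sim$record$samples, tolerance = 1e-6)
})
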