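test_that("R-peak detection recovers ground truth on clean and fast rhythms", {
  e <- synth_ecg(60, hr_bpm = 60, noise_sd = 0, seed = 1)
  pk <- detect_r_peaks(e$signal)
  # recall and precision 1.0 within +/-2 samples
  expect_equal(length(pk), nrow(e$truth))
  expect_lte(max(abs(pk - e$truth$index)), 2)

  flat <- sampled_signal(numeric(250 * 10), 250)
  expect_equal(length(detect_r_peaks(flat)), 0L)

  fast <- synth_ecg(60, hr_bpm = 180, noise_sd = 0, seed = 2)
  pkf <- detect_r_peaks(fast$signal)
  expect_equal(mean(diff(pkf)) / 250 * 1000, 1000 / 3,
               tolerance = 1000 / 250)
  expect_error(detect_r_peaks(sampled_signal(rnorm(100), 250)),
               "insufficient")
  expect_error(detect_r_peaks(sampled_signal(rnorm(100), 50)), "100 Hz")
})

test_that("heart rate is the reciprocal mean interval", {
  expect_equal(heart_rate(seq(1, 2501, by = 250), 250), 60)
  expect_equal(heart_rate(seq(1, 1251, by = 125), 250), 120)
  e <- synth_ecg(60, hr_bpm = 72, noise_sd = 0.02, seed = 3)
  expect_equal(heart_rate(detect_r_peaks(e$signal), 250), 72, tolerance = 0.5)
  expect_error(heart_rate(c(10), 250), "insufficient")
})

test_that("SDNN matches hand-computed interval statistics", {
  # perfectly periodic
  expect_equal(hrv_sdnn(seq(1, 2501, by = 250), 250), 0)
  # intervals {800, 900, 1000} ms -> sample SD 100 ms
  peaks_ms <- cumsum(c(0, 800, 900, 1000))
  expect_equal(hrv_sdnn(peaks_ms / 1000 * 250 + 1, 250), 100)
  expect_error(hrv_sdnn(c(1, 251), 250), "insufficient")
  # jittered train with known interval SD, 300 beats
  e <- synth_ecg(300, hr_bpm = 60, rr_jitter_sd_ms = 40, noise_sd = 0,
                 seed = 8)
  truth_sd <- stats::sd(diff(e$truth$time_s) * 1000)
  est <- hrv_sdnn(detect_r_peaks(e$signal), 250)
  expect_lt(abs(est - truth_sd) / truth_sd, 0.1)
})

test_that("heart rate and SDNN are invariant to time shift and amplitude scale", {
  e <- synth_ecg(120, hr_bpm = 65, rr_jitter_sd_ms = 25, noise_sd = 0.01,
                 seed = 5)
  base <- e$signal
  scaled <- sampled_signal(base$samples * 7.3, base$rate_hz,
                           base$start_time_s + 55, "ECG", "mV")
  pk1 <- detect_r_peaks(base); pk2 <- detect_r_peaks(scaled)
  expect_equal(heart_rate(pk1, 250), heart_rate(pk2, 250))
  expect_equal(hrv_sdnn(pk1, 250), hrv_sdnn(pk2, 250))
})

test_that("ECG-derived respiration recovers the modulation frequency", {
  for (resp in c(10, 15, 20, 25)) {
    e <- synth_ecg(90, hr_bpm = 75, resp_rate_bpm = resp,
                   r_amp_mod_depth = 0.15, noise_sd = 0.01, seed = resp)
    pk <- detect_r_peaks(e$signal)
    out <- respiration_rate(e$signal, pk)
    expect_lt(abs(out$resp_rate_bpm - resp), 1)
  }
  # no modulation -> missing with a reason
  e0 <- synth_ecg(90, hr_bpm = 75, r_amp_mod_depth = 0, noise_sd = 0,
                  seed = 1)
  out0 <- respiration_rate(e0$signal, detect_r_peaks(e0$signal))
  expect_true(is.na(out0$resp_rate_bpm))
  expect_match(out0$reason, "modulation")
  # monotone in the truth
  e12 <- synth_ecg(90, 75, 12, 0.2, seed = 2)
  e24 <- synth_ecg(90, 75, 24, 0.2, seed = 2)
  r12 <- respiration_rate(e12$signal, detect_r_peaks(e12$signal))$resp_rate_bpm
  r24 <- respiration_rate(e24$signal, detect_r_peaks(e24$signal))$resp_rate_bpm
  expect_lt(r12, r24)
  expect_error(respiration_rate(synth_ecg(10, 75, seed = 1)$signal, 1:12),
               "30 s")
})

test_that("oximetry follows the calibration line and rejects bad signals", {
  p8 <- synth_dual_ppg(0.8, 30, noise_sd = 0)
  expect_equal(spo2(p8$red, p8$ir)$spo2_pct, 90, tolerance = 1e-6)
  p4 <- synth_dual_ppg(0.4, 30, noise_sd = 0)
  expect_equal(spo2(p4$red, p4$ir)$spo2_pct, 100, tolerance = 1e-6)
  # strictly decreasing in R before clipping
  r_grid <- c(0.5, 0.8, 1.1, 1.4)
  vals <- vapply(r_grid, function(r) {
    p <- synth_dual_ppg(r, 20, noise_sd = 0)
    spo2(p$red, p$ir)$spo2_pct
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # zero-AC channels are invalid
  flat <- sampled_signal(rep(5, 500), 50, label = "PPG_RED")
  expect_error(spo2(flat, flat), "invalid signal")
})

test_that("SNR follows its closed form and is scale-invariant", {
  expect_equal(snr_db(rep(2, 100), rep(2, 100)), 0)
  expect_equal(snr_db(rep(10, 50), rep(1, 50)), 20)
  x <- rnorm(1000); n <- rnorm(1000)
  expect_equal(snr_db(3.7 * x, 3.7 * n), snr_db(x, n), tolerance = 1e-12)
  # constructed ECG + noise matches the closed-form expectation
  e <- synth_ecg(60, 70, noise_sd = 0, seed = 6)
  noise <- withr::with_seed(1, rnorm(length(e$signal$samples), 0, 0.05))
  expected <- 20 * log10(sqrt(mean(e$signal$samples^2)) /
                           sqrt(mean(noise^2)))
  expect_equal(snr_db(e$signal$samples, noise), expected, tolerance = 0.5)
  expect_error(snr_db(rnorm(10), numeric(0)), "length")
  expect_error(snr_db(rnorm(10), rep(0, 10)), "undefined SNR")
})

test_that("quality gating passes clean signals and names failing indices", {
  p <- synth_dual_ppg(0.8, 30, noise_sd = 0.05, seed = 2)
  q <- quality_gate(p$ir, "ppg")
  expect_true(q$pass)
  noise <- sampled_signal(rnorm(30 * 50), 50, label = "PPG_IR")
  qn <- quality_gate(noise, "ppg")
  expect_false(qn$pass)
  expect_false(is.na(qn$reason))
  cst <- sampled_signal(rep(4, 30 * 50), 50, label = "PPG_IR")
  qc <- quality_gate(cst, "ppg")
  expect_false(qc$pass)
  expect_equal(unname(qc$sqi_values["perfusion_pct"]), 0)
  e <- synth_ecg(30, 70, noise_sd = 0.01, seed = 4)
  expect_true(quality_gate(e$signal, "ecg")$pass)
})

test_that("Bland-Altman agreement matches the direct formula", {
  a <- c(1, 2, 3, 4)
  expect_equal(unlist(bland_altman(a, a)[1, 1:3]),
               c(bias = 0, loa_lower = 0, loa_upper = 0))
  ba <- bland_altman(a + 2, a)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_lower, 2)
  expect_equal(ba$loa_upper, 2)
  set.seed(31)
  x <- rnorm(200, 100, 10); y <- x + rnorm(200, 1, 2)
  ba2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba2$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "pairing")
})

test_that("windowed session vitals recover the generator panel", {
  rec <- withr::with_seed(1, {
    ecg <- synth_ecg(60, hr_bpm = 70, resp_rate_bpm = 15,
                     r_amp_mod_depth = 0.15, noise_sd = 0.01, seed = 2)
    ppg <- synth_dual_ppg(0.6, 60, hr_bpm = 70, noise_sd = 0.02, seed = 3)
    temp <- sampled_signal(rep(36.6, 60), 1, 0, "TEMP", "degC")
    session_record(list(ecg$signal, ppg$red, ppg$ir, temp), "S1", "low")
  })
  v <- session_vitals(rec, window_s = 30, stride_s = 15)
  expect_gte(nrow(v), 2)
  expect_equal(v$hr_bpm, rep(70, nrow(v)), tolerance = 1)
  expect_equal(v$hr_ppg_bpm, rep(70, nrow(v)), tolerance = 2)
  expect_equal(v$spo2_pct, rep(110 - 25 * 0.6, nrow(v)), tolerance = 1)
  expect_equal(v$temp_c, rep(36.6, nrow(v)))
  expect_equal(v$resp_rate_bpm, rep(15, nrow(v)), tolerance = 1)
})
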