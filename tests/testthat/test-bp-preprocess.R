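test_that("the PPG bandpass keeps the passband and kills out-of-band energy", {
  fs <- 125
  # frequency-response oracle via FFT of the filtered impulse
  imp <- sampled_signal(c(rep(0, 2000), 1, rep(0, 2000)), fs)
  h <- bandpass_ppg(imp)$samples
  n <- length(h)
  gain <- Mod(stats::fft(h))
  freq <- (seq_len(n) - 1) * fs / n
  g_at <- function(f) gain[which.min(abs(freq - f))]
  expect_lt(20 * log10(g_at(0.1)), -40)          # >= 40 dB rejection
  expect_gt(20 * log10(g_at(3)), -0.5)           # <= 0.5 dB ripple at 3 Hz
  expect_lt(20 * log10(g_at(0.05)), -60)

  # sinusoid checks through the actual filter path
  t <- (0:(40 * fs - 1)) / fs
  slow <- sampled_signal(sin(2 * pi * 0.1 * t), fs)
  out <- bandpass_ppg(slow)$samples
  mid <- seq(10 * fs, 30 * fs)
  expect_lt(sqrt(mean(out[mid]^2)) / sqrt(0.5), 0.01)
  inband <- sampled_signal(sin(2 * pi * 3 * t), fs)
  out3 <- bandpass_ppg(inband)$samples
  expect_equal(sqrt(mean(out3[mid]^2)) / sqrt(0.5), 1, tolerance = 0.05)
  # DC-only input decays to zero once the 0.8-Hz high-pass transient has
  # died away (a few seconds at the band edge)
  dc <- sampled_signal(rep(2, 40 * fs), fs)
  expect_lt(max(abs(bandpass_ppg(dc)$samples[(15 * fs):(25 * fs)])), 1e-6)
  expect_error(bandpass_ppg(sampled_signal(rnorm(100), 12)), "rate")
})

test_that("non-overlapping segmentation tiles the record and drops remainders", {
  fs <- 125
  seg95 <- segment_nonoverlap(sampled_signal(rnorm(95 * fs), fs))
  expect_equal(nrow(seg95), 9)
  expect_equal(nrow(segment_nonoverlap(sampled_signal(rnorm(10 * fs), fs))), 1)
  expect_equal(nrow(segment_nonoverlap(
    sampled_signal(rnorm(round(9.99 * fs)), fs))), 0)
  # exact lengths, contiguous disjoint prefix
  lens <- vapply(seg95$samples, length, integer(1))
  expect_true(all(lens == round(10 * fs)))
  expect_equal(seg95$start_index, (0:8) * 1250 + 1)
})

test_that("the SD-interquartile filter matches direct quartile computation", {
  # worked example: SDs 1..8 -> Q1 = 2.75, Q3 = 6.25 -> keep {3,4,5,6}
  segs <- tibble::tibble(
    segment_id = 1:8, start_index = 1, rate_hz = 125,
    sd = as.numeric(1:8),
    samples = replicate(8, numeric(0), simplify = FALSE)
  )
  kept <- sd_iqr_filter(segs)
  expect_equal(kept$sd, c(3, 4, 5, 6))
  expect_equal(attr(kept, "n_rejected_iqr"), 4L)
  # all-equal SDs are all retained
  segs$sd <- rep(2, 8)
  expect_equal(nrow(sd_iqr_filter(segs)), 8)
  # fewer than 4 segments: everything rejected, with a warning
  expect_warning(out <- sd_iqr_filter(segs[1:3, ]), "fewer than 4")
  expect_equal(nrow(out), 0)
})

test_that("IQR retention stays between 25% and 75% and output is a subset", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(8:60, 1))
    sds <- withr::with_seed(seed + 100, runif(n, 0.5, 5))
    segs <- tibble::tibble(segment_id = seq_len(n), start_index = 1,
                           rate_hz = 125, sd = sds,
                           samples = replicate(n, numeric(0),
                                               simplify = FALSE))
    kept <- sd_iqr_filter(segs)
    expect_gte(nrow(kept), floor(0.25 * n))
    expect_lte(nrow(kept), ceiling(0.75 * n))
    expect_true(all(kept$segment_id %in% segs$segment_id))
  }
})

test_that("ABP peak finding reports systolic and diastolic landmarks", {
  abp <- make_abp(120, 80, hr_bpm = 75, duration_s = 10)
  pk <- abp_peaks(abp)
  expect_equal(unname(abp$samples[pk$systolic]),
               rep(120, length(pk$systolic)), tolerance = 0.5)
  expect_equal(unname(abp$samples[pk$diastolic]),
               rep(80, length(pk$diastolic)), tolerance = 0.5)
  # ~12.5 beats in 10 s at 75 bpm
  expect_true(abs(length(pk$systolic) - 12) <= 1)
  ramp <- sampled_signal(seq(0, 100, length.out = 500), 125)
  pr <- abp_peaks(ramp)
  expect_equal(length(pr$systolic), 0)
  expect_equal(length(pr$diastolic), 0)
  # noisy ABP at ~20 dB SNR still yields the right beat count
  noisy <- abp
  noisy$samples <- noisy$samples +
    withr::with_seed(2, rnorm(length(abp$samples), 0, 1.5))
  pn <- abp_peaks(noisy)
  expect_lte(abs(length(pn$systolic) - length(pk$systolic)), 1)
  expect_error(abp_peaks(make_abp(120, 80, duration_s = 1)), "2 s")
})

test_that("segment labelling averages peaks and rejects any excursion", {
  lab <- label_segment(make_abp(120, 80))
  expect_true(lab$accepted)
  expect_equal(lab$sbp, 120, tolerance = 0.5)
  expect_equal(lab$dbp, 80, tolerance = 0.5)

  # one systolic excursion to 190 among valid beats rejects the segment
  abp <- make_abp(120, 80)
  pk <- abp_peaks(abp)
  i <- pk$systolic[3]
  abp$samples[(i - 2):(i + 2)] <- abp$samples[(i - 2):(i + 2)] + 70
  rej <- label_segment(abp)
  expect_false(rej$accepted)
  expect_match(rej$reason, "systolic")

  # flat segment: no peaks
  flat <- sampled_signal(rep(100, 1250), 125, label = "ABP")
  nop <- label_segment(flat)
  expect_false(nop$accepted)
  expect_match(nop$reason, "no peaks")

  # amplitude-offset equivariance (checked inside the bounds window)
  base <- make_abp(110, 75)
  shifted <- sampled_signal(base$samples + 10, 125, label = "ABP")
  l0 <- label_segment(base); l1 <- label_segment(shifted)
  expect_equal(l1$sbp - l0$sbp, 10, tolerance = 1e-6)
  expect_equal(l1$dbp - l0$dbp, 10, tolerance = 1e-6)
  # time-shift invariance
  rolled <- sampled_signal(c(base$samples[-(1:40)], base$samples[1:40]),
                           125, label = "ABP")
  lr <- label_segment(rolled)
  expect_equal(lr$sbp, l0$sbp, tolerance = 0.5)
})

test_that("dataset assembly composes the stages and keeps exact counts", {
  pairs <- synth_coupled_ppg_abp(60, noise_sd = 0, seed = 7)
  pairs$record_id <- "synth"
  ds <- build_bp_dataset(pairs)
  rej <- attr(ds, "rejections")
  n_iqr <- sum(rej$n[rej$reason == "sd outside IQR"])
  # only the IQR filter rejects noiseless in-bounds segments, keeping ~50%
  expect_equal(sum(rej$n), n_iqr)
  expect_equal(nrow(ds) + sum(rej$n), attr(ds, "n_input_segments"))
  expect_gte(nrow(ds), 0.25 * 60)
  expect_lte(nrow(ds), 0.75 * 60)
  # labels near the generator truth for retained segments
  truth <- pairs$sbp[ds$segment_id]
  expect_lt(max(abs(ds$sbp - truth)), 1)

  # constant out-of-bounds ABP: everything rejected at the label stage
  bad <- tibble::tibble(
    record_id = "bad",
    ppg = pairs$ppg[1:6],
    abp = lapply(1:6, function(i) {
      s <- pairs$abp[[i]]
      sampled_signal(s$samples - s$samples + 200 +
                       20 * ppg_pulse_waveform(signal_times(s), 1.25),
                     s$rate_hz, 0, "ABP", "mmHg")
    })
  )
  ds_bad <- build_bp_dataset(bad)
  expect_equal(nrow(ds_bad), 0)

  # empty input
  ds0 <- build_bp_dataset(tibble::tibble(ppg = list(), abp = list()))
  expect_equal(nrow(ds0), 0)

  # misaligned pair
  broken <- pairs[1:2, ]
  broken$abp[[1]] <- sampled_signal(broken$abp[[1]]$samples[-1], 125,
                                    label = "ABP")
  expect_error(build_bp_dataset(broken), "pairing error")
})
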