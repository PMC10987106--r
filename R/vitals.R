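#' Detect R peaks in an ECG signal
#'
#' Energy-based QRS detector in the Pan-Tompkins tradition: zero-phase
#' bandpass (5-25 Hz) to isolate QRS energy, derivative, squaring and a
#' 150-ms moving-window integration, followed by an adaptive threshold and
#' a 200-ms refractory period. Candidate fiducials are refined to the
#' local extremum of the raw ECG within +/-60 ms so returned indices land
#' on the R wave itself.
#'
#' @param ecg A [sampled_signal()]; rate >= 100 Hz, length >= 2 s.
#' @param threshold_frac Fraction of the upper envelope of the integrated
#'   energy used as detection threshold.
#' @return Integer vector of strictly increasing 1-based sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.35) {
  stopifnot(inherits(ecg, "sampled_signal"))
  fs <- ecg$rate_hz
  if (fs < 100) stop("ECG rate must be >= 100 Hz", call. = FALSE)
  x <- ecg$samples
  if (length(x) < 2 * fs) {
    stop("insufficient data: need >= 2 s of ECG", call. = FALSE)
  }
  x[is.na(x)] <- 0
  bp <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  energy <- c(0, diff(xf))^2
  win <- max(1L, round(0.15 * fs))
  integ <- stats::filter(energy, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- threshold_frac * stats::quantile(integ, 0.995, names = FALSE)
  if (thr <= 0 || !is.finite(thr)) return(integer(0))
  refractory <- round(0.2 * fs)
  above <- integ > thr
  # rising edges of the supra-threshold regions
  starts <- which(above & !c(FALSE, above[-length(above)]))
  peaks <- integer(0)
  last <- -Inf
  search <- round(0.06 * fs)
  for (s in starts) {
    e <- s
    while (e < length(above) && above[e + 1]) e <- e + 1
    cand <- s - 1 + which.max(integ[s:e])
    lo <- max(1L, cand - search); hi <- min(length(x), cand + search)
    r <- lo - 1L + which.max(abs(x[lo:hi]))
    if (r - last >= refractory) {
      peaks <- c(peaks, r)
      last <- r
    }
  }
  unique(peaks)
}

#' Heart rate from R-peak indices
#'
#' `60 / mean(inter-peak interval)` in seconds.
#'
#' @param peaks Strictly increasing sample indices (>= 2).
#' @param rate_hz Sampling rate of the source signal.
#' @return Heart rate in beats/min.
#' @export
heart_rate <- function(peaks, rate_hz) {
  if (length(peaks) < 2) {
    stop("insufficient data: heart rate needs >= 2 peaks", call. = FALSE)
  }
  60 / mean(diff(peaks) / rate_hz)
}

#' Heart-rate variability as SDNN
#'
#' Sample standard deviation (n-1 denominator) of successive inter-peak
#' intervals, in milliseconds. No ectopic-beat rejection is applied; with
#' short windows a single mis-detected beat inflates the estimate, which
#' is why this statistic is always paired with the quality gate in
#' session-level summaries.
#'
#' @inheritParams heart_rate
#' @return SDNN in milliseconds.
#' @export
hrv_sdnn <- function(peaks, rate_hz) {
  if (length(peaks) < 3) {
    stop("insufficient data: SDNN needs >= 3 peaks", call. = FALSE)
  }
  stats::sd(diff(peaks) / rate_hz * 1000)
}

#' Respiration rate from R-peak amplitude modulation
#'
#' ECG-derived respiration: the R-peak amplitude series is interpolated to
#' a uniform 4-Hz grid (cubic spline), detrended, and the dominant
#' spectral peak within the physiological band 0.1-0.7 Hz is reported in
#' breaths/min (with parabolic interpolation around the FFT bin). When the
#' amplitude series carries no modulation, or no spectral peak stands
#' above the in-band noise floor, the result is missing with a reason.
#'
#' @param ecg A [sampled_signal()] covering >= 30 s.
#' @param peaks R-peak indices from [detect_r_peaks()] (>= 10).
#' @param band Frequency band searched, Hz.
#' @param min_peak_ratio Required ratio of dominant-bin power to mean
#'   in-band power.
#' @return List with `resp_rate_bpm` (numeric or `NA`) and `reason`
#'   (`NA` when a rate is returned).
#' @export
respiration_rate <- function(ecg, peaks, band = c(0.1, 0.7),
                             min_peak_ratio = 5) {
  stopifnot(inherits(ecg, "sampled_signal"))
  if (signal_duration(ecg) < 30) {
    stop("insufficient data: need >= 30 s of ECG", call. = FALSE)
  }
  if (length(peaks) < 10) {
    stop("insufficient data: need >= 10 R peaks", call. = FALSE)
  }
  amp <- ecg$samples[peaks]
  t <- (peaks - 1) / ecg$rate_hz
  if (stats::sd(amp) < 1e-4 * max(abs(mean(amp)), 1e-12)) {
    return(list(resp_rate_bpm = NA_real_, reason = "no amplitude modulation"))
  }
  fs_i <- 4
  tg <- seq(t[1], t[length(t)], by = 1 / fs_i)
  a <- stats::spline(t, amp, xout = tg)$y
  a <- stats::resid(stats::lm(a ~ tg))      # detrend (linear)
  nfft <- 2^ceiling(log2(max(4096, length(a))))
  spec <- Mod(stats::fft(c(a, numeric(nfft - length(a)))))^2
  freq <- (seq_len(nfft) - 1) * fs_i / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  p <- spec[in_band]; f <- freq[in_band]
  i <- which.max(p)
  if (p[i] < min_peak_ratio * mean(p)) {
    return(list(resp_rate_bpm = NA_real_, reason = "no spectral peak above noise floor"))
  }
  # parabolic interpolation of the peak position
  f_hat <- f[i]
  if (i > 1 && i < length(p)) {
    d <- 0.5 * (p[i - 1] - p[i + 1]) / (p[i - 1] - 2 * p[i] + p[i + 1])
    f_hat <- f[i] + d * (f[2] - f[1])
  }
  list(resp_rate_bpm = unname(60 * f_hat), reason = NA_character_)
}

#' Oxygen saturation from dual-wavelength PPG
#'
#' Ratio-of-ratios pulse oximetry: within the analysis window, each
#' channel's DC level is the window mean and its AC level the RMS of the
#' 0.8-8 Hz band (band-limited RMS is used instead of peak-to-peak for
#' robustness to noise). Then
#' `R = (AC_red/DC_red) / (AC_ir/DC_ir)` and `SpO2 = 110 - 25 R`, clipped
#' to `[70, 100]`. The linear calibration is the widely used empirical
#' line for reflectance oximeters and is exposed as configuration; a
#' device-specific calibration should replace it in production.
#'
#' @param red,ir Red and infrared [sampled_signal()] channels at equal
#'   rates covering >= 4 s.
#' @param cal Calibration line `c(intercept, slope)` for
#'   `SpO2 = intercept + slope * R`.
#' @return List with `spo2_pct` and the measured `r_ratio`.
#' @export
spo2 <- function(red, ir, cal = c(110, -25)) {
  stopifnot(inherits(red, "sampled_signal"), inherits(ir, "sampled_signal"))
  if (red$rate_hz != ir$rate_hz) stop("channels must share one rate", call. = FALSE)
  if (signal_duration(red) < 4 || signal_duration(ir) < 4) {
    stop("insufficient data: need >= 4 s of PPG", call. = FALSE)
  }
  acdc <- function(s) {
    x <- s$samples[!is.na(s$samples)]
    dc <- mean(x)
    if (dc <= 0) stop("invalid signal: nonpositive DC level", call. = FALSE)
    bp <- signal::butter(4, c(0.8, 8) / (s$rate_hz / 2), type = "pass")
    ac <- sqrt(mean(signal::filtfilt(bp, x - dc)^2))
    c(ac = ac, dc = dc)
  }
  r_ch <- acdc(red); i_ch <- acdc(ir)
  if (r_ch["ac"] == 0 || i_ch["ac"] == 0) {
    stop("invalid signal: no pulsatile component", call. = FALSE)
  }
  r <- (r_ch[["ac"]] / r_ch[["dc"]]) / (i_ch[["ac"]] / i_ch[["dc"]])
  list(spo2_pct = min(100, max(70, cal[1] + cal[2] * r)), r_ratio = r)
}

#' Signal-to-noise ratio in decibels
#'
#' `20 * log10(RMS(signal) / RMS(noise))`.
#'
#' @param signal_est,noise_est Numeric vectors holding the signal and
#'   noise estimates (nonempty; noise RMS > 0).
#' @return SNR in dB.
#' @export
snr_db <- function(signal_est, noise_est) {
  stopifnot(length(signal_est) > 0, length(noise_est) > 0)
  rms <- function(v) sqrt(mean(v^2))
  rn <- rms(noise_est)
  if (rn == 0) stop("undefined SNR: noise RMS is zero", call. = FALSE)
  20 * log10(rms(signal_est) / rn)
}

#' Signal-quality gating
#'
#' Computes the signal-quality indices used to prompt users to correct
#' device placement: sample skewness (pathological for saturated or
#' artifact-dominated windows), perfusion index (PPG only: AC amplitude as
#' a percentage of DC), and a beat-template correlation (mean correlation
#' of individual beats against their average). The window passes only if
#' every applicable index is within its configured bounds; the report
#' names the first failing index.
#'
#' @param segment A [sampled_signal()] covering >= 5 s.
#' @param kind `"ecg"` or `"ppg"`.
#' @param bounds Named list of bounds: `skewness` (c(lo, hi)),
#'   `perfusion_min` (%), `template_corr_min`. Defaults depend on `kind`:
#'   the spiky QRS morphology makes healthy ECG strongly right-skewed, so
#'   its skewness window is much wider than the PPG one.
#' @return List of class `quality_report`: `sqi_values` (named numeric),
#'   `pass`, `reason`.
#' @export
quality_gate <- function(segment, kind = c("ppg", "ecg"), bounds = NULL) {
  kind <- match.arg(kind)
  if (is.null(bounds)) {
    bounds <- list(skewness = if (kind == "ecg") c(-12, 12) else c(-3, 3),
                   perfusion_min = 0.2,
                   template_corr_min = 0.7)
  }
  stopifnot(inherits(segment, "sampled_signal"))
  if (signal_duration(segment) < 5) {
    stop("insufficient data: need >= 5 s", call. = FALSE)
  }
  x <- segment$samples
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  fs <- segment$rate_hz
  m <- mean(x); s <- stats::sd(x)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  sqi <- c(skewness = skew)
  pass <- TRUE; reason <- NA_character_
  if (skew < bounds$skewness[1] || skew > bounds$skewness[2]) {
    pass <- FALSE; reason <- "skewness out of bounds"
  }
  if (kind == "ppg") {
    dc <- abs(m)
    bp <- signal::butter(4, c(0.8, min(8, 0.45 * fs)) / (fs / 2), type = "pass")
    ac <- sqrt(mean(signal::filtfilt(bp, x - m)^2))
    perf <- if (dc > 0) 100 * ac / dc else 0
    sqi <- c(sqi, perfusion_pct = perf)
    if (pass && perf < bounds$perfusion_min) {
      pass <- FALSE; reason <- "perfusion index below bound"
    }
  }
  tc <- beat_template_correlation(x, fs, kind)
  sqi <- c(sqi, template_corr = tc)
  if (pass && (is.na(tc) || tc < bounds$template_corr_min)) {
    pass <- FALSE; reason <- "beat-template correlation below bound"
  }
  structure(list(sqi_values = sqi, pass = pass, reason = reason),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>", if (x$pass) "PASS" else paste0("FAIL (", x$reason, ")"), "\n")
  print(round(x$sqi_values, 4))
  invisible(x)
}

# Pulse-peak finder for PPG-class signals: zero-phase 0.8-8 Hz bandpass,
# local maxima above an adaptive threshold, 300-ms refractory period.
ppg_peaks <- function(ppg) {
  stopifnot(inherits(ppg, "sampled_signal"))
  fs <- ppg$rate_hz
  x <- ppg$samples
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  bp <- signal::butter(4, c(0.8, min(8, 0.45 * fs)) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))
  thr <- 0.3 * stats::quantile(xf, 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  n <- length(xf)
  is_max <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] & xf[2:(n - 1)] >= xf[3:n], FALSE)
  cand <- which(is_max & xf > thr)
  refractory <- round(0.3 * fs)
  peaks <- integer(0); last <- -Inf
  for (p in cand) {
    if (p - last >= refractory) { peaks <- c(peaks, p); last <- p }
  }
  peaks
}

# Mean correlation of candidate beats against their ensemble average.
beat_template_correlation <- function(x, fs, kind) {
  sig <- sampled_signal(x, fs, label = "tmp")
  pk <- tryCatch(
    if (kind == "ecg") detect_r_peaks(sig) else ppg_peaks(sig),
    error = function(e) integer(0))
  if (length(pk) < 4) return(NA_real_)
  half <- round(0.3 * fs)
  ok <- pk - half >= 1 & pk + half <= length(x)
  pk <- pk[ok]
  if (length(pk) < 4) return(NA_real_)
  beats <- vapply(pk, function(p) x[(p - half):(p + half)], numeric(2 * half + 1))
  tmpl <- rowMeans(beats)
  if (stats::sd(tmpl) == 0) return(NA_real_)
  cors <- apply(beats, 2, function(b) {
    if (stats::sd(b) == 0) return(0)
    stats::cor(b, tmpl)
  })
  mean(cors)
}

#' Bland-Altman agreement statistics
#'
#' Bias and 95% limits of agreement for paired measurements:
#' `bias = mean(a - b)`, `LoA = bias +/- 1.96 * SD(a - b)`.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return Tibble with `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("pairing error: series lengths differ", call. = FALSE)
  }
  stopifnot(length(a) >= 2)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  tibble::tibble(bias = bias,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 sd_diff = s, n = length(d))
}

#' Windowed vital signs for a session
#'
#' Slides an analysis window across a session and derives the full vitals
#' panel per window: ECG heart rate, SDNN, respiration rate; PPG SpO2 and
#' a second heart-rate estimate; mean skin temperature; plus quality-gate
#' outcomes. Windows are half-open `[t0, t1)` on the clock-corrected
#' timeline.
#'
#' @param record A [session_record()].
#' @param window_s Window length in seconds (default 30).
#' @param stride_s Stride between window starts (default 10).
#' @return Tibble with one row per window.
#' @export
session_vitals <- function(record, window_s = 30, stride_s = 10) {
  stopifnot(inherits(record, "session_record"))
  chans <- lapply(record$channels, apply_clock_offset,
                  offset_s = record$clock_offset_s)
  t0s <- vapply(chans, `[[`, numeric(1), "start_time_s")
  t1s <- t0s + vapply(chans, signal_duration, numeric(1))
  lo <- max(t0s); hi <- min(t1s)
  if (hi - lo < window_s) {
    stop("insufficient data: no full window available", call. = FALSE)
  }
  starts <- seq(lo, hi - window_s, by = stride_s)
  crop <- function(sig, a, b) {
    i0 <- ceiling((a - sig$start_time_s) * sig$rate_hz - 1e-9)
    i1 <- ceiling((b - sig$start_time_s) * sig$rate_hz - 1e-9) - 1
    sampled_signal(sig$samples[(i0:i1) + 1], sig$rate_hz,
                   sig$start_time_s + i0 / sig$rate_hz, sig$label, sig$units)
  }
  purrr::map_dfr(starts, function(a) {
    b <- a + window_s
    out <- tibble::tibble(t0_s = a, t1_s = b,
                          hr_bpm = NA_real_, hrv_sdnn_ms = NA_real_,
                          resp_rate_bpm = NA_real_, hr_ppg_bpm = NA_real_,
                          spo2_pct = NA_real_, temp_c = NA_real_,
                          ecg_quality = NA, ppg_quality = NA)
    if (!is.null(chans$ECG)) {
      ecg <- crop(chans$ECG, a, b)
      q <- quality_gate(ecg, "ecg")
      out$ecg_quality <- q$pass
      pk <- tryCatch(detect_r_peaks(ecg), error = function(e) integer(0))
      if (length(pk) >= 2) out$hr_bpm <- heart_rate(pk, ecg$rate_hz)
      if (length(pk) >= 3) out$hrv_sdnn_ms <- hrv_sdnn(pk, ecg$rate_hz)
      if (window_s >= 30 && length(pk) >= 10) {
        out$resp_rate_bpm <- respiration_rate(ecg, pk)$resp_rate_bpm
      }
    }
    if (!is.null(chans$PPG_RED) && !is.null(chans$PPG_IR)) {
      red <- crop(chans$PPG_RED, a, b); ir <- crop(chans$PPG_IR, a, b)
      q <- quality_gate(ir, "ppg")
      out$ppg_quality <- q$pass
      out$spo2_pct <- tryCatch(spo2(red, ir)$spo2_pct, error = function(e) NA_real_)
      pk <- ppg_peaks(ir)
      if (length(pk) >= 2) out$hr_ppg_bpm <- heart_rate(pk, ir$rate_hz)
    }
    if (!is.null(chans$TEMP)) {
      out$temp_c <- mean(crop(chans$TEMP, a, b)$samples, na.rm = TRUE)
    }
    out
  })
}
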