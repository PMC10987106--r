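#' Synthetic ECG with respiratory amplitude modulation
#'
#' Generates a Gaussian-template QRS train at a fixed heart rate whose
#' R-peak amplitudes are modulated by respiration,
#' `a_i = 1 + depth * sin(2 * pi * f_resp * t_i)`, plus additive white
#' Gaussian noise. This emulates the respiratory amplitude modulation of
#' sternal ECG from which respiration rate is derived, and carries its own
#' ground truth for parameter-recovery tests.
#'
#' Optional beat-interval jitter (`rr_jitter_sd_ms`) perturbs successive
#' R-R intervals with zero-mean Gaussian noise so that heart-rate
#' variability estimators can be validated against a known interval SD.
#'
#' All generators in the package are pure functions of their arguments:
#' the same spec and seed give bit-identical output.
#'
#' @param duration_s Signal duration, seconds (> 0).
#' @param hr_bpm Heart rate in beats/min, in (20, 300).
#' @param resp_rate_bpm Respiration rate in breaths/min, in (4, 60).
#' @param r_amp_mod_depth Modulation depth in `[0, 1)`.
#' @param noise_sd Additive white-noise SD (signal units).
#' @param rr_jitter_sd_ms SD of beat-to-beat interval jitter, ms.
#' @param rate_hz Sampling rate (default 250 Hz, the device ECG rate).
#' @param qrs_width_s Gaussian QRS template SD, seconds.
#' @param seed Integer seed.
#' @return A list with `signal` (a [sampled_signal()]) and `truth`, a
#'   tibble of ground-truth R peaks (`index` 1-based, `time_s`,
#'   `amplitude`).
#' @export
synth_ecg <- function(duration_s, hr_bpm = 60, resp_rate_bpm = 15,
                      r_amp_mod_depth = 0, noise_sd = 0,
                      rr_jitter_sd_ms = 0, rate_hz = 250,
                      qrs_width_s = 0.01, seed = 1) {
  stopifnot(duration_s > 0, hr_bpm > 20, hr_bpm < 300,
            resp_rate_bpm > 4, resp_rate_bpm < 60,
            r_amp_mod_depth >= 0, r_amp_mod_depth < 1, noise_sd >= 0)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  period <- 60 / hr_bpm
  out <- withr::with_seed(as.integer(seed), {
    beat_t <- seq(period / 2, duration_s - 1e-9, by = period)
    if (rr_jitter_sd_ms > 0) {
      jit <- stats::rnorm(length(beat_t), 0, rr_jitter_sd_ms / 1000)
      beat_t <- beat_t + c(0, cumsum(jit[-1]))
      beat_t <- beat_t[beat_t > 3 * qrs_width_s & beat_t < duration_s - 3 * qrs_width_s]
    }
    amp <- 1 + r_amp_mod_depth * sin(2 * pi * resp_rate_bpm / 60 * beat_t)
    x <- numeric(n)
    half <- ceiling(5 * qrs_width_s * rate_hz)
    ctr <- round(beat_t * rate_hz)          # 0-based sample of each peak
    for (b in seq_along(ctr)) {
      lo <- max(0L, ctr[b] - half); hi <- min(n - 1L, ctr[b] + half)
      kk <- lo:hi
      x[kk + 1] <- x[kk + 1] +
        amp[b] * exp(-((kk / rate_hz - ctr[b] / rate_hz)^2) / (2 * qrs_width_s^2))
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    list(x = x, idx = ctr + 1L, amp = amp, time = ctr / rate_hz)
  })
  list(
    signal = sampled_signal(out$x, rate_hz, 0, "ECG", "mV"),
    truth = tibble::tibble(index = out$idx, time_s = out$time,
                           amplitude = out$amp)
  )
}

#' Synthetic dual-wavelength PPG with a controlled ratio-of-ratios
#'
#' Builds red and infrared PPG channels sharing one pulse waveform, with
#' DC offsets and AC amplitudes arranged so that the pulse-oximetry
#' ratio-of-ratios `R = (AC_red/DC_red) / (AC_ir/DC_ir)` equals `r_ratio`
#' exactly in the noiseless case. The pulsatile waveform is zero-mean over
#' the record so the window mean recovers the DC level exactly.
#'
#' @param r_ratio Target ratio-of-ratios, in (0.3, 3).
#' @param duration_s Duration in seconds.
#' @param hr_bpm Heart rate in beats/min.
#' @param rate_hz Sampling rate (default 50 Hz, the device PPG rate).
#' @param perfusion Infrared AC/DC fraction (typical PPG perfusion ~2%).
#' @param noise_sd Additive white-noise SD (fraction of the IR AC amplitude).
#' @param seed Integer seed.
#' @return List with `red` and `ir` [sampled_signal()] channels.
#' @export
synth_dual_ppg <- function(r_ratio, duration_s = 30, hr_bpm = 75,
                           rate_hz = 50, perfusion = 0.02,
                           noise_sd = 0, seed = 1) {
  stopifnot(r_ratio > 0.3, r_ratio < 3, duration_s > 0)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  pulse <- ppg_pulse_waveform(t, hr_bpm / 60, rise_frac = 0.15)
  pulse <- pulse - mean(pulse)
  dc <- 10
  ac_ir <- perfusion * dc
  ac_red <- r_ratio * ac_ir
  out <- withr::with_seed(as.integer(seed), {
    nr <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd * ac_ir) else 0
    ni <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd * ac_ir) else 0
    list(red = dc + ac_red * pulse + nr, ir = dc + ac_ir * pulse + ni)
  })
  list(
    red = sampled_signal(out$red, rate_hz, 0, "PPG_RED", "a.u."),
    ir = sampled_signal(out$ir, rate_hz, 0, "PPG_IR", "a.u.")
  )
}

#' PPG / ABP pulse waveform template
#'
#' Periodic pulse built from a half-cosine systolic upstroke followed by a
#' two-Gaussian decay (main systolic peak plus a dicrotic bump). The
#' waveform is scaled to `[0, 1]` within each cycle: the systolic foot is
#' exactly 0 and the systolic peak exactly 1, so an arterial pulse
#' `DBP + (SBP - DBP) * w(t)` has trough `DBP` and peak `SBP` by
#' construction.
#'
#' `rise_frac` is the fraction of the cycle spent on the systolic
#' upstroke; the downstream morphology-to-pressure mapping encodes
#' systolic pressure in this shape parameter.
#'
#' @param t Time vector, seconds.
#' @param f_hz Pulse frequency, Hz.
#' @param rise_frac Systolic rise-time fraction of the cycle, in (0.02, 0.6).
#' @param phase Phase offset in cycles, `[0, 1)`.
#' @param dicrotic Relative amplitude of the dicrotic bump.
#' @return Numeric vector of waveform values in `[0, 1]`.
#' @export
ppg_pulse_waveform <- function(t, f_hz, rise_frac = 0.15, phase = 0,
                               dicrotic = 0.12) {
  stopifnot(rise_frac > 0.02, rise_frac < 0.6)
  u <- (t * f_hz + phase) %% 1          # cycle phase in [0,1)
  up <- u < rise_frac
  w <- numeric(length(t))
  # systolic upstroke: half-cosine from 0 to 1
  w[up] <- 0.5 - 0.5 * cos(pi * u[up] / rise_frac)
  # decay: Gaussian fall from the peak + dicrotic bump, rescaled to hit 0
  # at the cycle end so the waveform is continuous at the foot
  v <- (u[!up] - rise_frac) / (1 - rise_frac)   # decay phase in [0,1)
  g <- exp(-(v / 0.35)^2) + dicrotic * exp(-((v - 0.45) / 0.12)^2)
  g_end <- exp(-(1 / 0.35)^2) + dicrotic * exp(-((1 - 0.45) / 0.12)^2)
  g0 <- 1 + dicrotic * exp(-(0.45 / 0.12)^2)
  w[!up] <- (g - g_end) / (g0 - g_end)
  w
}

#' Coupled synthetic PPG/ABP segment pairs with known pressures
#'
#' Emulates archival paired waveform records for blood-pressure model
#' development: each 10-s segment carries a latent `(SBP, DBP)` pair drawn
#' from truncated normal distributions (inverse-CDF sampling for
#' determinism), with `SBP - DBP >= 20` mmHg enforced by truncating the
#' diastolic draw. The ABP channel is a periodic pulse whose peak equals
#' SBP and trough equals DBP exactly. The PPG channel encodes the labels
#' through a fixed, documented `linear_morphology` mapping:
#' * pulse amplitude `= amp_per_mmhg * (SBP - DBP)` (a.u.), and
#' * systolic rise-time fraction `= rise_intercept - rise_slope * SBP`.
#'
#' The mapping is invertible from noiseless PPG (see
#' [invert_ppg_morphology()]), which provides the closed-form sanity
#' oracle for the learning task. Additive white noise is applied to the
#' PPG at a fixed absolute SD, by default 2% of the mean pulse amplitude.
#'
#' @param n_segments Number of segments.
#' @param sbp_mean,sbp_sd Systolic label distribution (mmHg), truncated to
#'   `[80, 180]`.
#' @param dbp_mean,dbp_sd Diastolic label distribution (mmHg), truncated to
#'   `[50, 100]` (upper bound further limited to `SBP - 20`).
#' @param hr_bpm Heart rate used for every segment.
#' @param rate_hz Sampling rate of both channels (125 Hz, typical of
#'   archival waveform records).
#' @param duration_s Segment duration (10 s).
#' @param noise_sd Absolute white-noise SD added to the PPG (a.u.);
#'   `NULL` uses 2% of the mean pulse amplitude.
#' @param amp_per_mmhg,rise_intercept,rise_slope `linear_morphology`
#'   constants (fixed, documented above).
#' @param seed Integer seed.
#' @return Tibble with one row per segment: `segment_id`, `sbp`, `dbp`,
#'   and list-columns `ppg`, `abp` of [sampled_signal()] objects.
#' @export
synth_coupled_ppg_abp <- function(n_segments, sbp_mean = 120, sbp_sd = 15,
                                  dbp_mean = 75, dbp_sd = 8,
                                  hr_bpm = 75, rate_hz = 125,
                                  duration_s = 10, noise_sd = NULL,
                                  amp_per_mmhg = 0.01,
                                  rise_intercept = 0.35,
                                  rise_slope = 0.0015,
                                  seed = 1) {
  stopifnot(n_segments >= 1)
  if (is.null(noise_sd)) {
    noise_sd <- 0.02 * amp_per_mmhg * (sbp_mean - dbp_mean)
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  f <- hr_bpm / 60
  withr::with_seed(as.integer(seed), {
    u1 <- stats::runif(n_segments)
    u2 <- stats::runif(n_segments)
    phase <- stats::runif(n_segments)
    sbp <- qtruncnorm(u1, sbp_mean, sbp_sd, 80, 180)
    dbp <- qtruncnorm(u2, dbp_mean, dbp_sd, 50, pmin(100, sbp - 20))
    rows <- lapply(seq_len(n_segments), function(i) {
      rise <- rise_intercept - rise_slope * sbp[i]
      w_ppg <- ppg_pulse_waveform(t, f, rise_frac = rise, phase = phase[i])
      w_abp <- ppg_pulse_waveform(t, f, rise_frac = rise, phase = phase[i])
      ppg <- amp_per_mmhg * (sbp[i] - dbp[i]) * w_ppg
      if (noise_sd > 0) ppg <- ppg + stats::rnorm(n, 0, noise_sd)
      abp <- dbp[i] + (sbp[i] - dbp[i]) * w_abp
      tibble::tibble(
        segment_id = i, sbp = sbp[i], dbp = dbp[i],
        ppg = list(sampled_signal(ppg, rate_hz, 0, "PPG", "a.u.")),
        abp = list(sampled_signal(abp, rate_hz, 0, "ABP", "mmHg"))
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "morphology") <- list(amp_per_mmhg = amp_per_mmhg,
                                    rise_intercept = rise_intercept,
                                    rise_slope = rise_slope,
                                    hr_bpm = hr_bpm, noise_sd = noise_sd)
    out
  })
}

#' Closed-form inversion of the linear morphology mapping
#'
#' Recovers `(SBP, DBP)` from a noiseless synthetic PPG segment by
#' measuring the pulse amplitude (max - min) and the systolic rise-time
#' fraction, then inverting the `linear_morphology` constants. Serves as
#' the independent sanity oracle for the learning task: the pressures a
#' network must learn are recoverable from waveform shape alone.
#'
#' @param ppg A [sampled_signal()] produced by [synth_coupled_ppg_abp()]
#'   (noiseless).
#' @param hr_bpm Heart rate used during generation.
#' @param amp_per_mmhg,rise_intercept,rise_slope Mapping constants.
#' @return Named numeric `c(sbp, dbp)`.
#' @export
invert_ppg_morphology <- function(ppg, hr_bpm = 75, amp_per_mmhg = 0.01,
                                  rise_intercept = 0.35, rise_slope = 0.0015) {
  x <- ppg$samples
  fs <- ppg$rate_hz
  period <- 60 / hr_bpm * fs              # samples per cycle
  lo <- min(x); amp <- max(x) - lo
  u <- (x - lo) / amp                     # normalised waveform in [0,1]
  # rise fraction from the 10%-90% upstroke time before an interior peak:
  # the half-cosine upstroke crosses 0.1 and 0.9 a fixed 0.590*rise apart
  pk <- which.max(x[ceiling(period):floor(length(x) - period)]) + ceiling(period) - 1
  cross_before <- function(level) {
    i <- pk
    while (i > 1 && u[i] > level) i <- i - 1
    i + (level - u[i]) / (u[i + 1] - u[i])  # linear interpolation
  }
  i90 <- cross_before(0.9)
  i10 <- cross_before(0.1)
  k <- (acos(-0.8) - acos(0.8)) / pi      # 0.5903...
  rise <- (i90 - i10) / period / k
  sbp <- (rise_intercept - rise) / rise_slope
  dbp <- sbp - amp / amp_per_mmhg
  c(sbp = sbp, dbp = dbp)
}

# Inverse-CDF sampling of a truncated normal; vectorised over u and bounds.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + u * (pu - pl), mean, sd)
}
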