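# Shared fixtures for the test suite: small deterministic signals built in
# code, plus a direct (definition-level) Morlet transform oracle.

make_tone <- function(freq_hz, duration_s, rate_hz, amplitude = 1, phase = 0) {
  t <- (seq_len(round(duration_s * rate_hz)) - 1) / rate_hz
  sampled_signal(amplitude * sin(2 * pi * freq_hz * t + phase), rate_hz,
                 label = "tone")
}

# ABP-like pulse with exact peak/trough values via the package template
make_abp <- function(sbp, dbp, hr_bpm = 75, duration_s = 10, rate_hz = 125) {
  t <- (seq_len(round(duration_s * rate_hz)) - 1) / rate_hz
  w <- ppg_pulse_waveform(t, hr_bpm / 60, rise_frac = 0.18)
  sampled_signal(dbp + (sbp - dbp) * w, rate_hz, label = "ABP", units = "mmHg")
}

# Direct discretised Morlet transform: literal sum over every sample, the
# independent oracle for the FFT-convolution implementation.
direct_morlet <- function(x, config, scales_idx, taus) {
  k <- seq_along(x) - 1
  out <- matrix(0i, length(scales_idx), length(taus))
  for (si in seq_along(scales_idx)) {
    s <- config$scales[scales_idx[si]]
    for (ti in seq_along(taus)) {
      arg <- (k - taus[ti]) / s
      psi <- exp(1i * config$omega * arg) * exp(-config$alpha * arg^2)
      out[si, ti] <- sum(x * Conj(psi)) / sqrt(s)
    }
  }
  out
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
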