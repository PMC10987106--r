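#' Construct a uniformly sampled signal
#'
#' The basic waveform container used throughout the package: a numeric
#' sample vector plus the metadata needed to place every sample on a
#' common UTC timeline. Sample `i` (1-based) occurs at
#' `start_time_s + (i - 1) / rate_hz`; all intervals are half-open
#' `[t0, t1)`.
#'
#' `NA`/`NaN` samples are legal and preserved: dropouts are common in
#' archived waveform records, and downstream operations decide explicitly
#' how to treat them.
#'
#' @param samples Numeric vector of sample values (may contain `NA`).
#' @param rate_hz Sampling rate in Hz; must be a single positive number.
#' @param start_time_s Time of the first sample, UTC seconds. Default 0.
#' @param label Channel label, e.g. `"ECG"`, `"PPG_RED"`, `"PPG_IR"`,
#'   `"ABP"`, `"TEMP"`.
#' @param units Physical units of the samples (`"mV"`, `"a.u."`,
#'   `"mmHg"`, `"degC"` ...).
#' @return An object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * (0:249) / 250), 250, label = "ECG", units = "mV")
#' signal_duration(s)
#' @export
sampled_signal <- function(samples, rate_hz, start_time_s = 0,
                           label = "signal", units = "a.u.") {
  stopifnot(is.numeric(samples),
            is.numeric(rate_hz), length(rate_hz) == 1L, is.finite(rate_hz),
            is.numeric(start_time_s), length(start_time_s) == 1L,
            is.finite(start_time_s))
  if (rate_hz <= 0) stop("`rate_hz` must be positive", call. = FALSE)
  if (any(is.infinite(samples))) {
    stop("samples must be finite or NA", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples),
         rate_hz = as.numeric(rate_hz),
         start_time_s = as.numeric(start_time_s),
         label = as.character(label),
         units = as.character(units)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s]: %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              x$label, x$units, length(x$samples), x$rate_hz,
              x$start_time_s, signal_duration(x)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Duration and sample times of a signal
#'
#' Duration is the length of the half-open interval covered by the
#' samples, `n / rate_hz`.
#'
#' @param x A [sampled_signal()].
#' @return `signal_duration()`: duration in seconds. `signal_times()`:
#'   numeric vector of per-sample UTC times.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  length(x$samples) / x$rate_hz
}

#' @rdname signal_duration
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$start_time_s + (seq_along(x$samples) - 1) / x$rate_hz
}

#' Shift a signal onto a corrected timeline
#'
#' Applies an additive clock correction (for example the offset obtained
#' from a reference time service) to the signal's start time. Samples are
#' untouched, so the operation is exactly invertible.
#'
#' @param signal A [sampled_signal()].
#' @param offset_s Finite scalar offset in seconds; positive values move
#'   the signal later.
#' @return The shifted `sampled_signal`.
#' @export
apply_clock_offset <- function(signal, offset_s) {
  stopifnot(inherits(signal, "sampled_signal"),
            is.numeric(offset_s), length(offset_s) == 1L)
  if (!is.finite(offset_s)) stop("`offset_s` must be finite", call. = FALSE)
  signal$start_time_s <- signal$start_time_s + offset_s
  signal
}

#' Overlap of two signals on the common timeline
#'
#' Half-open intersection `[t0, t1)` of the intervals covered by two
#' signals, or `NULL` when they do not overlap.
#'
#' @param a,b [sampled_signal()] objects.
#' @return Numeric `c(t0, t1)` or `NULL`.
#' @export
signal_overlap <- function(a, b) {
  t0 <- max(a$start_time_s, b$start_time_s)
  t1 <- min(a$start_time_s + signal_duration(a),
            b$start_time_s + signal_duration(b))
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

#' Band-limited resampling to a new uniform rate
#'
#' Resamples by windowed-sinc interpolation (Kaiser window), with the
#' interpolation cutoff set below the Nyquist frequency of both the input
#' and output rates so that downsampling is anti-aliased. The output
#' covers the same half-open interval as the input:
#' `n_out = round(duration * target_rate_hz)`, which maps a 10-s segment
#' at any archival rate onto exactly `10 * target` columns.
#'
#' @param signal A [sampled_signal()] with at least 2 samples and no `NA`s.
#' @param target_rate_hz New rate in Hz (> 0).
#' @param half_width Half-width of the sinc kernel in input samples.
#' @param kaiser_beta Kaiser window shape parameter.
#' @return A `sampled_signal` at the target rate.
#' @export
resample_uniform <- function(signal, target_rate_hz,
                             half_width = 32L, kaiser_beta = 10) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(target_rate_hz) || length(target_rate_hz) != 1L ||
      !is.finite(target_rate_hz) || target_rate_hz <= 0) {
    stop("`target_rate_hz` must be a positive number", call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  if (n < 2L) stop("resampling needs at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("resampling requires NA-free input; interpolate dropouts first",
                     call. = FALSE)
  fs <- signal$rate_hz
  n_out <- max(1L, round(n / fs * target_rate_hz))
  # output grid in units of input samples
  t_out <- (seq_len(n_out) - 1) * fs / target_rate_hz
  # cutoff as a fraction of the input Nyquist; < 1 when downsampling
  cutoff <- 0.98 * min(1, target_rate_hz / fs)
  L <- as.integer(half_width)
  k <- -L:L
  i0 <- floor(t_out)
  frac <- t_out - i0
  # rows: output samples; cols: kernel taps at integer input positions
  idx <- outer(i0, k, `+`)                     # input sample index (0-based)
  dt <- frac - outer(rep(0, n_out), k, `+`)    # t_out - idx
  arg <- pi * cutoff * dt
  kern <- cutoff * ifelse(abs(arg) < 1e-12, 1, sin(arg) / arg)
  w <- kaiser_window(dt / (L + 1), kaiser_beta)
  kern <- kern * w
  # edge handling: reflect indices outside the record
  idx_r <- idx
  idx_r[idx_r < 0] <- -idx_r[idx_r < 0]
  idx_r[idx_r > n - 1] <- 2 * (n - 1) - idx_r[idx_r > n - 1]
  idx_r[idx_r < 0] <- 0
  y <- rowSums(kern * matrix(x[idx_r + 1], nrow = n_out))
  # renormalise the kernel so constants pass through exactly
  y <- y / rowSums(kern)
  sampled_signal(y, target_rate_hz, signal$start_time_s,
                 signal$label, signal$units)
}

# Kaiser window on |u| <= 1 (0 outside), vectorised over a matrix.
kaiser_window <- function(u, beta) {
  w <- matrix(0, nrow(u), ncol(u))
  inside <- abs(u) <= 1
  w[inside] <- besselI(beta * sqrt(1 - u[inside]^2), 0) / besselI(beta, 0)
  w
}
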