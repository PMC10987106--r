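#' Configuration of the Morlet scalogram transform
#'
#' The analysing wavelet is the complex Morlet
#' `psi(t) = exp(i * omega * t) * exp(-alpha * t^2)`. Scales are expressed
#' in samples at the transform rate; the default grid is the 120 integer
#' scales `20..139` (step 1, half-open `[20, 140)`), which at the default
#' 120-Hz transform rate maps to pseudo-frequencies
#' `f = omega * rate / (2 * pi * s)` spanning roughly the 0.8-8 Hz PPG
#' passband. A 10-s segment resampled to 120 Hz yields exactly 1200 time
#' columns, so default images are 120 x 1200.
#'
#' `alpha = 1/2` is the standard Morlet envelope (about `omega/pi` cycles
#' under the Gaussian); together with `omega = 6` this is the conventional
#' analytic Morlet used across biosignal time-frequency analysis.
#'
#' `reduced = TRUE` gives a half-resolution configuration (60 scales
#' `10..69` at 60 Hz -> 60 x 600 images) covering the same frequency band
#' at a quarter of the compute, intended for desk-scale experiments.
#'
#' @param scale_min,scale_max Scale grid bounds (samples); grid is
#'   `n_scales` points from `scale_min` with step
#'   `(scale_max - scale_min) / n_scales` (half-open).
#' @param n_scales Number of scales (image rows).
#' @param omega Wavelet centre frequency, rad per wavelet-time unit.
#' @param alpha Gaussian envelope decay.
#' @param target_rate_hz Rate segments are resampled to before the
#'   transform.
#' @param reduced Use the half-resolution preset.
#' @return List of class `cwt_config` (includes the explicit `scales`
#'   grid).
#' @export
cwt_config <- function(scale_min = 20, scale_max = 140, n_scales = 120,
                       omega = 6, alpha = 0.5, target_rate_hz = 120,
                       reduced = FALSE) {
  if (reduced) {
    scale_min <- scale_min / 2; scale_max <- scale_max / 2
    n_scales <- n_scales / 2; target_rate_hz <- target_rate_hz / 2
  }
  stopifnot(scale_min < scale_max, n_scales >= 2, omega > 0, alpha > 0,
            target_rate_hz > 0)
  scales <- scale_min + (seq_len(n_scales) - 1) *
    (scale_max - scale_min) / n_scales
  structure(list(scale_min = scale_min, scale_max = scale_max,
                 n_scales = as.integer(n_scales), omega = omega,
                 alpha = alpha, target_rate_hz = target_rate_hz,
                 scales = scales),
            class = "cwt_config")
}

#' Pseudo-frequencies of a scalogram configuration
#'
#' `f = omega * rate / (2 * pi * s)` in Hz, one per scale (descending with
#' scale; image row 1 = smallest scale = highest frequency).
#'
#' @param config A [cwt_config()].
#' @return Numeric vector of pseudo-frequencies in Hz.
#' @export
pseudo_frequencies <- function(config) {
  config$omega * config$target_rate_hz / (2 * pi * config$scales)
}

#' Continuous wavelet transform with a Morlet wavelet
#'
#' Computes `W(s, tau) = (1/sqrt(s)) * sum_k x[k] * Conj(psi((k - tau)/s))`
#' over the configured scale grid, i.e. the discretised transform integral
#' with time measured in samples. Each row is evaluated by FFT
#' convolution with zero padding beyond the signal ends.
#'
#' @param x Numeric vector (a signal already at the transform rate).
#' @param config A [cwt_config()].
#' @return Complex matrix, `n_scales` rows (row 1 = smallest scale =
#'   highest pseudo-frequency) by `length(x)` columns.
#' @export
morlet_cwt <- function(x, config = cwt_config()) {
  stopifnot(is.numeric(x), inherits(config, "cwt_config"))
  n <- length(x)
  sd_t <- 1 / sqrt(2 * config$alpha)
  half_max <- ceiling(4 * sd_t * config$scale_max)
  if (n < 2 * ceiling(4 * sd_t * config$scale_min) + 1) {
    stop("signal too short for the smallest wavelet support", call. = FALSE)
  }
  nfft <- 2^ceiling(log2(n + 2 * half_max + 1))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0i, config$n_scales, n)
  for (r in seq_len(config$n_scales)) {
    s <- config$scales[r]
    half <- ceiling(4 * sd_t * s)
    k <- -half:half
    psi <- exp(1i * config$omega * k / s) * exp(-config$alpha * (k / s)^2)
    # cross-correlation of x with psi/sqrt(s): place w[-j] on the circular
    # grid so column tau equals sum_k x[k] w[k - tau]
    w <- Conj(psi) / sqrt(s)
    h <- complex(length.out = nfft)
    h[((-k) %% nfft) + 1] <- w
    conv <- stats::fft(xf * stats::fft(h), inverse = TRUE) / nfft
    out[r, ] <- conv[seq_len(n)]
  }
  out
}

#' Scalogram image of a 10-s segment
#'
#' Resamples the segment to the configured transform rate (1200 columns
#' for 10 s at the default 120 Hz), takes the magnitude of the Morlet
#' transform over the scale grid, and z-score normalises the whole image
#' by its own mean and standard deviation. Row 1 is the smallest scale
#' (highest pseudo-frequency); the scale axis is stored alongside the
#' matrix.
#'
#' @param segment A [sampled_signal()], or a one-row slice of the segment
#'   tibble from [build_bp_dataset()] via `samples` + `rate_hz`.
#' @param config A [cwt_config()].
#' @return Object of class `scalogram_image`: list with `values`
#'   (n_scales x n_time numeric matrix, mean 0 / SD 1), `scales`,
#'   `pseudo_freq_hz`, `rate_hz`.
#' @export
scalogram_image <- function(segment, config = cwt_config()) {
  stopifnot(inherits(segment, "sampled_signal"))
  if (stats::sd(segment$samples) == 0) {
    stop("constant segment: scalogram has zero variance", call. = FALSE)
  }
  rs <- if (abs(segment$rate_hz - config$target_rate_hz) < 1e-12) segment
        else resample_uniform(segment, config$target_rate_hz)
  # remove the segment mean: bandpassed PPG is already zero-mean, and this
  # keeps the zero-padded transform free of offset-driven edge artefacts
  # (making the z-scored image exactly invariant to affine input changes)
  m <- Mod(morlet_cwt(rs$samples - mean(rs$samples), config))
  mu <- mean(m); s <- stats::sd(as.vector(m))
  if (s == 0) stop("constant segment: scalogram has zero variance", call. = FALSE)
  structure(list(values = (m - mu) / s,
                 scales = config$scales,
                 pseudo_freq_hz = pseudo_frequencies(config),
                 rate_hz = config$target_rate_hz),
            class = "scalogram_image")
}

#' @export
print.scalogram_image <- function(x, ...) {
  cat(sprintf("<scalogram_image> %d x %d, scales %.4g-%.4g (%.3g-%.3g Hz)\n",
              nrow(x$values), ncol(x$values), min(x$scales), max(x$scales),
              min(x$pseudo_freq_hz), max(x$pseudo_freq_hz)))
  invisible(x)
}

#' Plot a scalogram image
#'
#' @param object A `scalogram_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalogram_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$values)),
    col = seq_len(ncol(object$values))
  )
  df$value <- as.vector(t(object$values))
  df$time_s <- (df$col - 1) / object$rate_hz
  df$freq_hz <- object$pseudo_freq_hz[df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "z") +
    ggplot2::labs(x = "time (s)", y = "pseudo-frequency (Hz)")
}

#' Scalograms for a labelled segment table
#'
#' Maps [scalogram_image()] over the `samples` list-column of a
#' [build_bp_dataset()] table, returning the table with a `scalogram`
#' list-column appended. Constant segments (zero variance) are dropped
#' with a message.
#'
#' @param dataset Labelled segment tibble.
#' @param config A [cwt_config()].
#' @return The tibble with a `scalogram` list-column of numeric matrices.
#' @export
add_scalograms <- function(dataset, config = cwt_config()) {
  stopifnot(all(c("samples", "rate_hz") %in% names(dataset)))
  imgs <- vector("list", nrow(dataset))
  ok <- logical(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    sig <- sampled_signal(dataset$samples[[i]], dataset$rate_hz[i],
                          label = "PPG")
    im <- tryCatch(scalogram_image(sig, config), error = function(e) NULL)
    if (!is.null(im)) { imgs[[i]] <- im$values; ok[i] <- TRUE }
  }
  if (any(!ok)) message(sum(!ok), " constant segment(s) dropped")
  out <- dataset[ok, ]
  out$scalogram <- imgs[ok]
  out
}
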