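#' Bandpass-filter a PPG channel for blood-pressure modelling
#'
#' Fourth-order Butterworth bandpass, 0.8-8 Hz, applied forward-backward
#' (zero phase) so pulse landmarks keep their timing relative to the
#' paired arterial-pressure channel. Output length equals input length.
#'
#' @param signal A [sampled_signal()]; rate must exceed 16 Hz so the
#'   passband sits below Nyquist.
#' @param band Passband in Hz.
#' @param order Butterworth order of each (low/high) section.
#' @return The filtered `sampled_signal`.
#' @export
bandpass_ppg <- function(signal, band = c(0.8, 8), order = 4) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal$rate_hz
  if (fs <= 2 * band[2]) {
    stop("sampling rate too low for the ", band[1], "-", band[2], " Hz band",
         call. = FALSE)
  }
  if (length(signal$samples) <= 3 * order) {
    stop("signal too short to filter", call. = FALSE)
  }
  if (anyNA(signal$samples)) {
    stop("bandpass requires NA-free input; interpolate dropouts first",
         call. = FALSE)
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, signal$samples)
  sampled_signal(y, fs, signal$start_time_s, signal$label, signal$units)
}

#' Cut a record into contiguous non-overlapping segments
#'
#' Tiles the record with `floor(duration / seg_s)` segments of exactly
#' `round(seg_s * rate)` samples; a trailing partial segment is dropped.
#'
#' @param signal A [sampled_signal()].
#' @param seg_s Segment length in seconds (default 10).
#' @return Tibble with one row per segment: `segment_id`, `start_index`
#'   (1-based), `rate_hz`, `sd` (sample SD of the segment) and a `samples`
#'   list-column.
#' @export
segment_nonoverlap <- function(signal, seg_s = 10) {
  stopifnot(inherits(signal, "sampled_signal"), seg_s > 0)
  n_seg_len <- round(seg_s * signal$rate_hz)
  k <- floor(length(signal$samples) / n_seg_len)
  if (k == 0) {
    return(tibble::tibble(segment_id = integer(0), start_index = integer(0),
                          rate_hz = numeric(0), sd = numeric(0),
                          samples = list()))
  }
  starts <- (seq_len(k) - 1L) * n_seg_len + 1L
  tibble::tibble(
    segment_id = seq_len(k),
    start_index = starts,
    rate_hz = signal$rate_hz,
    samples = lapply(starts, function(s) signal$samples[s:(s + n_seg_len - 1L)])
  ) |>
    dplyr::mutate(sd = vapply(samples, stats::sd, numeric(1)),
                  .before = "samples")
}

#' Select segments with interquartile-range variance
#'
#' Motion artifacts and dropouts in real-world biosignals show up as
#' outliers in the distribution of per-segment standard deviation, at both
#' extremes. This filter computes each record's SD distribution and keeps
#' exactly the segments with `Q1 <= sd <= Q3` (inclusive bounds,
#' linear-interpolation "type 7" quartiles). Records with fewer than 4
#' segments are rejected entirely with a warning.
#'
#' @param segments Segment tibble from [segment_nonoverlap()]; if a
#'   `record_id` column is present quartiles are computed per record.
#' @return The retained subset of `segments`, with an attribute
#'   `"n_rejected_iqr"` counting removals.
#' @export
sd_iqr_filter <- function(segments) {
  if (nrow(segments) < 4) {
    warning("fewer than 4 segments: all rejected by the SD-IQR filter")
    out <- segments[0, ]
    attr(out, "n_rejected_iqr") <- nrow(segments)
    return(out)
  }
  grp <- if ("record_id" %in% names(segments)) segments$record_id else
    rep("record", nrow(segments))
  keep <- logical(nrow(segments))
  for (g in unique(grp)) {
    i <- which(grp == g)
    q <- stats::quantile(segments$sd[i], c(0.25, 0.75), type = 7, names = FALSE)
    keep[i] <- segments$sd[i] >= q[1] & segments$sd[i] <= q[2]
  }
  out <- segments[keep, ]
  attr(out, "n_rejected_iqr") <- sum(!keep)
  out
}

#' Systolic and diastolic peaks of an arterial-pressure waveform
#'
#' Local maxima of the ABP (systolic peaks) and of the negated ABP
#' (diastolic troughs), with a minimum inter-peak distance of 300 ms
#' (supports rates up to 200 beats/min) and a configurable prominence
#' threshold to ignore dicrotic ripple.
#'
#' @param abp A [sampled_signal()] covering >= 2 s.
#' @param min_distance_s Minimum spacing between like peaks, seconds.
#' @param min_prominence Minimum peak prominence in signal units (mmHg);
#'   default 10.
#' @return List with integer index vectors `systolic` and `diastolic`.
#' @export
abp_peaks <- function(abp, min_distance_s = 0.3, min_prominence = 10) {
  stopifnot(inherits(abp, "sampled_signal"))
  if (signal_duration(abp) < 2) {
    stop("insufficient data: need >= 2 s of ABP", call. = FALSE)
  }
  x <- abp$samples
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  d <- round(min_distance_s * abp$rate_hz)
  list(systolic = local_peaks(x, d, min_prominence),
       diastolic = local_peaks(-x, d, min_prominence))
}

# Local maxima with refractory spacing and a simple prominence criterion:
# height above the highest of the two surrounding minima must exceed
# min_prom.
local_peaks <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(p) {
    # walk to the nearest higher point on each side; prominence is height
    # above the larger of the two intervening minima
    l <- p; while (l > 1 && x[l - 1] <= x[p]) l <- l - 1
    r <- p; while (r < n && x[r + 1] <= x[p]) r <- r + 1
    left_min <- min(x[l:p]); right_min <- min(x[p:r])
    x[p] - max(left_min, right_min) >= min_prom
  }, logical(1))
  cand <- cand[keep]
  # enforce spacing, keeping the taller peak
  if (length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    chosen <- integer(0)
    for (p in ord) {
      if (!length(chosen) || all(abs(chosen - p) >= min_dist)) {
        chosen <- c(chosen, p)
      }
    }
    cand <- sort(chosen)
  }
  cand
}

#' Label a 10-s ABP segment with mean systolic/diastolic pressure
#'
#' Finds the segment's systolic and diastolic peaks and applies the
#' plausibility screen: if any systolic peak lies outside `[80, 180]` mmHg
#' or any diastolic trough outside `[50, 100]` mmHg, the whole segment is
#' rejected (the screen is deliberately per-segment, not per-beat).
#' Otherwise the peak amplitudes are averaged into a single
#' `(SBP, DBP)` label pair.
#'
#' @param abp_segment A [sampled_signal()] of arterial pressure, 10 s.
#' @param sbp_bounds,dbp_bounds Plausibility windows in mmHg.
#' @param min_prominence Passed to [abp_peaks()].
#' @return List with `accepted` (logical), `sbp`, `dbp` (numeric or `NA`),
#'   and `reason` for rejections.
#' @export
label_segment <- function(abp_segment, sbp_bounds = c(80, 180),
                          dbp_bounds = c(50, 100), min_prominence = 10) {
  pk <- abp_peaks(abp_segment, min_prominence = min_prominence)
  sys <- abp_segment$samples[pk$systolic]
  dia <- abp_segment$samples[pk$diastolic]
  if (!length(sys) || !length(dia)) {
    return(list(accepted = FALSE, sbp = NA_real_, dbp = NA_real_,
                reason = "no peaks"))
  }
  if (any(sys < sbp_bounds[1] | sys > sbp_bounds[2])) {
    return(list(accepted = FALSE, sbp = NA_real_, dbp = NA_real_,
                reason = "systolic peak out of bounds"))
  }
  if (any(dia < dbp_bounds[1] | dia > dbp_bounds[2])) {
    return(list(accepted = FALSE, sbp = NA_real_, dbp = NA_real_,
                reason = "diastolic peak out of bounds"))
  }
  list(accepted = TRUE, sbp = mean(sys), dbp = mean(dia), reason = NA_character_)
}

#' Build a labelled segment dataset from paired PPG/ABP records
#'
#' Full preprocessing pipeline: per pair, the PPG is bandpass filtered
#' (0.8-8 Hz zero-phase Butterworth) and both channels are cut into
#' aligned non-overlapping 10-s windows; the PPG segments then pass
#' through the per-record SD-interquartile filter and each surviving
#' window is labelled from its ABP counterpart, with out-of-bounds
#' segments dropped. Rejection reasons are tallied so the count identity
#' `accepted = total - iqr_rejected - label_rejected` always holds.
#'
#' @param records Tibble with list-columns `ppg` and `abp` of
#'   [sampled_signal()] pairs (equal rates, time-aligned), and optionally
#'   `record_id` and label columns carried through.
#' @param seg_s Segment length, seconds.
#' @param min_prominence ABP peak prominence, mmHg.
#' @return Tibble of labelled segments (`record_id`, `segment_id`,
#'   `start_index`, `rate_hz`, `sd`, `sbp`, `dbp`, `samples` list-column
#'   of filtered PPG). Attribute `"rejections"` is a tibble of reason
#'   counts.
#' @export
build_bp_dataset <- function(records, seg_s = 10, min_prominence = 10) {
  stopifnot(all(c("ppg", "abp") %in% names(records)))
  if (!nrow(records)) {
    out <- tibble::tibble(record_id = character(0), segment_id = integer(0),
                          start_index = integer(0), rate_hz = numeric(0),
                          sd = numeric(0), sbp = numeric(0), dbp = numeric(0),
                          samples = list())
    attr(out, "rejections") <- tibble::tibble(reason = character(0), n = integer(0))
    return(out)
  }
  rid <- if ("record_id" %in% names(records)) as.character(records$record_id)
         else rep("record", nrow(records))
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    ppg <- records$ppg[[i]]; abp <- records$abp[[i]]
    if (ppg$rate_hz != abp$rate_hz ||
        length(ppg$samples) != length(abp$samples)) {
      stop("pairing error: PPG/ABP not aligned in record ", rid[i],
           call. = FALSE)
    }
    segs <- segment_nonoverlap(bandpass_ppg(ppg), seg_s)
    if (!nrow(segs)) return(NULL)
    abp_segs <- segment_nonoverlap(abp, seg_s)
    segs$record_id <- rid[i]
    segs$pair_row <- i
    segs$abp_samples <- abp_segs$samples
    segs
  })
  segs <- dplyr::bind_rows(pieces)
  # renumber segments uniquely within each record (input pairs may each
  # contribute segment 1, 2, ... locally)
  segs <- segs |>
    dplyr::group_by(.data$record_id) |>
    dplyr::mutate(segment_id = dplyr::row_number()) |>
    dplyr::ungroup()
  n_total <- nrow(segs)
  kept <- sd_iqr_filter(segs)
  n_iqr <- attr(kept, "n_rejected_iqr")
  labels <- lapply(kept$abp_samples, function(s) {
    label_segment(sampled_signal(s, kept$rate_hz[1], label = "ABP",
                                 units = "mmHg"),
                  min_prominence = min_prominence)
  })
  acc <- vapply(labels, `[[`, logical(1), "accepted")
  reasons <- vapply(labels, `[[`, character(1), "reason")
  out <- kept[acc, c("record_id", "segment_id", "start_index", "rate_hz",
                     "sd", "samples")]
  out$sbp <- vapply(labels[acc], `[[`, numeric(1), "sbp")
  out$dbp <- vapply(labels[acc], `[[`, numeric(1), "dbp")
  out <- dplyr::relocate(out, "samples", .after = dplyr::last_col())
  rej <- tibble::tibble(reason = c("sd outside IQR", reasons[!acc])) |>
    dplyr::count(reason, name = "n")
  attr(out, "rejections") <- rej |>
    dplyr::mutate(n = ifelse(reason == "sd outside IQR", n_iqr, n)) |>
    dplyr::filter(n > 0)
  attr(out, "n_input_segments") <- n_total
  out
}
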