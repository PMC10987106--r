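#' End-to-end synthetic blood-pressure experiment
#'
#' Runs the complete pipeline on synthetic coupled PPG/ABP segments with
#' known pressures: generation, bandpass + segmentation + SD-IQR
#' filtering + ABP labelling, scalogram rendering, an 80/20 held-out
#' split, residual-network training, and AAMI-style evaluation on the
#' held-out portion. This is the package's parameter-recovery experiment:
#' the labels are encoded in waveform morphology by construction, so a
#' correctly wired pipeline must recover systolic pressure on held-out
#' segments to within the clinic-grade error budget.
#'
#' Defaults define the reference experiment at desk scale: 800 segments with
#' SBP ~ N(120, 15^2) truncated to [80, 180] mmHg, DBP ~ N(75, 8^2)
#' truncated to [50, 100] mmHg, PPG noise at 2% of the mean pulse
#' amplitude, reduced 60x600 scalograms, and the default training
#' recipe (Adam, lr 0.001, batch 32, weight decay 0.0005, up to 20
#' epochs).
#'
#' @param n_segments Number of generated coupled segments.
#' @param seed Integer seed driving generation, splitting and training.
#' @param reduced Use reduced 60x600 scalograms (quarter compute).
#' @param test_fraction Held-out fraction for final evaluation.
#' @param config A [training_config()]; its seed is overridden by `seed`.
#' @param hr_bpm Heart rate of the generator.
#' @return List with `eval` (a [bp_evaluate()] report), `model`,
#'   `dataset` (labelled segments with scalograms), and `test_idx`.
#' @export
run_bp_experiment <- function(n_segments = 800, seed = 7, reduced = TRUE,
                              test_fraction = 0.2,
                              config = training_config(), hr_bpm = 75) {
  seed <- as.integer(seed)
  pairs <- synth_coupled_ppg_abp(n_segments, seed = seed, hr_bpm = hr_bpm)
  dataset <- build_bp_dataset(
    dplyr::mutate(pairs, record_id = "synth")
  )
  # carry labels for evaluation: build_bp_dataset labels from the ABP
  cfg <- cwt_config(reduced = reduced)
  dataset <- add_scalograms(dataset, cfg)
  n <- nrow(dataset)
  test_idx <- withr::with_seed(seed + 10L, {
    sort(sample.int(n, round(test_fraction * n)))
  })
  train_set <- dataset[-test_idx, ]
  test_set <- dataset[test_idx, ]
  config$seed <- seed
  config$split_policy <- "by_segment"
  spec <- network_spec(input_shape = dim(dataset$scalogram[[1]]))
  model <- bp_train(train_set, config, spec)
  ev <- bp_evaluate(model, test_set)
  list(eval = ev, model = model, dataset = dataset, test_idx = test_idx)
}

#' Write a synthetic monitoring session to disk
#'
#' Generates a session with ECG, dual-wavelength PPG and a constant
#' skin-temperature channel, together with a ground-truth sidecar file
#' (JSON) holding the generator parameters and true R-peak locations.
#' Used by the `simulate` command-line subcommand.
#'
#' @param path Session file path; the sidecar is written to
#'   `<path>.truth.json`.
#' @param duration_s Session length, seconds.
#' @param hr_bpm,resp_rate_bpm,r_amp_mod_depth,noise_sd ECG generator
#'   parameters (see [synth_ecg()]).
#' @param r_ratio Dual-PPG ratio-of-ratios (see [synth_dual_ppg()]).
#' @param temp_c Skin temperature, Celsius.
#' @param subject_id,risk_group Session metadata.
#' @param seed Integer seed.
#' @return The [session_record()], invisibly.
#' @export
simulate_session <- function(path, duration_s = 120, hr_bpm = 75,
                             resp_rate_bpm = 15, r_amp_mod_depth = 0.2,
                             noise_sd = 0.02, r_ratio = 0.6, temp_c = 36.8,
                             subject_id = "synthetic",
                             risk_group = "unknown", seed = 1) {
  ecg <- synth_ecg(duration_s, hr_bpm, resp_rate_bpm, r_amp_mod_depth,
                   noise_sd, seed = seed)
  ppg <- synth_dual_ppg(r_ratio, duration_s, hr_bpm, seed = seed + 1L,
                        noise_sd = noise_sd)
  temp <- sampled_signal(rep(temp_c, round(duration_s)), 1, 0, "TEMP", "degC")
  rec <- session_record(list(ecg$signal, ppg$red, ppg$ir, temp),
                        subject_id, risk_group)
  write_session(rec, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(hr_bpm = hr_bpm, resp_rate_bpm = resp_rate_bpm,
           r_amp_mod_depth = r_amp_mod_depth, r_ratio = r_ratio,
           temp_c = temp_c, seed = seed,
           r_peak_indices = ecg$truth$index),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(rec)
}

#' Bland-Altman agreement plot
#'
#' @param a,b Paired numeric vectors.
#' @param label Measurement label for the axes.
#' @return A ggplot object showing differences against means with bias
#'   and 95% limits of agreement.
#' @export
plot_bland_altman <- function(a, b, label = "measurement") {
  ba <- bland_altman(a, b)
  df <- tibble::tibble(mean = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = 2, colour = "indianred") +
    ggplot2::labs(x = paste("mean", label), y = paste("difference in", label))
}
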