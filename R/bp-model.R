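#' Residual network topology for scalogram regression
#'
#' The network is an image-regression residual CNN: an initial
#' large-kernel strided convolution (stem), three residual blocks with
#' 64-, 128- and 256-channel outputs, each downsampling both spatial
#' dimensions by two via strided 3x3 convolutions with batch
#' normalisation and ReLU activations (1x1 strided projection on the
#' shortcut), then global average pooling and a small fully connected
#' head emitting the (SBP, DBP) pair.
#'
#' @param input_shape `c(rows, cols)` of the scalogram images.
#' @param stem_channels,stem_kernel,stem_stride Stem convolution.
#' @param block_channels Output channels of the three residual blocks.
#' @param head_hidden Width of the hidden fully connected layer.
#' @return List of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(120, 1200), stem_channels = 32,
                         stem_kernel = 7, stem_stride = 2,
                         block_channels = c(64, 128, 256),
                         head_hidden = 64) {
  stopifnot(length(input_shape) == 2, all(input_shape >= 16),
            length(block_channels) == 3, all(block_channels > 0),
            stem_kernel %% 2 == 1)
  structure(list(input_shape = as.integer(input_shape),
                 stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 block_channels = as.integer(block_channels),
                 head_hidden = as.integer(head_hidden)),
            class = "network_spec")
}

#' Per-layer spatial dimensions of a network spec
#'
#' Stem and each residual block halve both spatial dimensions
#' (`ceil(n / 2)` with "same" padding), so a default-spec input undergoes
#' four halvings before pooling.
#'
#' @param spec A [network_spec()].
#' @return Tibble with `stage`, `height`, `width`, `channels`.
#' @export
network_shapes <- function(spec) {
  halve <- function(n, k, s) floor((n + 2 * ((k - 1) %/% 2) - k) / s) + 1
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  rows <- list(tibble::tibble(stage = "input", height = h, width = w,
                              channels = 1L))
  h <- halve(h, spec$stem_kernel, spec$stem_stride)
  w <- halve(w, spec$stem_kernel, spec$stem_stride)
  rows <- c(rows, list(tibble::tibble(stage = "stem", height = h, width = w,
                                      channels = spec$stem_channels)))
  for (b in seq_along(spec$block_channels)) {
    h <- halve(h, 3, 2); w <- halve(w, 3, 2)
    rows <- c(rows, list(tibble::tibble(stage = paste0("block", b),
                                        height = h, width = w,
                                        channels = spec$block_channels[b])))
  }
  dplyr::bind_rows(rows)
}

#' Training hyperparameters
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' learning rate 0.001 and first-moment decay ("momentum") 0.9, batch
#' size 32, at most 20 epochs, and an L2 weight penalty of 0.0005 applied
#' through the loss (biases and batch-norm parameters unpenalised).
#' Validation-based early stopping (patience in epochs) is available
#' within the 20-epoch cap; the parameters kept are those of the best
#' validation epoch.
#'
#' Labels are standardised by default (centred/scaled with statistics of
#' the training labels, predictions mapped back to mmHg); training on raw
#' mmHg targets is available with `standardize_labels = FALSE`.
#'
#' @param lr Learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param weight_decay L2 penalty coefficient lambda.
#' @param patience Early-stopping patience, epochs.
#' @param early_stop Enable validation-based early stopping.
#' @param validation_fraction Fraction of the training data held out for
#'   validation, in (0, 0.5].
#' @param split_policy `"by_subject"` (no record contributes to both
#'   sides) or `"by_segment"`.
#' @param standardize_labels Standardise targets during training.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return List of class `training_config`.
#' @export
training_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            batch_size = 32, max_epochs = 20,
                            weight_decay = 5e-4, patience = 5,
                            early_stop = TRUE, validation_fraction = 0.2,
                            split_policy = c("by_subject", "by_segment"),
                            standardize_labels = TRUE, seed = 1) {
  split_policy <- match.arg(split_policy)
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, max_epochs >= 1, weight_decay >= 0,
            validation_fraction > 0, validation_fraction <= 0.5)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay,
                 patience = as.integer(patience),
                 early_stop = isTRUE(early_stop),
                 validation_fraction = validation_fraction,
                 split_policy = split_policy,
                 standardize_labels = isTRUE(standardize_labels),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Build a network with deterministic initialisation
#'
#' He-normal initialisation for convolution and dense weights
#' (`sd = sqrt(2 / fan_in)`), zero biases, unit batch-norm scale. The
#' same seed yields bit-identical parameters.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return Object of class `bp_model` (untrained): `spec`, `params`,
#'   `n_parameters`, plus label-scaling slots filled in by [bp_train()].
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  he <- function(n_out, n_in, fan_in) {
    matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / fan_in)), n_out, n_in)
  }
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    k <- spec$stem_kernel
    p$stem_W <- he(spec$stem_channels, k * k, k * k)
    p <- c(p, bn_init("stem_bn", spec$stem_channels))
    cin <- spec$stem_channels
    for (b in seq_along(spec$block_channels)) {
      cb <- spec$block_channels[b]
      pre <- paste0("b", b)
      p[[paste0(pre, "_conv1_W")]] <- he(cb, cin * 9, cin * 9)
      p <- c(p, bn_init(paste0(pre, "_bn1"), cb))
      p[[paste0(pre, "_conv2_W")]] <- he(cb, cb * 9, cb * 9)
      p <- c(p, bn_init(paste0(pre, "_bn2"), cb))
      p[[paste0(pre, "_sc_W")]] <- he(cb, cin, cin)
      p <- c(p, bn_init(paste0(pre, "_bnsc"), cb))
      cin <- cb
    }
    p$fc1_W <- he(spec$head_hidden, cin, cin)
    p$fc1_b <- numeric(spec$head_hidden)
    # near-zero output layer: predictions start close to the
    # (standardised) label mean so no optimiser steps are spent
    # un-learning a random head, while gradients still reach every layer
    p$fc2_W <- 0.01 * he(2L, spec$head_hidden, spec$head_hidden)
    p$fc2_b <- numeric(2)
    p
  })
  structure(list(spec = spec, params = params,
                 n_parameters = sum(vapply(params, length, numeric(1))),
                 label_center = c(0, 0), label_scale = c(1, 1),
                 trained = FALSE, history = NULL, train_ids = character(0)),
            class = "bp_model")
}

bn_init <- function(base, C) {
  stats::setNames(list(rep(1, C), rep(0, C), rep(0, C), rep(1, C)),
                  paste0(base, c("_g", "_b", "_rm", "_rv")))
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s, input %dx%d, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              x$spec$input_shape[1], x$spec$input_shape[2],
              format(x$n_parameters, big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  %d epoch(s); best validation loss %.4g (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss, na.rm = TRUE),
                attr(x$history, "best_epoch")))
  }
  invisible(x)
}

#' Training loss with explicit L2 weight penalty
#'
#' Mean over the batch of half the squared error summed across the two
#' outputs, plus `lambda / 2` times the squared norm of the network
#' weights (convolution and dense weights only; biases and normalisation
#' parameters are excluded from the penalty).
#'
#' @param predictions,targets Numeric matrices `n x 2` (or vectors).
#' @param weights Numeric vector of penalised weights (optional).
#' @param lambda Weight-decay coefficient.
#' @return Scalar loss.
#' @export
bp_loss <- function(predictions, targets, weights = numeric(0), lambda = 0) {
  predictions <- rbind(predictions); targets <- rbind(targets)
  stopifnot(all(dim(predictions) == dim(targets)))
  mean(0.5 * rowSums((predictions - targets)^2)) +
    lambda / 2 * sum(weights^2)
}

# Penalised-weight vector of a model (conv + dense weights only).
model_weights <- function(model) {
  nm <- names(model$params)
  unlist(model$params[grepl("_W$", nm)], use.names = FALSE)
}

#' Train the residual network on labelled scalograms
#'
#' Splits the dataset into training and validation portions per the
#' configured policy, standardises labels if configured, and runs the
#' Adam training loop. Fully reproducible under the config seed.
#'
#' @param dataset Tibble with a `scalogram` list-column of equally sized
#'   matrices and label columns `sbp`, `dbp` (plus `record_id` /
#'   `segment_id` for provenance).
#' @param config A [training_config()].
#' @param spec A [network_spec()]; its `input_shape` must match the
#'   images. Defaults to the image size found in the data.
#' @return A trained `bp_model` with a `history` tibble of per-epoch
#'   train/validation loss.
#' @export
bp_train <- function(dataset, config = training_config(), spec = NULL) {
  stopifnot(all(c("scalogram", "sbp", "dbp") %in% names(dataset)),
            nrow(dataset) >= 2)
  dims <- dim(dataset$scalogram[[1]])
  if (is.null(spec)) spec <- network_spec(input_shape = dims)
  if (!all(spec$input_shape == dims)) {
    stop("input error: images are ", dims[1], "x", dims[2],
         " but spec expects ", spec$input_shape[1], "x",
         spec$input_shape[2], call. = FALSE)
  }
  n <- nrow(dataset)
  ids <- dataset_ids(dataset)
  split <- withr::with_seed(config$seed + 1L, {
    if (config$split_policy == "by_subject" &&
        "record_id" %in% names(dataset)) {
      recs <- unique(dataset$record_id)
      if (length(recs) < 2) {
        stop("by_subject split needs >= 2 records; use split_policy = \"by_segment\"",
             call. = FALSE)
      }
      n_val <- max(1L, round(config$validation_fraction * length(recs)))
      val_recs <- sample(recs, n_val)
      list(val = which(dataset$record_id %in% val_recs))
    } else {
      list(val = sample.int(n, max(1L, round(config$validation_fraction * n))))
    }
  })
  val_idx <- sort(split$val)
  train_idx <- setdiff(seq_len(n), val_idx)
  y <- cbind(dataset$sbp, dataset$dbp)
  if (config$standardize_labels) {
    center <- colMeans(y[train_idx, , drop = FALSE])
    scale <- pmax(apply(y[train_idx, , drop = FALSE], 2, stats::sd), 1e-8)
  } else {
    center <- c(0, 0); scale <- c(1, 1)
  }
  y_std <- sweep(sweep(y, 2, center), 2, scale, "/")
  images <- array(unlist(dataset$scalogram), dim = c(dims, n))
  model <- build_network(spec, seed = config$seed)
  perms <- withr::with_seed(config$seed + 2L, {
    vapply(seq_len(config$max_epochs),
           function(e) sample.int(length(train_idx)),
           integer(length(train_idx)))
  })
  fit <- cpp_resnet_train(model$params, unclass(spec), images, y_std,
                          train_idx, val_idx, perms, unclass(config))
  model$params <- fit$params
  model$label_center <- center
  model$label_scale <- scale
  model$trained <- TRUE
  model$config <- config
  model$train_ids <- ids
  hist <- tibble::tibble(epoch = seq_along(fit$train_loss),
                         train_loss = fit$train_loss,
                         val_loss = fit$val_loss)
  attr(hist, "best_epoch") <- fit$best_epoch
  model$history <- hist
  model
}

dataset_ids <- function(dataset) {
  if (all(c("record_id", "segment_id") %in% names(dataset))) {
    paste(dataset$record_id, dataset$segment_id, sep = "#")
  } else {
    paste0("row#", seq_len(nrow(dataset)))
  }
}

#' Predict blood pressure from scalogram images
#'
#' Evaluation-mode forward pass (batch statistics frozen), so predictions
#' are independent of how inputs are batched. Outputs are mapped back to
#' mmHg using the label scaling stored in the model.
#'
#' @param object A trained `bp_model`.
#' @param newdata Tibble with a `scalogram` list-column, a plain list of
#'   matrices, or a single matrix.
#' @param ... Unused.
#' @return Tibble with `sbp_pred`, `dbp_pred`.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  imgs <- if (is.matrix(newdata)) list(newdata)
          else if (is.data.frame(newdata)) newdata$scalogram
          else newdata
  stopifnot(length(imgs) >= 1)
  dims <- dim(imgs[[1]])
  if (!all(dims == object$spec$input_shape)) {
    stop("input error: image shape ", dims[1], "x", dims[2],
         " does not match the model input ", object$spec$input_shape[1],
         "x", object$spec$input_shape[2], call. = FALSE)
  }
  arr <- array(unlist(imgs), dim = c(dims, length(imgs)))
  raw <- cpp_resnet_predict(object$params, unclass(object$spec), arr)
  tibble::tibble(
    sbp_pred = raw[, 1] * object$label_scale[1] + object$label_center[1],
    dbp_pred = raw[, 2] * object$label_scale[2] + object$label_center[2]
  )
}

#' Evaluate predictions against the device-accuracy criterion
#'
#' Computes the mean absolute error and the standard deviation of the
#' absolute errors for each output on a held-out test set, and flags
#' whether each output meets the clinic-grade 5 +/- 8 mmHg criterion
#' (MAE <= 5 and error SD <= 8). Training/test overlap is detected via
#' segment provenance and raises an error.
#'
#' @param model A trained `bp_model`.
#' @param test Labelled scalogram tibble disjoint from the training data.
#' @return Object of class `bp_eval`: list with the summary statistics and
#'   a `pairs` tibble of predictions vs labels for agreement plots.
#' @export
bp_evaluate <- function(model, test) {
  stopifnot(inherits(model, "bp_model"), model$trained)
  ids <- dataset_ids(test)
  overlap <- intersect(ids, model$train_ids)
  if (length(overlap)) {
    stop("leakage error: ", length(overlap),
         " test segment(s) were seen in training", call. = FALSE)
  }
  pred <- predict(model, test)
  err_s <- pred$sbp_pred - test$sbp
  err_d <- pred$dbp_pred - test$dbp
  structure(list(
    sbp_mae = mean(abs(err_s)), sbp_sd = stats::sd(abs(err_s)),
    dbp_mae = mean(abs(err_d)), dbp_sd = stats::sd(abs(err_d)),
    n_test = nrow(test),
    aami_pass_sbp = mean(abs(err_s)) <= 5 && stats::sd(abs(err_s)) <= 8,
    aami_pass_dbp = mean(abs(err_d)) <= 5 && stats::sd(abs(err_d)) <= 8,
    pairs = tibble::tibble(sbp = test$sbp, dbp = test$dbp,
                           sbp_pred = pred$sbp_pred,
                           dbp_pred = pred$dbp_pred)
  ), class = "bp_eval")
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> n = %d\n  SBP: MAE %.2f mmHg, SD %.2f mmHg  [AAMI %s]\n  DBP: MAE %.2f mmHg, SD %.2f mmHg  [AAMI %s]\n",
              x$n_test, x$sbp_mae, x$sbp_sd,
              if (x$aami_pass_sbp) "pass" else "fail",
              x$dbp_mae, x$dbp_sd,
              if (x$aami_pass_dbp) "pass" else "fail"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bp_eval <- function(x, ...) {
  tibble::tibble(output = c("sbp", "dbp"),
                 mae_mmhg = c(x$sbp_mae, x$dbp_mae),
                 sd_mmhg = c(x$sbp_sd, x$dbp_sd),
                 aami_pass = c(x$aami_pass_sbp, x$aami_pass_dbp))
}

#' @export
glance.bp_eval <- function(x, ...) {
  tibble::tibble(n_test = x$n_test, sbp_mae = x$sbp_mae, sbp_sd = x$sbp_sd,
                 dbp_mae = x$dbp_mae, dbp_sd = x$dbp_sd,
                 aami_pass = x$aami_pass_sbp && x$aami_pass_dbp)
}

#' @export
tidy.bp_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.bp_model <- function(x, ...) {
  tibble::tibble(trained = x$trained, n_parameters = x$n_parameters,
                 epochs_run = if (is.null(x$history)) 0L else nrow(x$history))
}

#' Parity and agreement plots for an evaluation
#'
#' @param object A `bp_eval`.
#' @param ... Unused.
#' @return A ggplot object (predicted vs true, both outputs).
#' @export
autoplot.bp_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(output = "SBP", truth = object$pairs$sbp,
                   pred = object$pairs$sbp_pred),
    tibble::tibble(output = "DBP", truth = object$pairs$dbp,
                   pred = object$pairs$dbp_pred)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~output, scales = "free") +
    ggplot2::labs(x = "reference (mmHg)", y = "predicted (mmHg)")
}

#' Training-history plot
#'
#' @param model A trained `bp_model`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  stopifnot(!is.null(model$history))
  df <- tidyr::pivot_longer(model$history, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss")
}
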