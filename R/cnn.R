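#' Training configuration for the marker-regression CNN
#'
#' Defaults follow the published training protocol: Adam for 50 epochs at
#' batch size 64, a random 10% validation split, best-validation-loss
#' checkpointing, early stopping with patience 5, and flip augmentation.
#' The learning rate is the conventional Adam default.
#'
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size (reduced with a warning when the
#'   training set is smaller).
#' @param validation_fraction fraction of images held out for validation.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param augment random vertical/horizontal/both flips per image per epoch.
#' @param seed integer seed for the split, shuffling and augmentation.
#' @return a list of class `ifc_cnn_config`.
#' @export
cnn_config <- function(epochs = 50L, batch_size = 64L,
                       validation_fraction = 0.1,
                       early_stop_patience = 5L, optimizer = "adam",
                       learning_rate = 1e-3, augment = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            early_stop_patience >= 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 optimizer = optimizer, learning_rate = learning_rate,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "ifc_cnn_config")
}

#' Build the residual CNN that regresses markers from brightfield images
#'
#' Constructs the residual architecture: a convolutional stem followed by
#' three stages of residual blocks (2/3/3 blocks at widths
#' `widths[1:3]`), each block conv-BN-ReLU-conv-BN plus an identity skip
#' (zero-padded in channels when the width grows), global average pooling
#' and a dense sigmoid head whose outputs lie in \[0, 1\]. All 17
#' convolutions are 3x3 with zero padding, so spatial size changes only at
#' the pooling steps; every activation except the final sigmoid is preceded
#' by batch normalization. The default widths give 712,354 trainable
#' parameters.
#'
#' @param image_shape input shape; must be `c(32, 32, 1)`.
#' @param n_markers number of regressed markers (2 for the CD34/FcgR
#'   configuration).
#' @param widths channel widths of the three residual stages.
#' @param seed seed for weight initialization.
#' @return an object of class `ifc_cnn` with fields `params` (weights),
#'   `n_conv_layers`, `n_parameters`, `widths`, `marker_names` (set at
#'   training time), `log` (training history once trained).
#' @export
build_marker_cnn <- function(image_shape = c(32, 32, 1), n_markers = 2L,
                             widths = c(32L, 64L, 96L), seed = 1L) {
  if (!identical(as.integer(image_shape), c(32L, 32L, 1L)))
    stop("build_marker_cnn: only 32x32 single-channel input is supported")
  stopifnot(n_markers >= 1, length(widths) == 3)
  params <- cnn_init_cpp(as.integer(n_markers), as.integer(widths),
                         as.integer(seed))
  structure(list(params = params,
                 n_conv_layers = length(params$conv),
                 n_parameters = cnn_count_parameters(params),
                 widths = as.integer(widths),
                 n_markers = as.integer(n_markers),
                 marker_names = NULL, log = NULL, trained = FALSE),
            class = "ifc_cnn")
}

# trainable parameters: conv kernels, BN scale/shift, dense head
# (BN running statistics are state, not parameters)
cnn_count_parameters <- function(params) {
  sum(vapply(params$conv, length, 0)) +
    sum(vapply(params$gamma, length, 0)) +
    sum(vapply(params$beta, length, 0)) +
    length(params$dense_W) + length(params$dense_b)
}

#' @export
print.ifc_cnn <- function(x, ...) {
  cat("<ifc_cnn> ", x$n_conv_layers, " conv layers, ",
      format(x$n_parameters, big.mark = ","), " parameters, widths ",
      paste(x$widths, collapse = "/"), ", ", x$n_markers, " markers",
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Randomly flip images for augmentation
#'
#' Each image is independently mapped to one of identity, vertical flip,
#' horizontal flip, or both. Marker targets are unchanged by construction
#' (flips preserve the morphology that encodes them).
#'
#' @param stack an [image_stack()].
#' @param flips optional integer vector in `0:3` (0 none, 1 vertical,
#'   2 horizontal, 3 both), one per image; drawn uniformly when omitted.
#' @param seed seed used when `flips` is drawn.
#' @return the flipped [image_stack()].
#' @export
augment_flips <- function(stack, flips = NULL, seed = 1L) {
  stopifnot(inherits(stack, "ifc_images"))
  n <- dim(stack$pixels)[1]
  if (is.null(flips))
    flips <- with_seed(seed, sample(0:3, n, replace = TRUE))
  stopifnot(length(flips) == n, all(flips %in% 0:3))
  px <- stack$pixels
  for (i in seq_len(n)) {
    img <- px[i, , ]
    if (flips[i] %in% c(1, 3)) img <- img[rev(seq_len(nrow(img))), ]
    if (flips[i] %in% c(2, 3)) img <- img[, rev(seq_len(ncol(img)))]
    px[i, , ] <- img
  }
  image_stack(px, stack$cell_ids)
}

#' Train the marker CNN on brightfield images
#'
#' Mini-batch Adam on the mean squared error between the sigmoid outputs
#' and the normalized marker values. A random validation fraction is held
#' out, the best-validation-loss weights are kept, and training stops early
#' after `early_stop_patience` epochs without improvement.
#'
#' @param model an untrained (or previously trained) [build_marker_cnn()]
#'   object.
#' @param images an [image_stack()].
#' @param markers a normalized [marker_table()] with one row per image, in
#'   the same order.
#' @param config an [cnn_config()].
#' @return the trained `ifc_cnn`; `$log` holds per-epoch train/validation
#'   loss.
#' @export
train_marker_cnn <- function(model, images, markers,
                             config = cnn_config()) {
  stopifnot(inherits(model, "ifc_cnn"), inherits(images, "ifc_images"),
            inherits(markers, "ifc_markers"),
            inherits(config, "ifc_cnn_config"))
  if (!markers$normalized)
    stop("train_marker_cnn: markers must be normalized to [0, 1]")
  n <- dim(images$pixels)[1]
  if (nrow(markers$values) != n)
    stop("train_marker_cnn: ", n, " images but ", nrow(markers$values),
         " marker rows")
  if (ncol(markers$values) != model$n_markers)
    stop("train_marker_cnn: model regresses ", model$n_markers,
         " markers but the table has ", ncol(markers$values))
  n_train <- n - max(1, floor(config$validation_fraction * n))
  batch <- config$batch_size
  if (batch > n_train) {
    warning("batch_size ", batch, " exceeds the training set (", n_train,
            "); reducing")
    batch <- n_train
  }
  cube <- aperm(images$pixels, c(2, 3, 1)) / 65535
  res <- cnn_train_cpp(model$params, cube, t(markers$values),
                       config$epochs, batch, config$learning_rate,
                       config$validation_fraction,
                       config$early_stop_patience, config$augment,
                       config$seed)
  model$params <- res$params
  model$marker_names <- markers$marker_names
  model$trained <- TRUE
  model$log <- data.frame(epoch = seq_along(res$train_loss),
                          train_loss = res$train_loss,
                          val_loss = res$val_loss)
  model$best_val_loss <- res$best_val_loss
  model$stopped_epoch <- res$stopped_epoch
  model
}

#' Predict marker values from brightfield images
#'
#' @param model a trained (or untrained, for smoke testing) `ifc_cnn`.
#' @param images an [image_stack()] of 32x32 frames.
#' @return an [marker_table()] with `normalized = TRUE`; the sigmoid head
#'   guarantees values in \[0, 1\].
#' @export
predict_markers <- function(model, images) {
  stopifnot(inherits(model, "ifc_cnn"), inherits(images, "ifc_images"))
  d <- dim(images$pixels)
  if (d[2] != 32 || d[3] != 32)
    stop("predict_markers: images must be 32x32, got ", d[2], "x", d[3])
  cube <- aperm(images$pixels, c(2, 3, 1)) / 65535
  pred <- cnn_predict_cpp(model$params, cube)
  nm <- if (!is.null(model$marker_names)) model$marker_names
        else paste0("marker", seq_len(ncol(pred)))
  rownames(pred) <- images$cell_ids
  colnames(pred) <- nm
  marker_table(pred, normalized = TRUE)
}
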