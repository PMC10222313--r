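#' Model specification for the two CNN variants
#'
#' Both classifiers share the same two-block backbone — conv(32, 3x3,
#' stride 1, pad 1) + batch norm + ReLU, max pool, conv(64, 3x3, stride 1,
#' no pad) + batch norm + ReLU, max pool, then two fully connected layers
#' and a softmax — and differ only in pooling geometry: the time-domain
#' variant pools 3 then 2 columns (1 row), keeping its few channel rows
#' intact, while the spectral variant pools 2 x 2.
#'
#' @param arch `"time_cnn"` or `"spectral_cnn"`.
#' @param input_shape integer length-2 `(rows, cols)`. Time CNN accepts 8
#'   or 16 rows; spectral CNN accepts 32, 36, 64 or 68 rows.
#' @param n_classes number of gesture classes (default 10).
#' @param fc_hidden width of the first fully connected layer.
#' @return A `model_spec` object.
#' @examples
#' model_spec("spectral_cnn", c(64, 129))
#' @export
model_spec <- function(arch = c("time_cnn", "spectral_cnn"), input_shape,
                       n_classes = 10, fc_hidden = 128) {
  arch <- match.arg(arch)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2 || any(input_shape < 1)) {
    abort("`input_shape` must be two positive integers (rows, cols).")
  }
  rows <- input_shape[1]
  ok <- switch(arch, time_cnn = rows %in% c(8L, 16L),
               spectral_cnn = rows %in% c(32L, 36L, 64L, 68L))
  if (!ok) {
    abort(sprintf("%s does not support %d input rows.", arch, rows))
  }
  if (n_classes < 2) abort("`n_classes` must be >= 2.")
  structure(
    list(arch = arch, input_shape = input_shape,
         n_classes = as.integer(n_classes), fc_hidden = as.integer(fc_hidden)),
    class = "model_spec"
  )
}

#' Training configuration
#'
#' Hyperparameters of the Adam training loop. Defaults (learning rate 1e-3,
#' batch 32, 10 epochs) are the package's own choices: the loss on the
#' synthetic datasets plateaus within a few epochs, so 10 epochs leaves
#' headroom without inflating the cost of the six-condition comparison.
#'
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training data.
#' @param seed integer seed controlling shuffling (and weight
#'   initialization when a model is built from this config's seed).
#' @param split train fraction used by the grouped train/test split.
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 32, epochs = 10, seed = 1L,
                         split = 0.8) {
  if (!identical(optimizer, "adam")) abort("only the 'adam' optimizer is implemented.")
  stopifnot_scalar_num(learning_rate, "learning_rate")
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (split <= 0 || split >= 1) abort("`split` must be in (0, 1).")
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed), split = split),
    class = "train_config"
  )
}

cpp_cfg <- function(spec) {
  pools <- switch(spec$arch,
    time_cnn = list(p1h = 1L, p1w = 3L, p2h = 1L, p2w = 2L),
    spectral_cnn = list(p1h = 2L, p1w = 2L, p2h = 2L, p2w = 2L)
  )
  c(list(H = spec$input_shape[1], W = spec$input_shape[2], C1 = 32L,
         C2 = 64L, fc = spec$fc_hidden, n_classes = spec$n_classes), pools)
}

#' Per-layer output shapes of a CNN
#'
#' Computes every layer's output shape with the standard floor-based
#' convolution/pooling arithmetic (conv with padding p, kernel k, stride 1:
#' `n + 2p - k + 1`; non-overlapping pooling of width w: `floor(n / w)`).
#'
#' @param spec a [model_spec()].
#' @return A tibble with columns `layer`, `channels`, `rows`, `cols`.
#' @examples
#' cnn_layer_shapes(model_spec("time_cnn", c(16, 250)))
#' @export
cnn_layer_shapes <- function(spec) {
  cfg <- cpp_cfg(spec)
  h <- cfg$H; w <- cfg$W
  sh <- list(list("input", 1L, h, w))
  sh <- c(sh, list(list("conv1 (32, 3x3, pad 1)", 32L, h, w)))
  h <- h %/% cfg$p1h; w <- w %/% cfg$p1w
  sh <- c(sh, list(list(sprintf("maxpool1 (%dx%d)", cfg$p1h, cfg$p1w), 32L, h, w)))
  h <- h - 2L; w <- w - 2L
  if (h < 1 || w < 1) abort("input collapses before the second convolution.")
  sh <- c(sh, list(list("conv2 (64, 3x3, no pad)", 64L, h, w)))
  h <- h %/% cfg$p2h; w <- w %/% cfg$p2w
  if (h < 1 || w < 1) abort("input collapses at the second pooling layer.")
  sh <- c(sh, list(list(sprintf("maxpool2 (%dx%d)", cfg$p2h, cfg$p2w), 64L, h, w)))
  sh <- c(sh, list(
    list("flatten", 1L, 1L, 64L * h * w),
    list("fc1", 1L, 1L, cfg$fc),
    list("fc2 + softmax", 1L, 1L, cfg$n_classes)
  ))
  tibble(
    layer = purrr::map_chr(sh, 1),
    channels = purrr::map_int(sh, 2),
    rows = purrr::map_int(sh, 3),
    cols = purrr::map_int(sh, 4)
  )
}

new_emg_cnn <- function(spec, weights, seed) {
  structure(list(spec = spec, weights = weights, seed = seed),
            class = "emg_cnn")
}

#' Build the time-domain image CNN
#'
#' conv(32, 3x3, pad 1) + BN + ReLU, max pool over 3 columns, conv(64,
#' 3x3, no pad) + BN + ReLU, max pool over 2 columns, two fully connected
#' layers, softmax. Weight initialization is He-scaled Gaussian from the
#' given seed, so building is deterministic.
#'
#' @param spec a [model_spec()] with `arch = "time_cnn"`.
#' @param seed integer seed for weight initialization.
#' @return An `emg_cnn` (untrained).
#' @examples
#' m <- build_time_cnn(model_spec("time_cnn", c(16, 250)))
#' @export
build_time_cnn <- function(spec, seed = 1L) {
  if (spec$arch != "time_cnn") abort("`spec` must have arch 'time_cnn'.")
  cfg <- cpp_cfg(spec)
  invisible(cpp_cnn_check_shapes(cfg))  # fails with a diagnostic if infeasible
  new_emg_cnn(spec, cpp_cnn_init(cfg, seed), as.integer(seed))
}

#' Build the spectral image CNN
#'
#' Same backbone as [build_time_cnn()] with 2 x 2 pooling at both stages.
#' One architecture accepts both the plain (32/64-row) and feature-enhanced
#' (36/68-row) spectrogram stacks; only the first fully connected layer's
#' input width changes with the image height.
#'
#' @param spec a [model_spec()] with `arch = "spectral_cnn"`.
#' @inheritParams build_time_cnn
#' @return An `emg_cnn` (untrained).
#' @export
build_spectral_cnn <- function(spec, seed = 1L) {
  if (spec$arch != "spectral_cnn") abort("`spec` must have arch 'spectral_cnn'.")
  cfg <- cpp_cfg(spec)
  invisible(cpp_cnn_check_shapes(cfg))
  new_emg_cnn(spec, cpp_cnn_init(cfg, seed), as.integer(seed))
}

#' @export
print.emg_cnn <- function(x, ...) {
  cat(sprintf("<emg_cnn> %s, input %d x %d, %d classes, %s parameters\n",
              x$spec$arch, x$spec$input_shape[1], x$spec$input_shape[2],
              x$spec$n_classes, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `emg_cnn` or `emg_cnn_fit`.
#' @return Integer parameter count (weights, biases, batch-norm scales and
#'   shifts; running statistics excluded).
#' @export
n_parameters <- function(model) {
  w <- model$weights
  train_names <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
                   "W3", "b3", "W4", "b4")
  sum(vapply(w[train_names], length, integer(1)))
}

images_to_cube <- function(images, expect_shape = NULL) {
  pix <- if (is.data.frame(images)) {
    purrr::map(images$image, "pixels")
  } else {
    purrr::map(images, "pixels")
  }
  dims <- unique(purrr::map(pix, dim))
  if (length(dims) != 1) abort("all images must share one shape.")
  if (!is.null(expect_shape) && !identical(as.integer(dims[[1]]),
                                           as.integer(expect_shape))) {
    abort(sprintf("images are %d x %d but the model expects %d x %d.",
                  dims[[1]][1], dims[[1]][2], expect_shape[1], expect_shape[2]))
  }
  array(unlist(pix, use.names = FALSE), dim = c(dims[[1]], length(pix)))
}

image_labels <- function(images) {
  if (is.data.frame(images)) {
    purrr::map_int(images$image, "label")
  } else {
    purrr::map_int(images, "label")
  }
}

#' Train a CNN on encoded images
#'
#' One full optimization run: mini-batch Adam on the softmax cross-entropy,
#' batch statistics for batch norm during training and exponential running
#' statistics for inference. Identical model, data, and config reproduce
#' the loss curve bit for bit.
#'
#' @param model an `emg_cnn` from [build_time_cnn()] / [build_spectral_cnn()].
#' @param images tibble with an `image` list column (from
#'   [encode_dataset()]) or a plain list of `emg_image`; labels must lie in
#'   `0..n_classes-1`.
#' @param cfg a [train_config()].
#' @return An `emg_cnn_fit` carrying the trained weights and a `history`
#'   tibble (`epoch`, `loss`, `accuracy` on the training stream).
#' @export
train_cnn <- function(model, images, cfg = train_config()) {
  if (!inherits(model, "emg_cnn")) abort("`model` must be an emg_cnn.")
  labels <- image_labels(images)
  if (any(labels < 0 | labels >= model$spec$n_classes)) {
    abort("labels must be in 0..n_classes-1.")
  }
  if (length(unique(labels)) < model$spec$n_classes) {
    warn("not every class is present in the training images.")
  }
  cube <- images_to_cube(images, model$spec$input_shape)
  res <- cpp_cnn_train(model$weights, cpp_cfg(model$spec), cube,
                       as.integer(labels), cfg$epochs, cfg$batch_size,
                       cfg$learning_rate, cfg$seed)
  structure(
    list(spec = model$spec, weights = res$weights, cfg = cfg,
         history = tibble(epoch = seq_len(cfg$epochs),
                          loss = as.numeric(res$loss),
                          accuracy = as.numeric(res$accuracy))),
    class = "emg_cnn_fit"
  )
}

#' @export
print.emg_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<emg_cnn_fit> %s | %d epochs | final training loss %.4f, accuracy %.1f%%\n",
    x$spec$arch, nrow(x$history), last$loss, 100 * last$accuracy))
  invisible(x)
}

predict_cnn <- function(object, images) {
  cube <- images_to_cube(images, object$spec$input_shape)
  prob <- cpp_cnn_predict(object$weights, cpp_cfg(object$spec), cube)
  colnames(prob) <- paste0(".prob_", seq_len(object$spec$n_classes) - 1)
  out <- as_tibble(prob)
  out$.pred <- max.col(prob, ties.method = "first") - 1L
  dplyr::relocate(out, ".pred")
}

#' Predict gesture probabilities
#'
#' Runs the network in inference mode (batch norm frozen at its running
#' statistics), so repeated calls give identical output.
#'
#' @param object a trained `emg_cnn_fit` (or an untrained `emg_cnn`).
#' @param images images as in [train_cnn()].
#' @param ... unused.
#' @return A tibble with `.pred` (argmax class id) and one `.prob_<k>`
#'   column per class; each row sums to 1.
#' @export
predict.emg_cnn_fit <- function(object, images, ...) {
  predict_cnn(object, images)
}

#' @rdname predict.emg_cnn_fit
#' @export
predict.emg_cnn <- function(object, images, ...) {
  predict_cnn(object, images)
}

#' Tidy the training history of a fitted CNN
#' @param x an `emg_cnn_fit`.
#' @param ... unused.
#' @return The per-epoch history tibble.
#' @importFrom generics tidy
#' @export
tidy.emg_cnn_fit <- function(x, ...) x$history

#' One-row summary of a fitted CNN
#' @param x an `emg_cnn_fit`.
#' @param ... unused.
#' @return A tibble with architecture, parameter count, epochs, and final
#'   training loss/accuracy.
#' @importFrom generics glance
#' @export
glance.emg_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    arch = x$spec$arch, n_parameters = n_parameters(x),
    epochs = nrow(x$history), final_loss = last$loss,
    final_accuracy = last$accuracy
  )
}

#' @export
generics::tidy

#' @export
generics::glance
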