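#' Convolution output-size arithmetic
#'
#' Standard convolution arithmetic,
#' `floor((F - W + 2 * pad) / stride) + 1`, used throughout the layer plan:
#' e.g. a 7x7 kernel on a 150-wide map gives 144, and 4x4/2 max pooling takes
#' 144 to 71, 65 to 31, 25 to 11 and 7 to 2.
#'
#' @param F Input size (one spatial axis).
#' @param W Kernel size.
#' @param pad Zero padding. Default 0.
#' @param stride Stride. Default 1.
#' @return Integer output size.
#' @export
conv_output_size <- function(F, W, pad = 0, stride = 1) {
  if (F < W) stop("input smaller than kernel", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  out <- (F - W + 2 * pad) %/% stride + 1L
  if (out < 1) stop("non-positive output size", call. = FALSE)
  as.integer(out)
}

#' Architecture specification for the hybrid BiLSTM-CNN
#'
#' The reference plan stacks five convolution blocks (7x7 kernels, then a
#' final 5x5; 3/512/256/128/64 output channels at `channel_scale = 1`), each
#' with ReLU, 4x4/2 max pooling after blocks 2-5 and dropout after the first
#' two pooling stages. The printed 224-to-150 first stage is not realisable
#' by a stride-1 7x7 convolution, so block 1 convolves (224 -> 218) and then
#' deterministically resamples its feature maps to 150 x 150 bilinearly;
#' every subsequent size follows exactly from standard convolution
#' arithmetic (144, 71, 65, 31, 25, 11, 7, 2). The final 2 x 2 x 64 maps are
#' flattened into a length-256 sequence of scalars feeding a bidirectional
#' LSTM (64 hidden units per direction, concatenated to 128), a 128-unit
#' dense layer and a 2-way softmax. When `fusion_dim > 0` the z-normalised
#' handcrafted feature vector is concatenated to the recurrent output before
#' the dense stack.
#'
#' `channel_scale` shrinks every convolution's channel count (never below 1)
#' while leaving all spatial arithmetic untouched; 0.125 is the test-scale
#' default used in this package's evaluation runs.
#'
#' @param input_size Input height/width in pixels. Default 224.
#' @param channel_scale Multiplier on convolution channel counts. Default 1.
#' @param fusion_dim Width of the fused handcrafted vector (0 disables
#'   fusion). Default 0.
#' @param bilstm_hidden_total Total BiLSTM output width (both directions
#'   concatenated); must be even. Default 128.
#' @param dense_units Dense layer width. Default 128.
#' @param dropout_conv,dropout_lstm Dropout rates. Defaults 0.25 / 0.5.
#' @param conv_kernels,conv_channels,conv_pools,conv_dropout,resample_after1
#'   Expert overrides for the convolution plan (used e.g. by tiny
#'   gradient-check configurations); leave NULL for the reference plan.
#' @param pool_kernel,pool_stride Pooling geometry. Defaults 4 and 2.
#' @return An object of class `bilstm_cnn_spec`.
#' @export
bilstm_cnn_spec <- function(input_size = 224, channel_scale = 1,
                            fusion_dim = 0, bilstm_hidden_total = 128,
                            dense_units = 128, dropout_conv = 0.25,
                            dropout_lstm = 0.5, conv_kernels = NULL,
                            conv_channels = NULL, conv_pools = NULL,
                            conv_dropout = NULL, resample_after1 = NULL,
                            pool_kernel = 4, pool_stride = 2) {
  if (bilstm_hidden_total %% 2 != 0) {
    stop("bilstm_hidden_total must be even (two concatenated directions)",
         call. = FALSE)
  }
  if (channel_scale <= 0) stop("channel_scale must be positive", call. = FALSE)
  base_channels <- conv_channels %||% c(3, 512, 256, 128, 64)
  spec <- list(
    input_size = as.integer(input_size),
    channel_scale = channel_scale,
    conv_kernels = as.integer(conv_kernels %||% c(7, 7, 7, 7, 5)),
    conv_channels = pmax(1L, as.integer(round(base_channels * channel_scale))),
    conv_pools = as.logical(conv_pools %||% c(FALSE, TRUE, TRUE, TRUE, TRUE)),
    conv_dropout = as.numeric(conv_dropout %||%
                                c(0, dropout_conv, dropout_conv, 0, 0)),
    resample_after1 = as.integer(resample_after1 %||%
                                   if (is.null(conv_kernels)) 150L else 0L),
    pool_kernel = as.integer(pool_kernel),
    pool_stride = as.integer(pool_stride),
    lstm_hidden = as.integer(bilstm_hidden_total / 2),
    bilstm_hidden_total = as.integer(bilstm_hidden_total),
    dropout_lstm = as.numeric(dropout_lstm),
    dense_units = as.integer(dense_units),
    n_classes = 2L,
    fusion_dim = as.integer(fusion_dim)
  )
  nb <- length(spec$conv_kernels)
  stopifnot(length(spec$conv_channels) == nb, length(spec$conv_pools) == nb,
            length(spec$conv_dropout) == nb)
  structure(spec, class = "bilstm_cnn_spec")
}

#' Layer-by-layer output shapes
#'
#' Walks the architecture with standard convolution arithmetic (see
#' [conv_output_size()]) and reports every layer's output shape; a compiled
#' dry forward pass reproduces these shapes exactly (cross-checked in the
#' test suite), so the arithmetic route is used here for speed.
#'
#' @param spec A [bilstm_cnn_spec()] (or a model built from one).
#' @return Tibble with `layer`, `type`, and output `height`, `width`,
#'   `channels` (sequence layers report length/width in `height` with
#'   `width = channels = NA`).
#' @export
introspect_shapes <- function(spec) {
  if (inherits(spec, "bilstm_cnn")) spec <- spec$spec
  stopifnot(inherits(spec, "bilstm_cnn_spec"))
  rows <- list()
  add <- function(type, h, w = NA, c = NA) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = length(rows) + 1L, type = type,
      height = as.integer(h), width = as.integer(w), channels = as.integer(c))
  }
  sz <- spec$input_size
  for (b in seq_along(spec$conv_kernels)) {
    sz <- conv_output_size(sz, spec$conv_kernels[b])
    if (b == 1L && spec$resample_after1 > 0L) sz <- spec$resample_after1
    add(sprintf("conv%d", b), sz, sz, spec$conv_channels[b])
    if (spec$conv_pools[b]) {
      sz <- conv_output_size(sz, spec$pool_kernel, 0, spec$pool_stride)
      add(sprintf("maxpool%d", sum(spec$conv_pools[1:b])), sz, sz,
          spec$conv_channels[b])
    }
    if (spec$conv_dropout[b] > 0) {
      add(sprintf("dropout%d", b), sz, sz, spec$conv_channels[b])
    }
  }
  seq_len_ <- sz * sz * spec$conv_channels[length(spec$conv_channels)]
  add("reshape", seq_len_, 1)
  add("bilstm", spec$bilstm_hidden_total)
  if (spec$dropout_lstm > 0) add("dropout_lstm", spec$bilstm_hidden_total)
  if (spec$fusion_dim > 0) {
    add("concat_fusion", spec$bilstm_hidden_total + spec$fusion_dim)
  }
  add("dense1", spec$dense_units)
  add("dense2_softmax", spec$n_classes)
  dplyr::bind_rows(rows)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate. Default 0.001.
#' @param batch_size Minibatch size. Default 32.
#' @param epochs Training epochs. Default 12.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32, epochs = 12,
                         seed = 0) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) hybrid BiLSTM-CNN model
#'
#' @param spec A [bilstm_cnn_spec()].
#' @return An object of class `bilstm_cnn` with `spec`, `params`
#'   (NULL until trained), `label_order` (`c("normal", "abnormal")`) and
#'   `history`.
#' @export
build_model <- function(spec = bilstm_cnn_spec()) {
  stopifnot(inherits(spec, "bilstm_cnn_spec"))
  structure(list(spec = spec, params = NULL,
                 label_order = c("normal", "abnormal"), history = NULL),
            class = "bilstm_cnn")
}

#' @export
print.bilstm_cnn <- function(x, ...) {
  sh <- introspect_shapes(x$spec)
  cat(sprintf(
    "<bilstm_cnn> input %dx%d, %d conv blocks, BiLSTM width %d%s, %s\n",
    x$spec$input_size, x$spec$input_size, length(x$spec$conv_kernels),
    x$spec$bilstm_hidden_total,
    if (x$spec$fusion_dim > 0) sprintf(" + %d fused features", x$spec$fusion_dim)
    else "",
    if (is.null(x$params)) "untrained" else "trained"))
  print(sh, n = nrow(sh))
  invisible(x)
}

# Stack a list of gray_images into an H x W x N array for the engine.
images_to_array <- function(images, input_size) {
  arr <- array(0, dim = c(input_size, input_size, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!all(dim(img$pixels) == c(input_size, input_size))) {
      img <- resize_image(img, c(input_size, input_size))
    }
    arr[, , i] <- img$pixels / img$max_value  # engine input scaled to [0, 1]
  }
  arr
}

spec_for_engine <- function(spec) {
  spec[c("input_size", "conv_kernels", "conv_channels", "conv_pools",
         "conv_dropout", "resample_after1", "pool_kernel", "pool_stride",
         "lstm_hidden", "dropout_lstm", "dense_units", "n_classes",
         "fusion_dim")]
}

#' Train the hybrid classifier
#'
#' Deterministic given `(data, features, cfg$seed)`: initialisation, epoch
#' shuffling and dropout all derive from one Mersenne-Twister stream inside
#' the compiled engine.
#'
#' @param model A [build_model()] object.
#' @param data A [mammo_dataset()]; images are resized to the spec input size
#'   if necessary.
#' @param features Optional numeric matrix (n images x `fusion_dim`), row
#'   aligned with `data`, already normalised (see [fit_feature_scaler()]).
#' @param cfg A [train_config()].
#' @return The fitted `bilstm_cnn` (with `params` and a `history` tibble of
#'   per-epoch mean loss).
#' @export
train_model <- function(model, data, features = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "bilstm_cnn"), inherits(data, "mammo_dataset"),
            inherits(cfg, "train_config"))
  if (length(unique(data$labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  spec <- model$spec
  if (spec$fusion_dim > 0) {
    if (is.null(features) || ncol(features) != spec$fusion_dim ||
        nrow(features) != length(data$images)) {
      stop("`features` must be a (n x fusion_dim) matrix aligned with `data`",
           call. = FALSE)
    }
  } else {
    features <- matrix(0, length(data$images), 0)
  }
  arr <- images_to_array(data$images, spec$input_size)
  y <- as.integer(data$labels == "abnormal")  # abnormal = positive class 1
  fit <- cpp_train(spec_for_engine(spec), arr, features, y,
                   cfg$learning_rate, cfg$batch_size, cfg$epochs, cfg$seed)
  if (any(!is.finite(fit$loss))) {
    stop("training diverged: non-finite loss", call. = FALSE)
  }
  model$params <- fit$params
  model$history <- tibble::tibble(epoch = seq_along(fit$loss), loss = fit$loss)
  model
}

#' Predict class probabilities and labels
#'
#' Softmax rows sum to 1; the label is the argmax, with exact ties broken
#' toward `"abnormal"` (the safer clinical default).
#'
#' @param object A trained `bilstm_cnn`.
#' @param images List of [gray_image()] or a [mammo_dataset()].
#' @param features Optional feature matrix (see [train_model()]).
#' @param ... Unused.
#' @return Tibble with `p_normal`, `p_abnormal`, `label`.
#' @export
predict.bilstm_cnn <- function(object, images, features = NULL, ...) {
  if (is.null(object$params)) stop("model is untrained", call. = FALSE)
  if (inherits(images, "mammo_dataset")) images <- images$images
  spec <- object$spec
  if (spec$fusion_dim > 0) {
    if (is.null(features) || ncol(features) != spec$fusion_dim ||
        nrow(features) != length(images)) {
      stop("`features` must be a (n x fusion_dim) matrix aligned with images",
           call. = FALSE)
    }
  } else {
    features <- matrix(0, length(images), 0)
  }
  arr <- images_to_array(images, spec$input_size)
  probs <- cpp_predict(spec_for_engine(spec), object$params, arr, features)
  colnames(probs) <- c("p_normal", "p_abnormal")
  tibble::tibble(
    p_normal = probs[, 1], p_abnormal = probs[, 2],
    label = ifelse(probs[, 2] >= probs[, 1], "abnormal", "normal")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bilstm_cnn <- function(x, ...) {
  sh <- introspect_shapes(x$spec)
  np <- if (is.null(x$params)) NA_integer_ else
    sum(vapply(x$params, length, 1L))
  dplyr::mutate(sh, n_parameters_total = np)
}

#' @export
glance.bilstm_cnn <- function(x, ...) {
  tibble::tibble(
    input_size = x$spec$input_size,
    channel_scale = x$spec$channel_scale,
    bilstm_width = x$spec$bilstm_hidden_total,
    fusion_dim = x$spec$fusion_dim,
    trained = !is.null(x$params),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}
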