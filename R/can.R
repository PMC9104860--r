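#' Configuration of the context aggregation network
#'
#' A ten-level fully-convolutional image-to-image regressor. Levels 1-9 are
#' 3x3 convolutions with dilation schedule 1, 2, 4, 8, 16, 32, 64, 128, 1
#' (padding equals dilation, stride 1, so the spatial size is preserved
#' everywhere), each followed by adaptive normalization and a leaky ReLU
#' (slope 0.2 at levels 1-8, 0.01 at level 9); level 10 is a 1x1 convolution
#' to a single output channel feeding a mean-squared-error regression head.
#' After the dilation-128 level the receptive field spans
#' `1 + 2*(1+2+4+8+16+32+64+128) = 511` pixels, covering a 256-pixel input.
#'
#' @param input_channels number of input channels N (1-3 depending on which
#'   intensity planes are stacked).
#' @param features feature width M of the hidden levels (64-512 at full
#'   scale; small values make a CPU-sized model).
#' @param input_size spatial size of the (square) input, default 256.
#' @return a `can_config` object.
#' @export
can_config <- function(input_channels = 1L, features = 64L,
                       input_size = 256L) {
  stopifnot(input_channels >= 1, features >= 1, input_size >= 8)
  dil <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L, 1L)
  structure(list(input_channels = as.integer(input_channels),
                 features = as.integer(features),
                 input_size = as.integer(input_size),
                 dilations = dil,
                 lrelu = c(rep(0.2, 8), 0.01),
                 cin = as.integer(c(input_channels,
                                    rep(features, length(dil) - 1))),
                 cout = as.integer(rep(features, length(dil)))),
            class = "can_config")
}

#' Number of learnable parameters of a configuration
#'
#' Each 3x3 level carries `3*3*Cin*Cout` weights, `Cout` biases, two
#' adaptive-normalization mixing scalars and `2*Cout` per-channel
#' normalization scale/offset values; the 1x1 head carries `M + 1`.
#'
#' @param config a [can_config()].
#' @return integer parameter count.
#' @export
can_num_params <- function(config) {
  sum(9L * config$cin * config$cout + config$cout + 2L + 2L * config$cout) +
    config$features + 1L
}

#' Build an untrained network
#'
#' Weights use fan-in-scaled Gaussian initialization
#' (`sd = sqrt(2 / (9 * Cin))` for the 3x3 levels); biases start at zero.
#' Adaptive normalization starts as `x + IN(x)` (`a = b = gamma = 1`,
#' `beta = 0`).
#'
#' @param config a [can_config()].
#' @param seed integer RNG seed for the weight draw.
#' @return a `can_model` with flat parameter vector `params`.
#' @export
build_can <- function(config, seed = 1L) {
  stopifnot(inherits(config, "can_config"))
  set.seed(seed)
  params <- numeric(0)
  for (l in seq_along(config$dilations)) {
    ci <- config$cin[l]; co <- config$cout[l]
    w <- stats::rnorm(9 * ci * co, sd = sqrt(2 / (9 * ci)))
    params <- c(params, w, rep(0, co), 1, 1, rep(1, co), rep(0, co))
  }
  m <- config$features
  params <- c(params, stats::rnorm(m, sd = sqrt(1 / m)), 0)
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE, seed = seed),
            class = "can_model")
}

#' @export
print.can_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<can_model> N = %d, M = %d, %dx%d input | %s | %d parameters\n",
              cfg$input_channels, cfg$features, cfg$input_size,
              cfg$input_size, if (x$trained) "trained" else "untrained",
              length(x$params)))
  if (!is.null(x$history)) {
    n <- nrow(x$history)
    cat(sprintf("  final train MSE %.3g, validation MSE %.3g (%d epochs)\n",
                x$history$train_loss[n], x$history$val_loss[n], n))
  }
  invisible(x)
}

.as_input_cube <- function(x, config) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[3] != config$input_channels) {
    stop("input has ", dim(x)[3], " channels, model expects ",
         config$input_channels)
  }
  x
}

#' Training hyper-parameters
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4, minibatch size 1, 100 epochs, mean-squared-error loss.
#'
#' @param learning_rate Adam step size.
#' @param epochs passes over the training set.
#' @param minibatch fixed at 1 (one image per update).
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param seed RNG seed for the per-epoch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L, minibatch = 1L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, minibatch == 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 minibatch = 1L, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network on a dataset split
#'
#' Stochastic training with Adam, one image per update, mean-squared error
#' on the wrapped-phase label. Records are reshuffled every epoch
#' (deterministically given the seed); per-epoch training and validation
#' losses are logged.
#'
#' @param model a [build_can()] model.
#' @param split a [split_dataset()] result (lists `train` and `validation`
#'   of records), or a plain list of records (no validation).
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `can_model` with a `history` data.frame.
#' @export
train_can <- function(model, split, tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "can_model"))
  if (!is.null(split$train)) {
    train <- split$train; val <- split$validation
  } else {
    train <- split; val <- list()
  }
  if (length(train) == 0) stop("empty training set")
  cfg <- model$config
  xs <- lapply(train, function(r) .as_input_cube(r$inputs, cfg))
  ys <- lapply(train, function(r) r$label)
  xv <- lapply(val, function(r) .as_input_cube(r$inputs, cfg))
  yv <- lapply(val, function(r) r$label)

  p <- model$params
  m1 <- numeric(length(p)); m2 <- numeric(length(p))
  t_step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  set.seed(tc$seed)
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(length(xs))
    tot <- 0
    for (i in ord) {
      fg <- .can_loss_grad_cpp(xs[[i]], ys[[i]], p, cfg$cin, cfg$cout,
                               cfg$dilations, cfg$lrelu)
      tot <- tot + fg$loss
      g <- fg$grad
      t_step <- t_step + 1
      m1 <- tc$beta1 * m1 + (1 - tc$beta1) * g
      m2 <- tc$beta2 * m2 + (1 - tc$beta2) * g^2
      mhat <- m1 / (1 - tc$beta1^t_step)
      vhat <- m2 / (1 - tc$beta2^t_step)
      p <- p - tc$learning_rate * mhat / (sqrt(vhat) + tc$adam_eps)
    }
    vloss <- if (length(xv)) {
      mean(vapply(seq_along(xv), function(i) {
        pr <- .can_forward_cpp(xv[[i]], p, cfg$cin, cfg$cout,
                               cfg$dilations, cfg$lrelu)
        mean((pr - yv[[i]])^2)
      }, numeric(1)))
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / length(xs),
                                   val_loss = vloss))
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.5g  val MSE %.5g",
                      ep, tot / length(xs), vloss))
    }
  }
  model$params <- p
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predict a phase map
#'
#' Raw regression output (not wrapped); wrapping, if wanted, is applied by
#' the evaluation stage.
#'
#' @param model a `can_model`.
#' @param inputs an `H x W x N` array (or `H x W` matrix for N = 1), or a
#'   list of such inputs.
#' @return an `H x W` matrix, or a list of matrices (order preserved).
#' @export
predict_can <- function(model, inputs) {
  stopifnot(inherits(model, "can_model"))
  cfg <- model$config
  one <- function(x) {
    .can_forward_cpp(.as_input_cube(x, cfg), model$params, cfg$cin,
                     cfg$cout, cfg$dilations, cfg$lrelu)
  }
  if (is.list(inputs)) lapply(inputs, one) else one(inputs)
}

#' Switch off an input channel
#'
#' Replaces the selected channel by zeros (after any normalization), leaving
#' the other channels untouched — the channel "switch-off" used to probe
#' which plane a trained network relies on.
#'
#' @param inputs `H x W x N` array (or `H x W` matrix).
#' @param channel_index channel to zero (1-based).
#' @return array of the same shape.
#' @export
ablate_channel <- function(inputs, channel_index) {
  if (is.matrix(inputs)) inputs <- array(inputs, dim = c(dim(inputs), 1L))
  stopifnot(length(dim(inputs)) == 3,
            channel_index >= 1, channel_index <= dim(inputs)[3])
  inputs[, , channel_index] <- 0
  inputs
}

#' Save / load a trained model
#'
#' Single-file serialized weights plus a JSON sidecar with the
#' architecture and training provenance.
#'
#' @param model a `can_model`.
#' @param path file path (an `.json` sidecar is written next to it).
#' @return `save_can`: the path, invisibly. `load_can`: the model.
#' @export
save_can <- function(model, path) {
  stopifnot(inherits(model, "can_model"))
  saveRDS(model, path)
  sidecar <- list(input_channels = model$config$input_channels,
                  features = model$config$features,
                  input_size = model$config$input_size,
                  n_params = length(model$params),
                  trained = model$trained, seed = model$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_can
#' @export
load_can <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "can_model"))
  model
}

#' 2-D Gaussian filter
#'
#' Separable Gaussian smoothing with mirror boundary, the window used by
#' the SSIM metric.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param win odd window width in pixels.
#' @return filtered matrix.
#' @export
gauss_filter2 <- function(x, sigma = 1.5, win = 11L) {
  stopifnot(is.matrix(x), win %% 2 == 1)
  .gauss_filter2_cpp(x, sigma, as.integer(win))
}
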