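#' Configuration of the context aggregation network (CAN)
#'
#' The CAN is a fully convolutional image-to-image regressor whose 3x3
#' convolutions carry exponentially growing dilation so that the receptive
#' field covers the whole image without any downsampling. Hidden layers
#' apply a learnable per-channel affine (adaptive normalization) and a leaky
#' rectifier; a final 1x1 convolution maps back to one channel and the model
#' is trained with a mean-square-error regression loss.
#'
#' With the defaults (\code{input_size = 256}, \code{base_channels = 64})
#' the architecture is the CAN64: dilations 1, 2, 4, ..., 128 in layers
#' 1--8 (each 3x3, padding equal to its dilation, stride 1), a dilation-1
#' 3x3 layer 9, and the 1x1 output layer 10. Leaky-rectifier slopes are 0.2
#' for layers 1--8 and 0.01 for layer 9.
#'
#' @param input_size Side of the square input image (a power of 2).
#' @param base_channels Hidden channel count (64 for the full model).
#' @param dilations Dilation sequence for the 3x3 layers; the default grows
#'   as 1, 2, 4, ... until the receptive field spans \code{input_size},
#'   followed by the final dilation-1 layer.
#' @param learning_rate Adam learning rate (full-scale default 1e-4).
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 4).
#' @param init Weight initialization: \code{"he"} (default, fan-in-scaled
#'   random) or \code{"identity"} (centre-tap identity plus small noise,
#'   the context-aggregation literature's choice; on this task it converges
#'   no faster and is kept for comparison runs).
#' @param norm Adaptive-normalization flavour. \code{"affine"} (default)
#'   is the literal learnable per-channel scale and offset; \code{"instance"}
#'   standardizes each channel map with its own mean and variance before
#'   the affine, the normalized variant of the context-aggregation
#'   literature, which conditions deep stacks better and tolerates larger
#'   learning rates.
#' @param seed Integer seed for weight initialization and data shuffling.
#' @return List of class \code{can_config}.
#' @export
can_config <- function(input_size = 256, base_channels = 64,
                       dilations = NULL, learning_rate = 1e-4,
                       epochs = 50, batch_size = 4,
                       init = c("he", "identity"),
                       norm = c("affine", "instance"), seed = 1) {
  stopifnot(input_size >= 8, bitwAnd(input_size, input_size - 1L) == 0,
            base_channels >= 1, all(learning_rate > 0), epochs >= 1,
            batch_size >= 1)
  if (is.null(dilations))
    dilations <- c(2^(0:(log2(input_size) - 1)), 1)
  if (any(dilations < 1) || any(dilations != round(dilations)))
    stop("dilations must be positive integers")
  if (2 * max(dilations) > input_size)
    stop("dilation exceeds the input size; padding cannot preserve shape")
  slopes <- c(rep(0.2, length(dilations) - 1), 0.01)
  structure(list(input_size = input_size, base_channels = base_channels,
                 dilations = as.integer(dilations), leaky_slopes = slopes,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, init = match.arg(init),
                 norm = match.arg(norm), seed = seed),
            class = "can_config")
}

#' Build an untrained CAN model
#'
#' Weights use fan-in-scaled (He) random initialization seeded from the
#' configuration; adaptive-normalization scales start at 1 and offsets at 0.
#'
#' @param cfg A \code{can_config}.
#' @return List of class \code{can_model} with elements \code{config},
#'   \code{layers}, \code{trained}, \code{training_log}.
#' @export
build_can <- function(cfg = can_config()) {
  stopifnot(inherits(cfg, "can_config"))
  C <- cfg$base_channels
  layers <- with_seed(cfg$seed, {
    c_in <- 1L
    hidden <- lapply(seq_along(cfg$dilations), function(l) {
      fan_in <- 9L * c_in
      if (identical(cfg$init, "identity")) {
        # centre-tap identity plus noise: the k = 5th of the nine kernel
        # taps (offset (0,0)) passes channel i -> i
        W <- matrix(stats::rnorm(C * fan_in, sd = 0.1 * sqrt(2 / fan_in)),
                    C, fan_in)
        ctr <- 4L * c_in
        for (c in seq_len(C))
          W[c, ctr + ((c - 1L) %% c_in) + 1L] <-
            W[c, ctr + ((c - 1L) %% c_in) + 1L] + 1
      } else {
        W <- matrix(stats::rnorm(C * fan_in, sd = sqrt(2 / fan_in)), C,
                    fan_in)
      }
      ly <- list(type = "conv3", W = W, b = numeric(C), s = rep(1, C),
                 o = numeric(C), dilation = cfg$dilations[l],
                 slope = cfg$leaky_slopes[l],
                 norm = cfg$norm %||% "affine")
      c_in <<- C
      ly
    })
    out <- list(type = "conv1",
                W = matrix(stats::rnorm(C, sd = sqrt(2 / C)), 1, C),
                b = 0)
    c(hidden, list(out))
  })
  structure(list(config = cfg, layers = layers, trained = FALSE,
                 training_log = NULL),
            class = "can_model")
}

#' @export
print.can_model <- function(x, ...) {
  cat("CAN", x$config$base_channels, "model:",
      length(x$layers), "layers, input",
      x$config$input_size, "x", x$config$input_size,
      "| dilations", paste(x$config$dilations, collapse = ","),
      "|", format(can_parameter_count(x), big.mark = ","), "parameters",
      if (x$trained) "| trained" else "| untrained", "\n")
  invisible(x)
}

#' Total number of learnable parameters of a CAN model
#'
#' Counts convolution weights and biases plus the adaptive-normalization
#' scale and offset of every hidden layer.
#'
#' @param model A \code{can_model}.
#' @return Integer parameter count.
#' @export
can_parameter_count <- function(model) {
  stopifnot(inherits(model, "can_model"))
  sum(vapply(model$layers, function(ly) {
    length(ly$W) + length(ly$b) +
      if (ly$type == "conv3") length(ly$s) + length(ly$o) else 0L
  }, numeric(1)))
}

record_matrices <- function(records, what) lapply(records, `[[`, what)

#' Train a CAN model on an SPR BFP dataset
#'
#' Optimizes the mean-square error between predicted and label phase over
#' the training split with the Adam optimizer, logging training and
#' validation loss per epoch (the validation log starts with the loss of
#' the untrained model). Shuffling and initialization derive from the
#' configured seed, so training is reproducible.
#'
#' @param model An untrained (or previously trained) \code{can_model}.
#' @param dataset An \code{spr_dataset} with train and val splits, or a
#'   list with elements \code{train} and \code{val} of records.
#' @param epochs,learning_rate,batch_size Optional overrides of the model
#'   configuration; \code{learning_rate} may be a vector with one value per
#'   epoch (a step-decay schedule).
#' @param verbose Print per-epoch losses.
#' @return The trained \code{can_model} with \code{training_log} filled
#'   (\code{train_loss}, \code{val_loss}).
#' @export
train_can <- function(model, dataset, epochs = NULL, learning_rate = NULL,
                      batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "can_model"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  if (inherits(dataset, "spr_dataset")) {
    tr <- dataset_split(dataset, "train")
    va <- dataset_split(dataset, "val")
  } else {
    tr <- dataset$train
    va <- dataset$val %||% list()
  }
  if (length(tr) == 0) stop("training split is empty")
  side <- nrow(tr[[1]]$input)
  if (side != cfg$input_size)
    stop("dataset image side ", side, " does not match configured input_size ",
         cfg$input_size)
  order <- with_seed(cfg$seed + 1L, {
    matrix(unlist(lapply(seq_len(epochs),
                         function(e) sample.int(length(tr)))),
           nrow = epochs, byrow = TRUE)
  })
  lr_schedule <- if (length(lr) == 1) rep(lr, epochs) else lr
  if (length(lr_schedule) != epochs)
    stop("learning_rate must be scalar or one value per epoch")
  res <- can_train_cpp(model$layers,
                       record_matrices(tr, "input"),
                       record_matrices(tr, "label"),
                       record_matrices(va, "input"),
                       record_matrices(va, "label"),
                       order, lr_schedule, as.integer(bs))
  if (verbose)
    for (e in seq_len(epochs))
      message(sprintf("epoch %3d  train %.5f  val %.5f", e,
                      res$train_loss[e], res$val_loss[e + 1]))
  model$layers <- res$layers
  model$trained <- TRUE
  model$training_log <- list(train_loss = res$train_loss,
                             val_loss = res$val_loss,
                             epochs = epochs, learning_rate = lr,
                             batch_size = bs)
  model
}

#' Predict a phase image from a BFP amplitude image
#'
#' A single deterministic forward pass; the output is interpreted in rad on
#' the scale of the (wrapped) training labels.
#'
#' @param model A \code{can_model}.
#' @param amplitude Square matrix normalized to [0, 1] with side equal to
#'   the configured input size.
#' @return Matrix of predicted phase values in rad.
#' @export
predict_phase <- function(model, amplitude) {
  stopifnot(inherits(model, "can_model"), is.matrix(amplitude))
  if (nrow(amplitude) != model$config$input_size ||
      ncol(amplitude) != model$config$input_size)
    stop("input must be ", model$config$input_size, " pixels square")
  if (min(amplitude) < -1e-9 || max(amplitude) > 1 + 1e-9)
    stop("input amplitude must be normalized to [0, 1]")
  can_forward_cpp(model$layers, amplitude)
}

#' Save or load a CAN model
#'
#' @param model A \code{can_model}.
#' @param path File path (conventionally \code{.rds}).
#' @return \code{load_can} returns the model; \code{save_can} the path,
#'   invisibly.
#' @export
save_can <- function(model, path) {
  stopifnot(inherits(model, "can_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_can
#' @export
load_can <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "can_model"))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
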