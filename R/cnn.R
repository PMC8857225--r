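#' Training configuration for the polar-map CNN
#'
#' Hyperparameters of the compact four-layer 2D CNN: four convolution
#' blocks (3x3 kernel, stride 2x2, ReLU, same padding, each followed by
#' 2x2 max pooling) with 12/16/32/64 filters, a flatten, two dense ReLU
#' layers (512, 128) and a single sigmoid output with L2 kernel
#' regularization on the output layer only. Training uses class-weighted
#' binary cross-entropy under SGD with momentum and time-based decay; the
#' monitored metric (AUC by default, accuracy as an option) is recorded in
#' the history but never drives early stopping or checkpoint selection.
#'
#' @param filters Integer vector of convolution filter counts, strictly
#'   increasing, length 4.
#' @param kernel Convolution kernel side (kernel x kernel).
#' @param conv_stride Convolution stride (stride x stride).
#' @param pool_window Max-pooling window (and stride).
#' @param fc_sizes Sizes of the two hidden dense layers.
#' @param l2_penalty_output L2 penalty on the output layer's kernel.
#' @param learning_rate,decay,momentum SGD parameters; the effective rate
#'   at update t is `learning_rate / (1 + decay * t)`.
#' @param monitored_metric `"AUC"` or `"ACC"`; recorded per epoch.
#' @param batch_size Minibatch size.
#' @param epochs Number of training epochs (final weights = after the last
#'   epoch; no early stopping).
#' @param class_weights Length-2 vector `c(w0, w1)` weighting the loss of
#'   non-ischemic and ischemic samples.
#' @param decision_threshold Sigmoid threshold for the hard label; outputs
#'   strictly above it predict 1 (a tie predicts 0).
#' @param input_size Input image side in pixels.
#' @return An object of class `cnn_config`.
#' @examples
#' cnn_config()
#' @export
cnn_config <- function(filters = c(12L, 16L, 32L, 64L),
                       kernel = 3L, conv_stride = 2L, pool_window = 2L,
                       fc_sizes = c(512L, 128L),
                       l2_penalty_output = 0.1,
                       learning_rate = 0.005, decay = 1e-8, momentum = 0.9,
                       monitored_metric = c("AUC", "ACC"),
                       batch_size = 20L, epochs = 35L,
                       class_weights = c(1, 3),
                       decision_threshold = 0.5,
                       input_size = 256L) {
  monitored_metric <- match.arg(monitored_metric)
  cfg <- list(filters = as.integer(filters), kernel = as.integer(kernel),
              conv_stride = as.integer(conv_stride),
              pool_window = as.integer(pool_window),
              fc_sizes = as.integer(fc_sizes),
              l2_penalty_output = l2_penalty_output,
              learning_rate = learning_rate, decay = decay,
              momentum = momentum, monitored_metric = monitored_metric,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              class_weights = class_weights,
              decision_threshold = decision_threshold,
              input_size = as.integer(input_size))
  if (length(cfg$filters) != 4 || any(diff(cfg$filters) <= 0))
    stop("filters: must be a strictly increasing sequence of length 4")
  if (cfg$decision_threshold <= 0 || cfg$decision_threshold >= 1)
    stop("decision_threshold: must lie in (0, 1)")
  if (length(cfg$class_weights) != 2 || any(cfg$class_weights <= 0))
    stop("class_weights: need positive weights c(w0, w1)")
  structure(cfg, class = "cnn_config")
}

# Shape cascade of the conv/pool stack for a square input; errors if the
# spatial size does not reduce to exactly 1x1.
shape_cascade <- function(config) {
  s <- config$input_size
  rows <- list(data.frame(layer = "input",
                          output_shape = sprintf("%dx%dx3", s, s),
                          parameters = 0L))
  cin <- 3L
  for (i in seq_along(config$filters)) {
    f <- config$filters[i]
    s_conv <- ceiling(s / config$conv_stride)   # "same" padding
    np <- (config$kernel^2 * cin + 1L) * f
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("conv%d", i),
                 output_shape = sprintf("%dx%dx%d", s_conv, s_conv, f),
                 parameters = np)
    s_pool <- s_conv %/% config$pool_window
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("pool%d", i),
                 output_shape = sprintf("%dx%dx%d", s_pool, s_pool, f),
                 parameters = 0L)
    s <- s_pool
    cin <- f
  }
  if (s != 1)
    stop("input size ", config$input_size,
         " is not reduced to 1x1 by the conv/pool cascade (got ", s, "x", s, ")")
  nin <- cin
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "flatten", output_shape = as.character(nin),
               parameters = 0L)
  for (i in seq_along(config$fc_sizes)) {
    nout <- config$fc_sizes[i]
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("fc%d", i), output_shape = as.character(nout),
                 parameters = (nin + 1L) * nout)
    nin <- nout
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "output", output_shape = "1",
               parameters = (nin + 1L) * 1L)
  do.call(rbind, rows)
}

# Glorot-uniform initial weights, drawn from the current RNG stream.
init_weights <- function(config) {
  glorot <- function(fan_in, fan_out, nr, nc) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  conv <- list()
  cin <- 3L
  k <- config$kernel
  for (f in config$filters) {
    conv[[length(conv) + 1L]] <-
      list(W = glorot(k * k * cin, k * k * f, k * k * cin, f),
           b = rep(0, f))
    cin <- f
  }
  dense <- list()
  nin <- config$filters[length(config$filters)]
  for (nout in c(config$fc_sizes, 1L)) {
    dense[[length(dense) + 1L]] <-
      list(W = glorot(nin, nout, nin, nout), b = rep(0, nout))
    nin <- nout
  }
  list(conv = conv, dense = dense)
}

#' Build the polar-map CNN
#'
#' Instantiates the architecture (unfitted) and emits its layer shape
#' report and parameter count. For the default configuration the conv/pool
#' cascade reduces a 256x256x3 input to 1x1x64 before the flatten, and the
#' network has 124,289 trainable parameters.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for the Glorot-uniform weight initialization.
#' @return An object of class `ischemia_cnn` (unfitted; see
#'   [ischemia_cnn()] for training).
#' @examples
#' m <- build_model(cnn_config(), seed = 1)
#' m$parameter_count  # 124289
#' @export
build_model <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  report <- shape_cascade(config)
  weights <- with_seed(seed, init_weights(config))
  n_par <- sum(vapply(weights$conv, function(l) length(l$W) + length(l$b), 0)) +
    sum(vapply(weights$dense, function(l) length(l$W) + length(l$b), 0))
  structure(list(config = config, weights = weights,
                 layer_shape_report = report,
                 parameter_count = as.integer(n_par),
                 fitted = FALSE, seed = as.integer(seed), history = NULL),
            class = "ischemia_cnn")
}

#' Train the polar-map CNN
#'
#' Fits the network with class-weighted binary cross-entropy under SGD
#' (momentum, time-based decay), reshuffling the training data before each
#' epoch. The final model is the weights after the last epoch: the
#' monitored metric is recorded only. Training is deterministic given the
#' seed (initialization and shuffling both derive from it).
#'
#' @param model An `ischemia_cnn` from [build_model()]; its stored seed
#'   drives initialization and shuffling.
#' @param x Training images: `size x size x 3 x n` array in `[0, 1]`.
#' @param y Integer labels (0/1), length `n`.
#' @param val_x,val_y Optional validation set, monitored per epoch.
#' @return The fitted `ischemia_cnn`, with `history` (a data frame with one
#'   row per epoch: `epoch`, `loss`, `metric`, `val_loss`, `val_metric`).
#' @export
train <- function(model, x, y, val_x = NULL, val_y = NULL) {
  stopifnot(inherits(model, "ischemia_cnn"))
  cfg <- model$config
  y <- as.integer(y)
  d <- dim(x)
  if (length(d) != 4 || d[3] != 3)
    stop("x must be a (size, size, 3, n) array")
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stop("image size ", d[1], "x", d[2], " does not match the configured input size ",
         cfg$input_size)
  n <- d[4]
  if (length(y) != n) stop("length(y) must match dim(x)[4]")
  if (length(unique(y)) < 2)
    stop("training set has a single label class; weighted binary ",
         "cross-entropy needs both classes")
  shuffle <- with_seed(model$seed + 1L,
                       t(vapply(seq_len(cfg$epochs),
                                function(e) sample.int(n), integer(n))))
  if (is.null(val_x)) {
    val_x <- array(0, dim = c(0, 0, 0, 0))
    val_y <- integer(0)
  }
  fit <- .cnn_train_cpp(model$weights, x, y, val_x, as.integer(val_y),
                        shuffle, cfg$batch_size, cfg$learning_rate,
                        cfg$decay, cfg$momentum,
                        cfg$class_weights[1], cfg$class_weights[2],
                        cfg$l2_penalty_output,
                        tolower(cfg$monitored_metric))
  model$weights <- fit$weights
  h <- as.data.frame(fit$history)
  model$history <- cbind(epoch = seq_len(nrow(h)), h)
  model$fitted <- TRUE
  model
}

#' Fit the polar-map ischemia CNN
#'
#' One-call interface: builds the architecture ([build_model()]) and trains
#' it ([train()]).
#'
#' @param x Training images: `size x size x 3 x n` array in `[0, 1]`.
#' @param y Integer labels (0/1).
#' @param val_x,val_y Optional validation set monitored during training.
#' @param config A [cnn_config()].
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A fitted object of class `ischemia_cnn`.
#' @seealso [predict.ischemia_cnn()], [summary.ischemia_cnn()],
#'   [plot.ischemia_cnn()]
#' @export
ischemia_cnn <- function(x, y, val_x = NULL, val_y = NULL,
                         config = cnn_config(), seed = 1L) {
  model <- build_model(config, seed)
  train(model, x, y, val_x, val_y)
}

#' Predict ischemia labels or probabilities
#'
#' @param object A fitted `ischemia_cnn`.
#' @param x Images: `size x size x 3 x n` array in `[0, 1]` (a single
#'   image may be given as a 3-d array).
#' @param type `"class"` for hard 0/1 labels (sigmoid output strictly above
#'   the decision threshold predicts 1; a tie predicts 0) or `"prob"` for
#'   sigmoid outputs.
#' @param threshold Decision threshold; defaults to the configured one.
#' @param ... Unused.
#' @return Integer labels or numeric probabilities, length `n`.
#' @export
predict.ischemia_cnn <- function(object, x, type = c("class", "prob"),
                                 threshold = NULL, ...) {
  type <- match.arg(type)
  if (!object$fitted && type == "class")
    warning("model is not trained; predictions come from initial weights")
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4 || d[1] != object$config$input_size ||
      d[2] != object$config$input_size || d[3] != 3)
    stop("image shape ", paste(d[1:3], collapse = "x"),
         " does not match the configured input ",
         object$config$input_size, "x", object$config$input_size, "x3")
  p <- .cnn_forward_cpp(object$weights, x)
  if (type == "prob") return(p)
  if (is.null(threshold)) threshold <- object$config$decision_threshold
  as.integer(p > threshold)
}

#' @export
print.ischemia_cnn <- function(x, ...) {
  cat("Polar-map ischemia CNN",
      if (x$fitted) "(fitted)" else "(untrained)", "\n")
  cat(sprintf("  filters %s, dense %s -> 1 sigmoid, %s parameters\n",
              paste(x$config$filters, collapse = "/"),
              paste(x$config$fc_sizes, collapse = "/"),
              format(x$parameter_count, big.mark = ",")))
  if (x$fitted) {
    h <- x$history
    cat(sprintf("  %d epochs; final loss %.4f, %s %.4f\n",
                nrow(h), h$loss[nrow(h)], x$config$monitored_metric,
                h$metric[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.ischemia_cnn <- function(object, ...) {
  print(object)
  cat("\nLayer shape report:\n")
  print(object$layer_shape_report, row.names = FALSE)
  invisible(object$layer_shape_report)
}

#' Plot the training history
#'
#' @param x A fitted `ischemia_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ischemia_cnn <- function(x, ...) {
  if (!x$fitted) stop("model is not trained")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "grey40"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("training", "validation"),
                   lty = 1:2, col = c("black", "grey40"), bty = "n")
  invisible(h)
}
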