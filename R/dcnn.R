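#' Convolutional classifier configuration
#'
#' The stock architecture: two same-padded ReLU convolution layers with 2
#' and 4 filters of size 2 x 2, each followed by 2 x 2 max pooling; the
#' pooled maps are flattened and fed to fully connected ReLU layers of 48
#' and 24 neurons, each followed by dropout 0.5; a final softmax layer
#' with one output per activity closes the network. With 40 x 40 x 3
#' input the spatial size stays 40 through each same-padded convolution
#' and halves at each pool (40 -> 20 -> 10), giving a flattened vector of
#' 10 * 10 * 4 = 400 features.
#'
#' @param input_shape Length-3 integer: image rows, cols, channels.
#' @param conv_filters Integer vector, filters per convolution layer.
#' @param filter_size Length-2 integer, kernel rows and cols (shared by
#'   all convolution layers).
#' @param pool Pooling window per layer (scalar recycled, 1 = none).
#' @param dense Integer vector of hidden fully connected layer sizes.
#' @param dropout Dropout rate in \[0, 1\) applied after each hidden
#'   dense layer during training.
#' @param n_classes Number of output classes.
#' @param class_labels Class names in output order; defaults to
#'   [har_activities()] when `n_classes` is 6, else `"class1"`, ...
#' @return An object of class `har_model_config`. Its `shapes` element
#'   lists every layer's output shape, derived with
#'   [conv_output_shape()]/pooling arithmetic.
#' @export
model_config <- function(input_shape = c(40L, 40L, 3L),
                         conv_filters = c(2L, 4L),
                         filter_size = c(2L, 2L),
                         pool = 2L,
                         dense = c(48L, 24L),
                         dropout = 0.5,
                         n_classes = 6L,
                         class_labels = NULL) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1),
            length(conv_filters) >= 1L, all(conv_filters >= 1),
            length(filter_size) == 2L, all(filter_size >= 1),
            all(pool >= 1), length(dense) >= 0L,
            is.numeric(dropout), dropout >= 0, dropout < 1,
            n_classes >= 2)
  pool <- rep_len(as.integer(pool), length(conv_filters))
  if (is.null(class_labels))
    class_labels <- if (n_classes == 6L) har_activities()
                    else paste0("class", seq_len(n_classes))
  if (length(class_labels) != n_classes)
    stop("'class_labels' must have length 'n_classes'")
  # derive every layer's output shape; same-padded conv preserves size
  h <- as.integer(input_shape[1]); w <- as.integer(input_shape[2])
  ch <- as.integer(input_shape[3])
  shapes <- list(input = c(h, w, ch))
  for (l in seq_along(conv_filters)) {
    shapes[[paste0("conv", l)]] <- c(h, w, conv_filters[l])
    h <- h %/% pool[l]; w <- w %/% pool[l]
    if (h < 1 || w < 1)
      stop(sprintf("layer %d: pooled size collapses below 1 pixel", l))
    shapes[[paste0("pool", l)]] <- c(h, w, conv_filters[l])
    ch <- conv_filters[l]
  }
  flat <- h * w * ch
  shapes$flatten <- flat
  for (z in seq_along(dense)) shapes[[paste0("dense", z)]] <- dense[z]
  shapes$output <- as.integer(n_classes)
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 filter_size = as.integer(filter_size),
                 pool = pool, dense = as.integer(dense),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 class_labels = class_labels, shapes = shapes),
            class = "har_model_config")
}

#' Training configuration
#'
#' Defaults mirror the stock recipe: sparse categorical cross-entropy
#' loss, the Adam optimizer at its usual hyperparameters, 100 epochs,
#' mini-batches of 5 images.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed Integer seed controlling weight initialization, epoch
#'   shuffling and dropout; a given seed reproduces training exactly.
#' @return An object of class `har_training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 5L,
                            learning_rate = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, epsilon = 1e-7, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "har_training_config")
}

#' Build an untrained model
#'
#' Allocates the network's weights with Glorot (uniform) initialization
#' and zero biases, deterministically from `seed`. Layer shapes are
#' derived in [model_config()] and validated here against the kernel and
#' pooling arithmetic.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initial weights.
#' @return An object of class `har_dcnn` with elements `config`,
#'   `conv` (per layer: `W` a x b x in x out array, `b` vector),
#'   `dense` (per layer incl. output: `W` out x in matrix, `b` vector),
#'   and `trained = FALSE`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "har_model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  glorot <- function(fan_in, fan_out, dims) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(dims), -lim, lim), dim = dims)
  }
  a <- config$filter_size[1]; b <- config$filter_size[2]
  ch <- config$input_shape[3]
  conv <- vector("list", length(config$conv_filters))
  for (l in seq_along(conv)) {
    f <- config$conv_filters[l]
    conv[[l]] <- list(W = glorot(a * b * ch, a * b * f, c(a, b, ch, f)),
                      b = numeric(f))
    ch <- f
  }
  sizes <- c(config$shapes$flatten, config$dense, config$n_classes)
  dense <- vector("list", length(sizes) - 1L)
  for (z in seq_along(dense)) {
    dense[[z]] <- list(
      W = matrix(glorot(sizes[z], sizes[z + 1],
                        c(sizes[z + 1], sizes[z])),
                 nrow = sizes[z + 1]),
      b = numeric(sizes[z + 1]))
  }
  structure(list(config = config, conv = conv, dense = dense,
                 trained = FALSE, history = NULL),
            class = "har_dcnn")
}

.check_images <- function(model, images) {
  d <- dim(images)
  shp <- model$config$input_shape
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("'images' must be a rows x cols x channels (x N) array")
  if (length(d) == 3L) {
    images <- array(images, dim = c(d, 1L))
    d <- dim(images)
  }
  if (!all(d[1:3] == shp))
    stop(sprintf("image shape %s does not match model input %s",
                 paste(d[1:3], collapse = "x"), paste(shp, collapse = "x")))
  images
}

.encode_labels <- function(labels, class_labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, class_labels)
    if (anyNA(idx))
      stop("unknown label(s): ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
    return(idx - 1L)
  }
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= length(class_labels)))
    stop("integer labels must lie in [0, n_classes)")
  labels
}

#' Train the convolutional classifier
#'
#' Mini-batch gradient descent with the Adam optimizer on the sparse
#' categorical cross-entropy loss, in the package's compiled backend.
#' Dropout is active during training only. All randomness (shuffling,
#' dropout) derives from `tc$seed`, so a run is reproducible exactly.
#'
#' @param model An untrained (or previously trained) [build_model()].
#' @param images rows x cols x channels x N array of images in \[0, 1\].
#' @param labels Length-N labels: a factor/character vector of class
#'   labels, or 0-based integer class indices.
#' @param tc A [training_config()].
#' @return The model with learned weights, `trained = TRUE`, and
#'   `history` (data frame: epoch, mean training loss, training
#'   accuracy).
#' @export
train_dcnn <- function(model, images, labels, tc = training_config()) {
  stopifnot(inherits(model, "har_dcnn"), inherits(tc, "har_training_config"))
  images <- .check_images(model, images)
  n <- dim(images)[4]
  if (n == 0L) stop("empty training set")
  y <- .encode_labels(labels, model$config$class_labels)
  if (length(y) != n) stop("length of 'labels' must match image count")
  fit <- cpp_dcnn_train(images, y, model$conv, model$dense,
                        model$config$pool, model$config$dropout,
                        tc$epochs, tc$batch_size, tc$learning_rate,
                        tc$beta1, tc$beta2, tc$epsilon, tc$seed,
                        model$config$n_classes)
  # restore R-side array/matrix structure on the returned weights
  for (l in seq_along(model$conv)) {
    model$conv[[l]]$W <- array(fit$conv[[l]]$W, dim = dim(model$conv[[l]]$W))
    model$conv[[l]]$b <- as.numeric(fit$conv[[l]]$b)
  }
  for (z in seq_along(model$dense)) {
    model$dense[[z]]$W <- matrix(fit$dense[[z]]$W,
                                 nrow = nrow(model$dense[[z]]$W))
    model$dense[[z]]$b <- as.numeric(fit$dense[[z]]$b)
  }
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(tc$epochs),
                              loss = fit$loss, accuracy = fit$accuracy)
  model
}

#' Predict activities for a batch of images
#'
#' Runs the compiled forward pass (dropout inactive) and returns either
#' hard labels (the class with the highest softmax probability; exact
#' ties go to the lowest class index) or the full probability matrix.
#'
#' @param object A [train_dcnn()] model (an untrained model predicts with
#'   its initial weights).
#' @param images rows x cols x channels (x N) array.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted labels, or an N x n_classes probability
#'   matrix whose rows sum to 1.
#' @export
predict.har_dcnn <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  images <- .check_images(object, images)
  probs <- cpp_dcnn_predict(images, object$conv, object$dense,
                            object$config$pool, object$config$n_classes)
  colnames(probs) <- object$config$class_labels
  if (type == "prob") return(probs)
  idx <- apply(probs, 1L, which.max)  # ties -> lowest index
  factor(object$config$class_labels[idx],
         levels = object$config$class_labels)
}

#' @export
print.har_dcnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Convolutional activity classifier (%s)\n",
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  input %s; conv filters %s (%dx%d, same, ReLU); pool %s\n",
              paste(cfg$input_shape, collapse = "x"),
              paste(cfg$conv_filters, collapse = ","),
              cfg$filter_size[1], cfg$filter_size[2],
              paste(cfg$pool, collapse = ",")))
  cat(sprintf("  dense %s + dropout %.2f; softmax over %d classes\n",
              paste(cfg$dense, collapse = ","), cfg$dropout, cfg$n_classes))
  if (!is.null(x$history))
    cat(sprintf("  final epoch: loss %.4f, accuracy %.4f\n",
                utils::tail(x$history$loss, 1),
                utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' Reference forward pass (pure R)
#'
#' Composes the reference operations — [conv2d_multichannel()], [relu()],
#' [maxpool()], [flatten_concat()], [dense_forward()], [softmax()] — on a
#' single image. Slow by design; used as the oracle that the compiled
#' forward pass is tested against.
#'
#' @param model A `har_dcnn` model.
#' @param image rows x cols x channels array.
#' @param keep_intermediates If `TRUE`, also return every layer's output.
#' @return Probability vector (or a list with `prob` and `layers`).
#' @export
ref_forward <- function(model, image, keep_intermediates = FALSE) {
  stopifnot(inherits(model, "har_dcnn"), length(dim(image)) == 3L)
  layers <- list()
  x <- image
  for (l in seq_along(model$conv)) {
    y <- conv2d_multichannel(x, model$conv[[l]]$W, model$conv[[l]]$b,
                             stride = 1L, padding = "same")
    layers[[paste0("conv", l, "_pre")]] <- y
    y <- relu(y)
    x <- maxpool(y, model$config$pool[l])
    layers[[paste0("pool", l)]] <- x
  }
  h <- flatten_concat(x)
  layers$flatten <- h
  nz <- length(model$dense)
  for (z in seq_len(nz)) {
    act <- if (z < nz) relu else identity
    h <- dense_forward(h, model$dense[[z]]$W, model$dense[[z]]$b, act)
    layers[[paste0("dense", z)]] <- h
  }
  p <- softmax(h)
  if (keep_intermediates) list(prob = p, layers = layers) else p
}
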