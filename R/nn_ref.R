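#' Spatial output size of a convolution
#'
#' `floor((input - filter + 2*padding)/stride) + 1`. When the stride
#' divides exactly (the usual case here) the floor is inactive and the
#' formula is the familiar size arithmetic of a strided convolution.
#'
#' @param input Input size along one dimension.
#' @param filter Filter size along the same dimension.
#' @param padding Zeros added on *each* border (default 0).
#' @param stride Filter step (default 1).
#' @return Integer output size; an error if it would be < 1.
#' @export
#' @examples
#' conv_output_shape(5, 2)              # 4
#' conv_output_shape(4, 2, stride = 2)  # 2
conv_output_shape <- function(input, filter, padding = 0L, stride = 1L) {
  stopifnot(input >= 1, filter >= 1, padding >= 0, stride >= 1)
  out <- (input - filter + 2 * padding) %/% stride + 1
  if (out < 1) stop("filter larger than padded input")
  as.integer(out)
}

# "same" padding for stride 1: total padding filter-1, extra at
# bottom/right when odd (top/left gets the floor).
.same_pad <- function(filter) {
  total <- filter - 1L
  c(before = total %/% 2L, after = total - total %/% 2L)
}

.pad_matrix <- function(m, top, bottom, left, right) {
  out <- matrix(0, nrow(m) + top + bottom, ncol(m) + left + right)
  out[top + seq_len(nrow(m)), left + seq_len(ncol(m))] <- m
  out
}

# Plain 2D cross-correlation of one channel with one kernel (no flip):
# Y[i,j] = sum_{p,q} K[p,q] * X[i+p-1, j+q-1].
.xcorr2 <- function(X, K, stride = 1L) {
  a <- nrow(K); b <- ncol(K)
  oh <- conv_output_shape(nrow(X), a, 0L, stride)
  ow <- conv_output_shape(ncol(X), b, 0L, stride)
  Y <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    r <- (i - 1L) * stride; c <- (j - 1L) * stride
    Y[i, j] <- sum(K * X[r + seq_len(a), c + seq_len(b)])
  }
  Y
}

#' Reference multi-channel 2D convolution
#'
#' Direct evaluation of the network's convolution: each filter is
#' cross-correlated (no kernel flip, index arithmetic
#' `K[p,q] * X[i+p-1, j+q-1]`) with every input channel and the
#' per-channel results are summed element-wise, giving one output map per
#' filter. Deliberately loop-based and unoptimized: this is the oracle
#' the compiled trainer is tested against.
#'
#' @param x H x W x C numeric array (a single multi-channel image).
#' @param filters a x b x C x F numeric array of kernels.
#' @param bias Optional length-F numeric added per output map.
#' @param stride Filter step (default 1).
#' @param padding `"valid"` (none), `"same"` (output size = input size at
#'   stride 1; asymmetric padding goes bottom/right), or a single
#'   non-negative integer applied to every border.
#' @return H' x W' x F numeric array.
#' @export
conv2d_multichannel <- function(x, filters, bias = NULL, stride = 1L,
                                padding = "valid") {
  stopifnot(length(dim(x)) == 3L, length(dim(filters)) == 4L)
  C <- dim(x)[3]
  if (dim(filters)[3] != C)
    stop(sprintf("filter channels (%d) do not match input channels (%d)",
                 dim(filters)[3], C))
  nf <- dim(filters)[4]
  a <- dim(filters)[1]; b <- dim(filters)[2]
  if (identical(padding, "same")) {
    if (stride != 1L) stop("'same' padding is defined here for stride 1 only")
    pr <- .same_pad(a); pc <- .same_pad(b)
  } else if (identical(padding, "valid")) {
    pr <- pc <- c(before = 0L, after = 0L)
  } else {
    stopifnot(is.numeric(padding), length(padding) == 1L, padding >= 0)
    pr <- pc <- c(before = as.integer(padding), after = as.integer(padding))
  }
  xp <- array(0, dim = c(dim(x)[1] + sum(pr), dim(x)[2] + sum(pc), C))
  for (c_ in seq_len(C))
    xp[, , c_] <- .pad_matrix(x[, , c_], pr[1], pr[2], pc[1], pc[2])
  oh <- conv_output_shape(dim(xp)[1], a, 0L, stride)
  ow <- conv_output_shape(dim(xp)[2], b, 0L, stride)
  out <- array(0, dim = c(oh, ow, nf))
  for (f in seq_len(nf)) {
    acc <- matrix(0, oh, ow)
    for (c_ in seq_len(C))
      acc <- acc + .xcorr2(matrix(xp[, , c_], dim(xp)[1], dim(xp)[2]),
                           matrix(filters[, , c_, f], a, b), stride)
    if (!is.null(bias)) acc <- acc + bias[f]
    out[, , f] <- acc
  }
  out
}

#' Max pooling
#'
#' Each output cell is the maximum over its k x k block. Trailing rows or
#' columns that do not fill a block are dropped. Given a 3D array, each
#' map (third dimension) is pooled independently.
#'
#' @param y Numeric matrix, or H x W x F array.
#' @param k Pooling window size (>= 1).
#' @return Pooled matrix or array of size `floor(dim/k)` spatially.
#' @export
#' @examples
#' maxpool(matrix(1:4, 2, 2, byrow = TRUE), 2)  # 4
maxpool <- function(y, k = 2L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  k <- as.integer(k)
  if (is.array(y) && length(dim(y)) == 3L) {
    maps <- lapply(seq_len(dim(y)[3]), function(f) maxpool(y[, , f], k))
    return(array(unlist(maps), dim = c(dim(maps[[1]]), length(maps))))
  }
  stopifnot(is.matrix(y))
  oh <- nrow(y) %/% k; ow <- ncol(y) %/% k
  out <- matrix(-Inf, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow))
    out[i, j] <- max(y[(i - 1L) * k + seq_len(k), (j - 1L) * k + seq_len(k)])
  out
}

#' Flatten feature maps into one vector
#'
#' Maps are taken in input order and each is read row-major (row by row),
#' a fixed documented order shared with the compiled trainer. The result
#' length is the sum of `rows * cols` over the maps.
#'
#' @param feature_maps A list of numeric matrices, or an H x W x F array
#'   (treated as F maps in order).
#' @return Numeric vector.
#' @export
flatten_concat <- function(feature_maps) {
  if (is.array(feature_maps) && length(dim(feature_maps)) == 3L)
    feature_maps <- lapply(seq_len(dim(feature_maps)[3]),
                           function(f) feature_maps[, , f])
  if (length(feature_maps) == 0L) return(numeric(0))
  unlist(lapply(feature_maps, function(m) as.vector(t(m))), use.names = FALSE)
}

#' Fully connected layer forward pass
#'
#' `activation(W %*% h + b)`; the affine map of a dense layer.
#'
#' @param h Input numeric vector (length = ncol(W)).
#' @param W Weight matrix (out x in).
#' @param b Bias vector (length = nrow(W)).
#' @param activation Function applied element-wise (default identity).
#' @return Numeric vector of length nrow(W).
#' @export
dense_forward <- function(h, W, b, activation = identity) {
  stopifnot(is.matrix(W), length(h) == ncol(W), length(b) == nrow(W))
  as.vector(activation(W %*% h + b))
}

#' Rectified linear activation
#' @param x Numeric.
#' @return `pmax(x, 0)`.
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable softmax
#'
#' `exp(z_j) / sum(exp(z_k))`, computed after subtracting `max(z)` (which
#' leaves the value unchanged analytically). Components are positive and
#' sum to 1.
#'
#' @param z Numeric vector of logits.
#' @return Probability vector of the same length.
#' @export
softmax <- function(z) {
  stopifnot(length(z) >= 1, all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}
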