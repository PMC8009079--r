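# Shared fixtures and independent oracles, built in code at test time.

# A window object around a raw matrix.
make_window <- function(data, label = "Walking",
                        origin = list(user_id = 1L, segment_id = 1L,
                                      start = 0L)) {
  list(data = data, label = label, origin = origin)
}

# Constant window: n copies of the same (x, y, z) reading.
const_window <- function(xyz, n = 200L, label = "Walking") {
  make_window(matrix(rep(xyz, each = n), nrow = n), label)
}

# Independent histogram oracle: a literal double loop over samples and
# cells, no shared code with build_channel.
brute_channel <- function(window_data, pair, value_min, value_max, bins,
                          cap = 255L) {
  w <- (value_max - value_min) / bins
  bin_of <- function(v) {
    b <- floor((v - value_min) / w) + 1
    min(max(b, 1), bins)
  }
  out <- matrix(0L, bins, bins)
  for (t in seq_len(nrow(window_data))) {
    i <- bin_of(window_data[t, pair[1]])
    j <- bin_of(window_data[t, pair[2]])
    out[i, j] <- out[i, j] + 1L
  }
  out[out > cap] <- as.integer(cap)
  out
}

# Independent convolution oracle: direct triple-sum evaluation of the
# per-channel cross-correlation and element-wise channel summation,
# valid padding, stride 1.
brute_conv <- function(x, filters, bias = NULL) {
  a <- dim(filters)[1]; b <- dim(filters)[2]
  C <- dim(filters)[3]; nf <- dim(filters)[4]
  oh <- dim(x)[1] - a + 1L; ow <- dim(x)[2] - b + 1L
  out <- array(0, c(oh, ow, nf))
  for (f in seq_len(nf)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    s <- 0
    for (c_ in seq_len(C)) for (p in seq_len(a)) for (q in seq_len(b))
      s <- s + filters[p, q, c_, f] * x[i + p - 1, j + q - 1, c_]
    out[i, j, f] <- s + if (is.null(bias)) 0 else bias[f]
  }
  out
}

# Tiny perfectly separable image set: one bright quadrant per class.
toy_images <- function(n_per_class = 20L, size = 8L, classes = c("A", "B")) {
  n <- n_per_class * length(classes)
  imgs <- array(0, c(size, size, 3L, n))
  lab <- character(n)
  half <- size %/% 2L
  for (i in seq_len(n)) {
    cls <- ((i - 1L) %% length(classes)) + 1L
    if (cls == 1L) imgs[1:half, 1:half, , i] <- 1
    else imgs[(half + 1L):size, (half + 1L):size, , i] <- 1
    lab[i] <- classes[cls]
  }
  list(images = imgs, labels = lab)
}
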