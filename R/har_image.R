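#' Quantization specification for co-occurrence images
#'
#' Sensor values are discretized into `bins` equal-width bins over a
#' fixed, global range before histogramming, so every image has the same
#' geometry regardless of the window's own min/max. Bins are half-open
#' `[edge, edge + w)` with a closed top bin (`value_max` falls in bin
#' `bins`); out-of-range values are clipped to the border bins by default.
#'
#' The default (range \[-20, 20\], 40 bins, bin width 1) matches the stock
#' configuration: a quantization step of 0.025 on the range normalized to
#' \[0, 1\], i.e. `1/0.025 = 40` bins per axis and 40 x 40 channels. To
#' express a quantization step `Q` in raw sensor units instead, use
#' [bins_from_step()].
#'
#' @param value_min,value_max Global sensor range (default -20, 20).
#' @param bins Number of bins per axis (default 40).
#' @param clip_out_of_range If `TRUE` (default) values outside the range
#'   are clipped to the first/last bin; if `FALSE` they are an error.
#' @return An object of class `har_quant_spec` with the derived bin width
#'   `w = (value_max - value_min)/bins`.
#' @export
quantization_spec <- function(value_min = -20, value_max = 20, bins = 40L,
                              clip_out_of_range = TRUE) {
  if (!is.numeric(value_min) || !is.numeric(value_max) ||
      value_max <= value_min)
    stop("'value_max' must exceed 'value_min'")
  if (!is.numeric(bins) || length(bins) != 1L || bins < 1 ||
      bins != round(bins))
    stop("'bins' must be a positive integer")
  structure(list(value_min = value_min, value_max = value_max,
                 bins = as.integer(bins),
                 w = (value_max - value_min) / bins,
                 clip_out_of_range = isTRUE(clip_out_of_range)),
            class = "har_quant_spec")
}

#' Bin count from a quantization step in sensor units
#'
#' Given a step `Q` in the same units as the sensor range, the per-axis
#' bin count is `(value_max - value_min)/Q`, rounded to the nearest
#' integer (it must be within 1e-6 of one).
#'
#' @param Q Quantization step in sensor units (> 0).
#' @param value_min,value_max Sensor range.
#' @return Integer bin count.
#' @export
#' @examples
#' bins_from_step(1, -20, 20)      # 40
#' bins_from_step(0.025, 0, 1)     # 40 on the normalized range
bins_from_step <- function(Q, value_min = -20, value_max = 20) {
  stopifnot(is.numeric(Q), Q > 0, value_max > value_min)
  mu <- (value_max - value_min) / Q
  if (abs(mu - round(mu)) > 1e-6)
    stop("'Q' must divide the range into a whole number of bins")
  as.integer(round(mu))
}

#' Ordered axis pairs for the image channels
#'
#' All unordered pairs (a, b) with a < b in lexicographic order; for q
#' axes there are `q(q-1)/2` channels. With the usual three accelerometer
#' axes the channel order is (X,Y), (X,Z), (Y,Z).
#'
#' @param q Number of axes (>= 2).
#' @return Integer matrix with one row per pair, columns `a`, `b`
#'   (1-based axis indices).
#' @export
axis_pairs <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q))
    stop("'q' must be an integer >= 2 (no pair can be formed otherwise)")
  idx <- utils::combn(as.integer(q), 2L)
  matrix(as.integer(t(idx)), ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

#' Quantize sensor values to bin indices
#'
#' `bin = floor((v - value_min)/w) + 1`, clamped so that `v = value_max`
#' lands in the top bin `bins` (closed top bin). Out-of-range values are
#' clipped to bins 1 or `bins` when the spec allows clipping, otherwise
#' rejected with the offending value.
#'
#' @param v Numeric vector of sensor values.
#' @param spec A [quantization_spec()].
#' @return Integer vector of bin indices in `1..bins`.
#' @export
#' @examples
#' s <- quantization_spec()
#' quantize_values(c(-20, 0, 20), s)  # 1, 21, 40
quantize_values <- function(v, spec) {
  stopifnot(inherits(spec, "har_quant_spec"))
  if (any(!is.finite(v))) stop("sensor values must be finite")
  out <- (v < spec$value_min) | (v > spec$value_max)
  if (any(out) && !spec$clip_out_of_range)
    stop(sprintf("value %g outside [%g, %g] with clipping disabled",
                 v[which(out)[1]], spec$value_min, spec$value_max))
  b <- floor((v - spec$value_min) / spec$w) + 1
  b[b < 1] <- 1L
  b[b > spec$bins] <- spec$bins
  as.integer(b)
}

#' Build one co-occurrence channel from a window
#'
#' Each sample in the window contributes one dot at (bin of axis `a`,
#' bin of axis `b`); the channel is the 2D histogram of those dots with
#' counts capped at `cap` (255, the 8-bit pixel maximum). Axis `a` of the
#' pair indexes rows, axis `b` columns, so swapping the pair transposes
#' the channel. Before capping, the counts over a channel always sum to
#' the window length.
#'
#' @param window_data n x q numeric matrix of sensor values (n >= 1).
#' @param pair Length-2 integer vector of axis indices (1-based).
#' @param spec A [quantization_spec()].
#' @param cap Count cap per cell (default 255).
#' @return bins x bins integer matrix of capped counts.
#' @export
build_channel <- function(window_data, pair, spec, cap = 255L) {
  stopifnot(is.matrix(window_data), nrow(window_data) >= 1L,
            length(pair) == 2L, all(pair >= 1), all(pair <= ncol(window_data)))
  i <- quantize_values(window_data[, pair[1]], spec)
  j <- quantize_values(window_data[, pair[2]], spec)
  mu <- spec$bins
  counts <- tabulate(i + (j - 1L) * mu, nbins = mu * mu)
  counts[counts > cap] <- as.integer(cap)
  matrix(as.integer(counts), nrow = mu, ncol = mu)
}

#' Build a multi-channel HAR-Image from one window
#'
#' Stacks one capped co-occurrence channel per ordered axis pair (see
#' [axis_pairs()]) and normalizes by the cap (255), so every pixel lies
#' in \[0, 1\] and images remain comparable across windows. The image is
#' a pure function of the window's values and the spec, and invariant to
#' the order of the window's rows.
#'
#' @param window A window as produced by [slide_windows()], or any list
#'   with elements `data` (n x q matrix), `label`, and optional `origin`.
#' @param spec A [quantization_spec()].
#' @param cap Count cap per cell (default 255).
#' @return An object of class `har_image`: list with `pixels`
#'   (bins x bins x nC array in \[0, 1\]), `label`, `origin`,
#'   `channel_pairs`.
#' @export
build_har_image <- function(window, spec = quantization_spec(), cap = 255L) {
  stopifnot(is.list(window), is.matrix(window$data))
  q <- ncol(window$data)
  pairs <- axis_pairs(q)
  mu <- spec$bins
  px <- array(0, dim = c(mu, mu, nrow(pairs)))
  for (k in seq_len(nrow(pairs)))
    px[, , k] <- build_channel(window$data, pairs[k, ], spec, cap) / cap
  structure(list(pixels = px, label = window$label,
                 origin = window$origin, channel_pairs = pairs),
            class = "har_image")
}

#' Build a labeled image dataset from a list of windows
#'
#' One image per window, assembled into a single dense array for
#' efficient training, with per-class counts reported.
#'
#' @param windows List of windows ([extract_windows()] output).
#' @param spec A [quantization_spec()].
#' @param class_labels Class ordering used for the label factor; defaults
#'   to [har_activities()] restricted/extended to the labels present.
#' @param cap Count cap per cell (default 255).
#' @return List with `images` (bins x bins x nC x N array), `labels`
#'   (factor of length N), `class_counts` (named integer vector),
#'   `origins` (data frame user_id, segment_id, start), `spec`, and
#'   `channel_pairs`.
#' @export
build_image_dataset <- function(windows, spec = quantization_spec(),
                                class_labels = NULL, cap = 255L) {
  n <- length(windows)
  if (n == 0L)
    return(list(images = array(0, c(spec$bins, spec$bins, 0L, 0L)),
                labels = factor(character()),
                class_counts = integer(), origins = NULL, spec = spec,
                channel_pairs = NULL))
  q <- ncol(windows[[1]]$data)
  pairs <- axis_pairs(q)
  nC <- nrow(pairs)
  mu <- spec$bins
  images <- array(0, dim = c(mu, mu, nC, n))
  lab <- character(n)
  plane <- mu * mu
  for (t in seq_len(n)) {
    w <- windows[[t]]$data
    B <- matrix(quantize_values(as.vector(w), spec), nrow = nrow(w))
    off <- (t - 1L) * nC * plane
    for (k in seq_len(nC)) {
      counts <- tabulate(B[, pairs[k, 1]] + (B[, pairs[k, 2]] - 1L) * mu,
                         nbins = plane)
      counts[counts > cap] <- as.integer(cap)
      images[off + (k - 1L) * plane + seq_len(plane)] <- counts / cap
    }
    lab[t] <- windows[[t]]$label
  }
  if (is.null(class_labels)) {
    std <- har_activities()
    present <- unique(lab)
    class_labels <- c(std[std %in% present], setdiff(present, std))
  }
  labels <- factor(lab, levels = class_labels)
  ofield <- function(f) vapply(windows, function(w) {
    v <- w$origin[[f]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  origins <- data.frame(user_id = ofield("user_id"),
                        segment_id = ofield("segment_id"),
                        start = ofield("start"))
  list(images = images, labels = labels,
       class_counts = table(labels), origins = origins, spec = spec,
       channel_pairs = pairs)
}
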