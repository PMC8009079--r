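#' Split a sample stream into single-activity segments
#'
#' A segment is a maximal run of consecutive samples sharing the same
#' (user, activity); windows are later taken within segments only, so no
#' window ever mixes users or activities. Concatenating the segments in
#' order reproduces the input stream.
#'
#' @param samples Sample data frame in recording order.
#' @return List of segments, each a list with `user_id`, `activity` and
#'   `data` (an n x 3 matrix with columns x, y, z).
#' @export
segment_stream <- function(samples) {
  stopifnot(is.data.frame(samples))
  n <- nrow(samples)
  if (n == 0L) return(list())
  key <- paste(samples$user_id, samples$activity, sep = "\r")
  new_run <- c(TRUE, key[-1] != key[-n])
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  lapply(seq_along(starts), function(i) {
    rows <- starts[i]:ends[i]
    list(user_id = samples$user_id[starts[i]],
         activity = samples$activity[starts[i]],
         data = cbind(x = samples$x[rows], y = samples$y[rows],
                      z = samples$z[rows]))
  })
}

#' Number of sliding windows over a segment
#'
#' The window-count formula `ceiling((D - size)/stride + 1)` for a
#' recording of `D` samples. Its ceiling admits a final partial window;
#' [slide_windows()] emits complete windows only, so the two agree exactly
#' when `stride` divides `D - size` and differ by one otherwise.
#'
#' @param D Segment length in samples; must be >= `size`.
#' @param size Window length in samples (default 200 = 10 s at 20 Hz).
#' @param stride Offset between window starts in samples (default 10).
#' @return Integer window count.
#' @export
#' @examples
#' window_count(290, 200, 10)  # 10
#' window_count(295, 200, 10)  # 11 (ceiling active)
window_count <- function(D, size = 200L, stride = 10L) {
  stopifnot(size >= 1, stride >= 1)
  if (D < size) stop("'D' must be at least 'size'")
  as.integer(ceiling((D - size) / stride + 1))
}

#' Extract fixed-length sliding windows from one segment
#'
#' Complete windows only: start offsets 0, stride, 2*stride, ... with
#' `start + size <= D`. A segment shorter than `size` yields an empty
#' list. Each window's rows are a verbatim contiguous slice of the
#' segment and carry the segment's activity label.
#'
#' @param segment One element of [segment_stream()]'s result.
#' @param size,stride Window length and start offset in samples.
#' @param segment_id Optional identifier recorded in each window's origin.
#' @return List of windows, each a list with `data` (size x 3 matrix),
#'   `label`, and `origin` (user_id, segment_id, start offset, 0-based).
#' @export
slide_windows <- function(segment, size = 200L, stride = 10L,
                          segment_id = NA_integer_) {
  stopifnot(size >= 1, stride >= 1)
  D <- nrow(segment$data)
  if (D < size) return(list())
  starts <- seq.int(0L, D - size, by = stride)
  lapply(starts, function(s) {
    list(data = segment$data[(s + 1L):(s + size), , drop = FALSE],
         label = segment$activity,
         origin = list(user_id = segment$user_id, segment_id = segment_id,
                       start = s))
  })
}

#' Window an entire sample stream
#'
#' Convenience wrapper: segments the stream with [segment_stream()], then
#' applies [slide_windows()] to every segment.
#'
#' @inheritParams slide_windows
#' @param samples Sample data frame in recording order.
#' @return Flat list of windows.
#' @export
extract_windows <- function(samples, size = 200L, stride = 10L) {
  segs <- segment_stream(samples)
  out <- vector("list", length(segs))
  for (i in seq_along(segs))
    out[[i]] <- slide_windows(segs[[i]], size, stride, segment_id = i)
  unlist(out, recursive = FALSE)
}
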