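test_that("axis_pairs enumerates unordered pairs in lexicographic order", {
  p3 <- axis_pairs(3)
  expect_equal(nrow(p3), 3L)
  expect_equal(unname(p3), matrix(c(1L, 2L, 1L, 3L, 2L, 3L),
                                  ncol = 2, byrow = TRUE))
  expect_equal(nrow(axis_pairs(2)), 1L)
  p5 <- axis_pairs(5)
  expect_equal(nrow(p5), 10L)  # q(q-1)/2
  # oracle: exhaustive enumeration of pairs a < b
  all_pairs <- expand.grid(a = 1:5, b = 1:5)
  all_pairs <- all_pairs[all_pairs$a < all_pairs$b, ]
  expect_equal(nrow(p5), nrow(all_pairs))
  expect_error(axis_pairs(1), "pair")
})

test_that("quantize_values maps edges, midpoints and out-of-range correctly", {
  s <- quantization_spec(-20, 20, 40)
  expect_equal(s$w, 1)
  expect_equal(quantize_values(-20, s), 1L)     # lower edge -> first bin
  expect_equal(quantize_values(20, s), 40L)     # top bin is closed
  expect_equal(quantize_values(0, s), 21L)      # floor((0+20)/1) + 1
  expect_equal(quantize_values(c(1, 2, 3), s), c(22L, 23L, 24L))
  # clipping on by default
  expect_equal(quantize_values(c(-99, 99), s), c(1L, 40L))
  s2 <- quantization_spec(-20, 20, 40, clip_out_of_range = FALSE)
  expect_error(quantize_values(25, s2), "25")
  # quantization step in sensor units
  expect_equal(bins_from_step(1, -20, 20), 40L)
  expect_equal(bins_from_step(0.025, 0, 1), 40L)
  expect_error(bins_from_step(0.3, -20, 20), "whole")
})

test_that("build_channel places a constant window in a single cell", {
  s <- quantization_spec(-20, 20, 40)
  w <- const_window(c(1, 2, 3), n = 200)
  ch <- build_channel(w$data, c(1, 2), s)
  expect_equal(dim(ch), c(40L, 40L))
  expect_equal(sum(ch > 0), 1L)
  expect_equal(ch[22, 23], 200L)  # bins of 1 and 2
  # cap at 255 for 300 identical dots
  w300 <- const_window(c(1, 2, 3), n = 300)
  expect_equal(max(build_channel(w300$data, c(1, 2), s)), 255L)
})

test_that("build_channel equals the brute-force double loop on random windows", {
  set.seed(101)
  s <- quantization_spec(-20, 20, 40)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    w <- matrix(runif(n * 3, -20, 20), ncol = 3)
    pair <- sort(sample(1:3, 2))
    expect_identical(build_channel(w, pair, s),
                     brute_channel(w, pair, -20, 20, 40))
  }
})

test_that("channel counts conserve the window length before capping", {
  set.seed(7)
  s <- quantization_spec(-20, 20, 40)
  for (n in c(1, 50, 200, 255)) {
    w <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
    ch <- build_channel(w, c(1, 3), s)
    expect_equal(sum(ch), n)  # n <= 255: cap inactive, sum = window length
  }
})

test_that("swapping the axes of a pair transposes the channel", {
  set.seed(8)
  s <- quantization_spec(-20, 20, 40)
  w <- matrix(runif(120, -20, 20), ncol = 3)
  expect_identical(build_channel(w, c(1, 2), s),
                   t(build_channel(w, c(2, 1), s)))
})

test_that("build_har_image assembles normalized channels in the fixed order", {
  s <- quantization_spec()
  img <- build_har_image(const_window(c(1, 2, 3), n = 200), s)
  expect_equal(dim(img$pixels), c(40L, 40L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  # one nonzero entry per channel, each 200/255
  for (k in 1:3) {
    ch <- img$pixels[, , k]
    expect_equal(sum(ch > 0), 1L)
    expect_equal(max(ch), 200 / 255)
  }
  # channel order (X,Y), (X,Z), (Y,Z)
  expect_equal(unname(img$channel_pairs),
               matrix(c(1L, 2L, 1L, 3L, 2L, 3L), ncol = 2, byrow = TRUE))
  expect_equal(which(img$pixels[, , 1] > 0, arr.ind = TRUE)[1, ],
               c(row = 22L, col = 23L))
  expect_equal(which(img$pixels[, , 3] > 0, arr.ind = TRUE)[1, ],
               c(row = 23L, col = 24L))
  expect_equal(img$label, "Walking")
})

test_that("HAR-Images are invariant to the window's row order", {
  set.seed(9)
  s <- quantization_spec()
  w <- make_window(matrix(runif(600, -20, 20), ncol = 3))
  shuffled <- make_window(w$data[sample(nrow(w$data)), ])
  expect_equal(build_har_image(w, s)$pixels,
               build_har_image(shuffled, s)$pixels)
})

test_that("build_image_dataset batches windows with per-class accounting", {
  d <- generate_dataset(synth_spec(n_users = 2, segment_duration_s = 20,
                                   seed = 6))
  w <- extract_windows(d, 200, 40)
  ds <- build_image_dataset(w, quantization_spec())
  expect_equal(dim(ds$images)[4], length(w))
  expect_equal(length(ds$labels), length(w))
  win_counts <- table(vapply(w, `[[`, character(1), "label"))
  expect_equal(as.integer(ds$class_counts[names(win_counts)]),
               as.integer(win_counts))
  # consistency against the single-image builder
  one <- build_har_image(w[[5]], quantization_spec())
  expect_equal(ds$images[, , , 5], one$pixels)
  # empty input
  empty <- build_image_dataset(list(), quantization_spec())
  expect_equal(length(empty$labels), 0L)
})
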