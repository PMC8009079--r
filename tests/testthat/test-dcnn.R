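test_that("model shapes follow the conv/pool arithmetic", {
  mc <- model_config()
  expect_equal(mc$shapes$input, c(40L, 40L, 3L))
  expect_equal(mc$shapes$conv1, c(40L, 40L, 2L))  # same padding keeps 40
  expect_equal(mc$shapes$pool1, c(20L, 20L, 2L))
  expect_equal(mc$shapes$conv2, c(20L, 20L, 4L))
  expect_equal(mc$shapes$pool2, c(10L, 10L, 4L))
  expect_equal(mc$shapes$flatten, 400L)
  expect_equal(mc$shapes$dense1, 48L)
  expect_equal(mc$shapes$dense2, 24L)
  expect_equal(mc$shapes$output, 6L)
  # inconsistent geometry rejected
  expect_error(model_config(input_shape = c(2, 2, 3), pool = 4),
               "collapses")
  m <- build_model(mc)
  expect_equal(dim(m$conv[[1]]$W), c(2L, 2L, 3L, 2L))
  expect_equal(dim(m$conv[[2]]$W), c(2L, 2L, 2L, 4L))
  expect_equal(dim(m$dense[[1]]$W), c(48L, 400L))
  expect_equal(dim(m$dense[[3]]$W), c(6L, 24L))
})

test_that("an untrained model already emits valid probabilities", {
  m <- build_model(model_config(), seed = 2)
  p <- predict(m, array(0, c(40, 40, 3)), type = "prob")
  expect_equal(dim(p), c(1L, 6L))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(colnames(p), har_activities())
})

test_that("compiled first conv layer matches the reference operations", {
  set.seed(21)
  m <- build_model(model_config(input_shape = c(7, 7, 3)), seed = 5)
  for (rep in 1:10) {
    img <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
    ref <- conv2d_multichannel(img, m$conv[[1]]$W, m$conv[[1]]$b,
                               padding = "same")
    cpp <- harimage:::cpp_conv_forward(img, m$conv)
    expect_equal(cpp, ref, tolerance = 1e-10)
  }
})

test_that("compiled full forward pass matches the pure-R reference", {
  set.seed(22)
  mc <- model_config(input_shape = c(8, 8, 3), conv_filters = c(2, 4),
                     dense = c(10, 8), n_classes = 4)
  m <- build_model(mc, seed = 3)
  imgs <- array(runif(8 * 8 * 3 * 6), c(8, 8, 3, 6))
  probs <- predict(m, imgs, type = "prob")
  for (i in 1:6)
    expect_equal(as.vector(probs[i, ]), ref_forward(m, imgs[, , , i]),
                 tolerance = 1e-10)
})

test_that("training is deterministic given a seed and reduces the loss", {
  toy <- toy_images(n_per_class = 15)
  mc <- model_config(input_shape = c(8, 8, 3), conv_filters = c(2, 4),
                     dense = c(10, 8), n_classes = 2,
                     class_labels = c("A", "B"))
  tc <- training_config(epochs = 15, batch_size = 5, seed = 11)
  f1 <- train_dcnn(build_model(mc, seed = 1), toy$images, toy$labels, tc)
  f2 <- train_dcnn(build_model(mc, seed = 1), toy$images, toy$labels, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$dense[[1]]$W, f2$dense[[1]]$W)
  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
})

test_that("the model reaches 100% training accuracy on separable toy images", {
  toy <- toy_images(n_per_class = 20)
  mc <- model_config(input_shape = c(8, 8, 3), conv_filters = c(2, 4),
                     dense = c(10, 8), n_classes = 2,
                     class_labels = c("A", "B"))
  tc <- training_config(epochs = 30, batch_size = 5, seed = 7)
  fit <- train_dcnn(build_model(mc, seed = 2), toy$images, toy$labels, tc)
  pred <- predict(fit, toy$images)
  expect_equal(mean(as.character(pred) == toy$labels), 1.0)
})

test_that("prediction contracts: argmax, tie-break, batching, validation", {
  mc <- model_config(input_shape = c(8, 8, 3), dense = c(6, 4),
                     n_classes = 3, class_labels = c("a", "b", "c"))
  m <- build_model(mc, seed = 4)
  imgs <- array(runif(8 * 8 * 3 * 5), c(8, 8, 3, 5))
  probs <- predict(m, imgs, type = "prob")
  labs <- predict(m, imgs)
  expect_length(labs, 5L)
  expect_equal(as.integer(labs), apply(probs, 1, which.max))
  # exact tie resolves to the lowest class index (which.max semantics)
  expect_equal(which.max(c(0.3, 0.4, 0.4)), 2L)
  # shape mismatch rejected
  expect_error(predict(m, array(0, c(5, 5, 3))), "match")
  # label validation at training time
  expect_error(train_dcnn(m, imgs, c("a", "b", "zz", "a", "b"),
                          training_config(epochs = 1)), "unknown")
  expect_error(train_dcnn(m, imgs, c(0L, 1L, 2L, 3L, 0L),
                          training_config(epochs = 1)), "0, n_classes")
})
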