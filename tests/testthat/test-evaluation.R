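test_that("confusion_matrix tallies actual x predicted counts", {
  labs <- c("A", "B")
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), labs)
  expect_equal(unname(unclass(cm)),
               matrix(c(1L, 1L, 0L, 1L), 2, byrow = TRUE))
  expect_equal(sum(cm), 3L)
  # perfect prediction -> diagonal
  perf <- confusion_matrix(rep(labs, 5), rep(labs, 5), labs)
  expect_equal(sum(diag(perf)), 10L)
  expect_equal(sum(perf) - sum(diag(perf)), 0L)
  expect_error(confusion_matrix("A", "Q", labs), "unknown")
})

test_that("ovr_counts partitions the total for every class", {
  cm <- wisdm_reference_confusion()
  k <- ovr_counts(cm, "Upstairs")
  expect_equal(unname(k["TP"]), 11483L)
  expect_equal(unname(k["FN"]), 183L)
  expect_equal(unname(k["FP"]), 100L)
  expect_equal(sum(k), sum(cm))
  for (c_ in 1:6) expect_equal(sum(ovr_counts(cm, c_)), sum(cm))
  # identity matrix: no errors anywhere
  id <- diag(5L) * 7L
  for (c_ in 1:5) {
    k <- ovr_counts(id, c_)
    expect_equal(unname(k[c("FP", "FN")]), c(0L, 0L))
  }
})

test_that("class_metrics reproduces known values and bounds", {
  cm <- wisdm_reference_confusion()
  m <- class_metrics(cm)
  expect_equal(round(m$sensitivity[m$class == "Upstairs"], 3), 0.984)
  expect_equal(round(m$precision[m$class == "Downstairs"], 3), 0.988)
  vals <- as.matrix(m[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
  # AUC is identically the sensitivity/specificity average
  expect_equal(m$auc, (m$sensitivity + m$specificity) / 2)
  # F-measure is the harmonic mean of sensitivity and precision
  expect_equal(m$f_measure, 2 * m$sensitivity * m$precision /
                              (m$sensitivity + m$precision))
  # identity confusion matrix: every metric is 1
  perfect <- class_metrics(diag(6L) * 10L)
  expect_true(all(as.matrix(perfect[, -1]) == 1))
  # zero denominator surfaces as NaN, not silently 0
  degenerate <- matrix(c(0L, 0L, 5L, 5L), 2, 2, byrow = TRUE)
  expect_warning(dm <- class_metrics(degenerate), "undefined")
  expect_true(is.nan(dm$sensitivity[1]))
})

test_that("metrics_summary averages lie within per-class ranges", {
  m <- class_metrics(wisdm_reference_confusion())
  s <- metrics_summary(m)
  for (i in seq_len(nrow(s))) {
    col <- m[[s$metric[i]]]
    expect_gte(s$mean[i], min(col))
    expect_lte(s$mean[i], max(col))
  }
  # identical per-class metrics -> sd 0, degenerate interval
  same <- m; same[, -1] <- lapply(same[, -1], function(x) rep(0.9, 6))
  s2 <- metrics_summary(same)
  expect_true(all(s2$sd == 0))
  expect_equal(s2$ci95_lower, s2$ci95_upper)
  expect_equal(s2$mean, rep(0.9, 6))
})

test_that("stratified_kfold partitions every class evenly and reproducibly", {
  labels <- rep(c("A", "B", "C"), times = c(100, 55, 23))
  f <- stratified_kfold(labels, k = 10, seed = 3)
  expect_length(f, length(labels))
  expect_setequal(unique(f), 1:10)
  # within each class fold sizes differ by at most 1
  for (cl in c("A", "B", "C")) {
    sizes <- table(f[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # folds partition the index set
  expect_equal(sort(unlist(lapply(1:10, function(k) which(f == k)))),
               seq_along(labels))
  expect_identical(f, stratified_kfold(labels, 10, seed = 3))
  expect_false(identical(f, stratified_kfold(labels, 10, seed = 4)))
  expect_error(stratified_kfold(c("A", rep("B", 20)), 10), "A")
})

test_that("cross_validate pools every sample exactly once and aces a separable task", {
  toy <- toy_images(n_per_class = 30)
  mc <- model_config(input_shape = c(8, 8, 3), conv_filters = c(2, 4),
                     dense = c(10, 8), n_classes = 2,
                     class_labels = c("A", "B"))
  tc <- training_config(epochs = 15, batch_size = 5, seed = 5)
  res <- cross_validate(toy$images, toy$labels, mc, tc, k = 3)
  expect_equal(sum(res$confusion), 60L)
  # per-fold class proportions match overall within 1 sample
  for (k in 1:3)
    expect_lte(max(abs(table(toy$labels[res$folds == k]) - 10)), 1)
  # disjoint supports -> pooled accuracy 1
  expect_equal(sum(diag(res$confusion)), 60L)
  expect_equal(mean(res$metrics$accuracy), 1.0)
})
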