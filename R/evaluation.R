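#' Multi-class confusion matrix
#'
#' Rows are the actual class, columns the predicted class, in the fixed
#' order of `labels`; cell (i, j) counts samples of actual class i
#' predicted as class j.
#'
#' @param y_true,y_pred Equal-length vectors of class labels (character
#'   or factor). Labels outside `labels` are an error.
#' @param labels Class ordering (default [har_activities()]).
#' @return n x n integer matrix of class `har_confusion` with dimnames
#'   `actual` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = har_activities()) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  m <- matrix(as.integer(cm), nrow = length(labels),
              dimnames = list(actual = labels, predicted = labels))
  structure(m, class = c("har_confusion", "matrix", "array"))
}

.as_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  if (is.null(rownames(cm)))
    rownames(cm) <- colnames(cm) %||% paste0("class", seq_len(nrow(cm)))
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-vs-rest counts for a class
#'
#' Reduces the multi-class matrix to binary counts for class `c`: TP is
#' the diagonal cell, FN the rest of its row (its samples predicted
#' elsewhere), FP the rest of its column (other samples predicted as it),
#' TN everything else. The four always partition the total.
#'
#' @param cm Confusion matrix (rows actual, columns predicted).
#' @param class Class index (1-based) or label.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
ovr_counts <- function(cm, class) {
  cm <- .as_confusion(cm)
  if (is.character(class)) class <- match(class, rownames(cm))
  stopifnot(!is.na(class), class >= 1, class <= nrow(cm))
  tp <- unname(cm[class, class])
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

.metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                   "auc", "f_measure")

#' Per-class one-vs-rest metrics
#'
#' For every class, the six standard ratios from the one-vs-rest counts:
#' accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), AUC = (sensitivity+specificity)/2
#' (balanced accuracy, *not* a ROC area), and the F-measure, the harmonic
#' mean of sensitivity and precision. Values are returned at full
#' precision; round at display time only. A zero denominator yields `NaN`
#' (flagged, never silently 0) with a warning.
#'
#' @param cm Confusion matrix (rows actual, columns predicted).
#' @return Data frame with one row per class and the six metric columns,
#'   all in \[0, 1\] where defined.
#' @export
class_metrics <- function(cm) {
  cm <- .as_confusion(cm)
  n <- nrow(cm)
  out <- matrix(NA_real_, n, length(.metric_names),
                dimnames = list(rownames(cm), .metric_names))
  for (c_ in seq_len(n)) {
    k <- ovr_counts(cm, c_)
    tot <- sum(k)
    div <- function(num, den) if (den == 0) NaN else num / den
    sens <- div(k["TP"], k["TP"] + k["FN"])
    spec <- div(k["TN"], k["TN"] + k["FP"])
    prec <- div(k["TP"], k["TP"] + k["FP"])
    out[c_, ] <- c(div(k["TP"] + k["TN"], tot), sens, spec, prec,
                   (sens + spec) / 2,
                   if (is.nan(sens) || is.nan(prec)) NaN
                   else div(2 * sens * prec, sens + prec))
  }
  if (any(is.nan(out)))
    warning("zero denominator: some metrics are undefined (NaN)")
  df <- as.data.frame(out)
  df <- cbind(class = rownames(cm), df)
  rownames(df) <- NULL
  df
}

#' Summary rows across classes
#'
#' Per-metric mean, sample standard deviation, the normal-theory 95%
#' interval `mean +/- 1.96 sd/sqrt(n_classes)`, and the `mean +/- sd`
#' band. Both interval conventions are reported because neither is
#' canonical for this kind of table.
#'
#' @param metrics Data frame from [class_metrics()] (>= 2 classes).
#' @return Data frame with one row per metric and columns `mean`, `sd`,
#'   `ci95_lower`, `ci95_upper`, `sd_lower`, `sd_upper`.
#' @export
metrics_summary <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2L)
  vals <- as.matrix(metrics[, .metric_names])
  n <- nrow(vals)
  mu <- colMeans(vals)
  s <- apply(vals, 2L, sd)
  half <- 1.96 * s / sqrt(n)
  data.frame(metric = .metric_names, mean = unname(mu), sd = unname(s),
             ci95_lower = unname(mu - half), ci95_upper = unname(mu + half),
             sd_lower = unname(mu - s), sd_upper = unname(mu + s))
}

#' Stratified k-fold assignment
#'
#' Shuffles the indices of each class (with `seed`) and deals them
#' round-robin over k folds, so within every class the fold sizes differ
#' by at most one and the folds partition the data.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is reproducible.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("class(es) with fewer than k samples: ",
         paste(small, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the image classifier
#'
#' For each fold, trains a fresh model (initialized from
#' `seed + fold index`) on the other k-1 folds and predicts the held-out
#' fold; the held-out predictions are pooled into a single confusion
#' matrix covering every sample exactly once, from which the one-vs-rest
#' metrics and their summary are computed.
#'
#' @param images rows x cols x channels x N array.
#' @param labels Length-N labels (factor or character).
#' @param mc A [model_config()].
#' @param tc A [training_config()]; its `seed` also drives the fold
#'   assignment and per-fold weight initialization.
#' @param k Number of folds (default 10).
#' @param folds Optional precomputed fold vector (overrides `k`/seed).
#' @param verbose Print per-fold progress.
#' @return List with `confusion` (pooled matrix), `metrics`
#'   ([class_metrics()]), `summary` ([metrics_summary()]), `folds`, and
#'   `fold_accuracy` (held-out accuracy per fold).
#' @export
cross_validate <- function(images, labels, mc = model_config(),
                           tc = training_config(), k = 10L, folds = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(mc, "har_model_config"),
            inherits(tc, "har_training_config"))
  d <- dim(images)
  stopifnot(length(d) == 4L)
  labels <- as.character(labels)
  stopifnot(length(labels) == d[4])
  if (is.null(folds)) folds <- stratified_kfold(labels, k, tc$seed)
  k <- max(folds)
  pred <- character(length(labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- build_model(mc, seed = tc$seed + f)
    model <- train_dcnn(model, images[, , , !test, drop = FALSE],
                        labels[!test], tc)
    p <- predict(model, images[, , , test, drop = FALSE])
    pred[test] <- as.character(p)
    fold_acc[f] <- mean(pred[test] == labels[test])
    if (verbose)
      message(sprintf("fold %d/%d: held-out accuracy %.4f", f, k,
                      fold_acc[f]))
  }
  cm <- confusion_matrix(labels, pred, mc$class_labels)
  metrics <- class_metrics(cm)
  list(confusion = cm, metrics = metrics,
       summary = metrics_summary(metrics), folds = folds,
       fold_accuracy = fold_acc)
}

#' Reference pooled confusion matrix on WISDM v1.1
#'
#' The published pooled confusion matrix of a 10-fold cross-validation
#' of this method on the full WISDM v1.1 dataset (105,205 co-occurrence
#' images; rows actual, columns predicted). Bundled so the metric
#' pipeline can be exercised against known results without downloading
#' the dataset: applying [class_metrics()] and [metrics_summary()] to it
#' reproduces the published per-class metric table at 3-decimal
#' rounding.
#'
#' @return 6 x 6 integer matrix of class `har_confusion`.
#' @export
#' @examples
#' round(class_metrics(wisdm_reference_confusion())$sensitivity, 3)
wisdm_reference_confusion <- function() {
  labels <- har_activities()
  m <- matrix(c(
    32425,     7,     7,    0,    0,    0,
        0, 41648,    27,   44,    0,    0,
       37,    73, 11483,   73,    0,    0,
        5,    58,    65, 9300,    0,    0,
        0,     0,     1,    0, 5542,   19,
        0,     0,     0,    0,    3, 4388),
    nrow = 6, byrow = TRUE,
    dimnames = list(actual = labels, predicted = labels))
  structure(m, class = c("har_confusion", "matrix", "array"))
}
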