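#' Euclidean distance between two beats
#'
#' @param y,z Numeric vectors of equal length.
#' @export
knn_distance <- function(y, z) {
  if (length(y) != length(z)) stop("vectors must have equal length", call. = FALSE)
  sqrt(sum((y - z)^2))
}

#' Nearest-neighbour classification of a single beat
#'
#' k = 1 by default, as in the reference protocol. Distance ties are broken
#' toward the lower training-row index; for k > 1, majority vote with label
#' ties broken toward the smaller label in sort order.
#'
#' @param train Training matrix, one beat per row.
#' @param labels Training labels.
#' @param query One query beat (numeric vector).
#' @param k Neighbour count (<= nrow(train)).
#' @return The predicted label.
#' @export
knn_classify <- function(train, labels, query, k = 1L) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  if (k > nrow(train)) stop("k exceeds the training-set size", call. = FALSE)
  d <- sqrt(rowSums(sweep(train, 2L, query)^2))
  if (k == 1L) return(labels[which.min(d)])
  ord <- order(d, seq_along(d))[seq_len(k)]
  tab <- table(labels[ord])
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1L]
}

# batch 1-NN used by the CV wrapper and the evaluation harness; same
# first-index tie rule as knn_classify (max.col ties.method = "first")
knn_predict1 <- function(train, labels, test) {
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
  labels[max.col(-d2, ties.method = "first")]
}

#' Confusion counts for a binary evaluation
#'
#' NOTE the polarity: in the reference protocol the NORMAL class is the
#' positive one (TP counts correctly classified normal beats, TN correctly
#' classified abnormal beats) — the opposite of the usual clinical
#' convention where disease is positive. The standard confusion mapping is
#' used (FP = beat predicted positive whose truth is negative, FN the
#' converse); change `positive` to flip the polarity.
#'
#' @param predicted,truth Equal-length label vectors over exactly two classes.
#' @param positive The positive label (default `"normal"`).
#' @return An object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion <- function(predicted, truth, positive = "normal") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  classes <- unique(c(predicted, truth))
  if (length(classes) > 2L)
    stop("confusion counts are defined for binary labels only", call. = FALSE)
  if (!positive %in% classes)
    stop(sprintf("positive label '%s' not present", positive), call. = FALSE)
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(
    TP = sum(is_pos & pred_pos),
    TN = sum(!is_pos & !pred_pos),
    FP = sum(!is_pos & pred_pos),
    FN = sum(is_pos & !pred_pos),
    positive = positive
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (positive = %s): TP=%d TN=%d FP=%d FN=%d\n",
              x$positive, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined: zero denominator", what))
    return(NA_real_)
  }
  100 * num / den
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' `sensitivity = 100 TP / (TP + FN)`, `specificity = 100 TN / (TN + FP)`,
#' `accuracy = 100 (TP + TN) / (TP + TN + FP + FN)`. A zero denominator
#' yields `NA` with a warning rather than an error.
#'
#' @param counts A [confusion()] result.
#' @return Percentage (numeric scalar).
#' @export
sensitivity <- function(counts) metric_ratio(counts$TP, counts$TP + counts$FN, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(counts) metric_ratio(counts$TN, counts$TN + counts$FP, "specificity")

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  metric_ratio(counts$TP + counts$TN,
               counts$TP + counts$TN + counts$FP + counts$FN, "accuracy")
}

# stratified train/test split, seeded; returns logical train membership
stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round_half_up(train_frac * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Train/test evaluation of a masked beat matrix
#'
#' Masks the beat columns, splits the beats into stratified train/test sets
#' (seeded, so a seed fully determines the report), fits the named
#' classifier and reports confusion counts plus sensitivity / specificity /
#' accuracy. Only the built-in nearest-neighbour classifier is available in
#' this build; the `svm` / `mlp-lm` / `mlp-scg` comparator ids are reserved
#' for external implementations and raise an informative error when their
#' backing packages are absent.
#'
#' @param beats Beat matrix (numeric matrix or [beat_matrix()]).
#' @param labels Per-beat labels (ignored when `beats` is a [beat_matrix()]).
#' @param mask A [feature_mask()] or integer column indices; `NULL` keeps all
#'   columns.
#' @param classifier `"knn"` (built in) or a reserved comparator id.
#' @param train_frac Training fraction (default 0.64, mirroring the
#'   1800-of-2806 protocol split).
#' @param seed Split seed.
#' @param k Neighbour count for the built-in classifier.
#' @param positive Positive label for the confusion mapping.
#' @return An object of class `classification_report`.
#' @export
evaluate_pipeline <- function(beats, labels = NULL, mask = NULL,
                              classifier = "knn", train_frac = 0.64,
                              seed = 1L, k = 1L, positive = "normal") {
  if (inherits(beats, "beat_matrix")) {
    labels <- beats$labels
    beats <- beats$beats
  }
  beats <- as.matrix(beats)
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need at least two classes to evaluate", call. = FALSE)
  if (!classifier %in% c("knn", "svm", "mlp-lm", "mlp-scg"))
    stop(sprintf("unknown classifier id '%s'", classifier), call. = FALSE)
  if (classifier != "knn")
    stop(sprintf(paste0("classifier '%s' is an external comparator and its ",
                        "backing package is not installed; use 'knn'"),
                 classifier), call. = FALSE)
  cols <- if (is.null(mask)) seq_len(ncol(beats)) else
    if (inherits(mask, "feature_mask")) mask$indices else as.integer(mask)
  if (any(cols < 1L) || any(cols > ncol(beats)))
    stop("mask indices out of range", call. = FALSE)
  X <- beats[, cols, drop = FALSE]
  tr <- stratified_split(labels, train_frac, seed)
  pred <- if (k == 1L) {
    knn_predict1(X[tr, , drop = FALSE], labels[tr], X[!tr, , drop = FALSE])
  } else {
    apply(X[!tr, , drop = FALSE], 1L, function(q)
      knn_classify(X[tr, , drop = FALSE], labels[tr], q, k = k))
  }
  counts <- confusion(pred, labels[!tr], positive = positive)
  structure(list(
    counts = counts,
    sensitivity = sensitivity(counts),
    specificity = specificity(counts),
    accuracy = accuracy(counts),
    classifier = classifier, k = k,
    mask = cols, n_train = sum(tr), n_test = sum(!tr),
    train_frac = train_frac, seed = as.integer(seed),
    positive = positive
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%s, %d train / %d test, seed %d)\n",
              x$classifier, x$n_train, x$n_test, x$seed))
  print(x$counts)
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
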