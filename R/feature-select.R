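#' Ordered feature subset
#'
#' @param indices Strictly increasing 1-based column indices.
#' @param D Total feature count.
#' @export
feature_mask <- function(indices, D) {
  indices <- as.integer(indices)
  D <- as.integer(D)
  if (!length(indices)) stop("a mask must select at least one feature", call. = FALSE)
  if (anyDuplicated(indices)) stop("mask indices must be unique", call. = FALSE)
  if (is.unsorted(indices, strictly = TRUE))
    stop("mask indices must be strictly increasing", call. = FALSE)
  if (indices[1L] < 1L || indices[length(indices)] > D)
    stop("mask indices must lie in 1..D", call. = FALSE)
  structure(list(indices = indices, k = length(indices), D = D),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("Feature mask: %d of %d features: %s\n", x$k, x$D,
              paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Map a continuous bat position to a k-feature mask
#'
#' The k columns with the largest position magnitudes are selected;
#' magnitude ties break toward the lower index, so the mapping is
#' deterministic. This keeps the continuous move equations meaningful while
#' still producing a discrete subset.
#'
#' @param x Position vector of length D.
#' @param k Subset size, `1 <= k <= D`.
#' @return A [feature_mask()].
#' @export
position_to_mask <- function(x, k) {
  D <- length(x)
  k <- as.integer(k)
  if (k < 1L || k > D) stop("k must lie in 1..D", call. = FALSE)
  ord <- order(-abs(x), seq_len(D))[seq_len(k)]
  feature_mask(sort(ord), D)
}

# stratified fold assignment, fixed before optimization so the wrapper
# fitness is a pure function of the mask
make_folds <- function(labels, nfolds = 5L, seed = 1L) {
  if (length(unique(labels)) < 2L)
    stop("wrapper fitness needs at least two classes", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Cross-validated 1-NN wrapper fitness of a feature mask
#'
#' The misclassification rate of a nearest-neighbour classifier on the
#' masked columns, estimated by stratified k-fold cross-validation with a
#' fold assignment fixed up front — so for a given dataset and fold spec the
#' fitness is a deterministic function of the mask alone, in \[0, 1\],
#' lower is better. This supplies the class information that a
#' position-only benchmark fitness cannot.
#'
#' @param mask A [feature_mask()] (or plain index vector).
#' @param beats Beat matrix (numeric matrix or [beat_matrix()]).
#' @param labels Per-beat labels (taken from `beats` if it is a
#'   [beat_matrix()]).
#' @param folds Integer fold assignment per beat; built from `nfolds` and
#'   `fold_seed` when omitted.
#' @param nfolds,fold_seed Fold construction parameters.
#' @return Misclassification rate in \[0, 1\].
#' @export
wrapper_fitness <- function(mask, beats, labels = NULL, folds = NULL,
                            nfolds = 5L, fold_seed = 1L) {
  if (inherits(beats, "beat_matrix")) {
    labels <- beats$labels
    beats <- beats$beats
  }
  beats <- as.matrix(beats)
  cols <- if (inherits(mask, "feature_mask")) mask$indices else as.integer(mask)
  if (any(cols < 1L) || any(cols > ncol(beats)))
    stop("mask indices out of range for this beat matrix", call. = FALSE)
  if (is.null(folds)) folds <- make_folds(labels, nfolds, fold_seed)
  X <- beats[, cols, drop = FALSE]
  wrong <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred <- knn_predict1(X[!te, , drop = FALSE], labels[!te], X[te, , drop = FALSE])
    wrong <- wrong + sum(pred != labels[te])
  }
  wrong / length(labels)
}

#' Benchmark fitness on the raw position
#'
#' Delegates to [rosenbrock()] on the bat's position vector. Retained for
#' fidelity with the original formulation, where the swarm fitness is the
#' Rosenbrock value of the position; note that it is label-blind by
#' construction — permuting the class labels cannot change it, so it carries
#' no class information into the selection.
#'
#' @param x Position vector.
#' @export
rosenbrock_fitness <- function(x) rosenbrock(x)

#' Select k of D beat features with a bat-algorithm optimizer
#'
#' Runs the standard or improved bat algorithm over D-dimensional continuous
#' positions; each position is decoded by [position_to_mask()] and scored
#' either by the cross-validated 1-NN wrapper error (default) or by the
#' label-blind benchmark fitness. Fold assignment is fixed from the config
#' seed before optimization, and repeated wrapper evaluations of the same
#' mask are cached. Same config and seed give the same mask.
#'
#' @param beats Beat matrix (numeric matrix or [beat_matrix()]).
#' @param labels Per-beat labels.
#' @param k Subset size (20 in the reference protocol, with D = 200).
#' @param config A [swarm_config()] with `dim = ncol(beats)`; a default
#'   config (25 bats, 30 generations, bounds \[-1, 1\]) is built when
#'   omitted.
#' @param mode Fitness mode, `"wrapper"` or `"rosenbrock"`.
#' @param optimizer `"iba"` (default) or `"ba"`.
#' @param nfolds Folds for the wrapper fitness.
#' @param seed Seed used when `config` is omitted.
#' @param fold_seed Seed of the wrapper-fitness fold assignment; defaults to
#'   the config seed. Fix it across runs to make fitnesses comparable
#'   between optimizers, seeds and the exhaustive oracle.
#' @return A list of class `selection_result`: `mask`, `fitness`, `trace`,
#'   `mode`, `optimizer`, `config`.
#' @export
select_features <- function(beats, labels = NULL, k = 20L, config = NULL,
                            mode = c("wrapper", "rosenbrock"),
                            optimizer = c("iba", "ba"), nfolds = 5L,
                            seed = 1L, fold_seed = NULL) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer)
  if (inherits(beats, "beat_matrix")) {
    labels <- beats$labels
    beats <- beats$beats
  }
  beats <- as.matrix(beats)
  D <- ncol(beats)
  k <- as.integer(k)
  if (k < 1L || k > D) stop("k must lie in 1..D", call. = FALSE)
  if (is.null(config))
    config <- swarm_config(dim = D, bounds = c(-1, 1), seed = seed)
  if (config$dim != D)
    stop("config$dim must equal the beat width", call. = FALSE)

  if (mode == "wrapper") {
    if (is.null(fold_seed)) fold_seed <- config$seed
    folds <- make_folds(labels, nfolds, seed = fold_seed)
    cache <- new.env(parent = emptyenv())
    objective <- function(x) {
      m <- position_to_mask(x, k)
      key <- paste(m$indices, collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- wrapper_fitness(m, beats, labels, folds = folds)
      cache[[key]] <- val
      val
    }
  } else {
    objective <- rosenbrock_fitness
  }

  res <- run_optimizer(config, objective, mode = optimizer)
  structure(list(
    mask = position_to_mask(res$best_position, k),
    fitness = res$best_fitness,
    trace = res$trace,
    mode = mode, optimizer = optimizer, config = config
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection (%s, %s fitness): fitness %.4g\n",
              toupper(x$optimizer), x$mode, x$fitness))
  print(x$mask)
  invisible(x)
}

#' Brute-force best k-subset under the wrapper fitness
#'
#' Enumerates every k-subset of the D columns (refusing when `choose(D, k)`
#' exceeds `cap`) and returns the wrapper-fitness optimum. Enumeration is in
#' lexicographic order and only strict improvements are kept, so ties
#' resolve to the lexicographically smallest index list. Serves as the
#' independent optimum oracle for the swarm selectors on small instances.
#'
#' @inheritParams wrapper_fitness
#' @param k Subset size.
#' @param cap Enumeration cap (default 1e5 subsets).
#' @return List: `mask` ([feature_mask()]), `fitness`, `n_evaluated`.
#' @export
exhaustive_best_subset <- function(beats, labels = NULL, k, folds = NULL,
                                   nfolds = 5L, fold_seed = 1L, cap = 1e5) {
  if (inherits(beats, "beat_matrix")) {
    labels <- beats$labels
    beats <- beats$beats
  }
  beats <- as.matrix(beats)
  D <- ncol(beats)
  k <- as.integer(k)
  if (k < 1L || k > D) stop("k must lie in 1..D", call. = FALSE)
  n_sub <- choose(D, k)
  if (n_sub > cap)
    stop(sprintf("choose(%d, %d) = %g exceeds the enumeration cap %g",
                 D, k, n_sub, cap), call. = FALSE)
  if (is.null(folds)) folds <- make_folds(labels, nfolds, fold_seed)
  subsets <- utils::combn(D, k)
  best <- NULL
  best_fit <- Inf
  for (i in seq_len(ncol(subsets))) {
    fit <- wrapper_fitness(subsets[, i], beats, labels, folds = folds)
    if (fit < best_fit) {
      best_fit <- fit
      best <- subsets[, i]
    }
  }
  list(mask = feature_mask(best, D), fitness = best_fit,
       n_evaluated = ncol(subsets))
}
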