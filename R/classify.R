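#' Evaluation configuration
#'
#' @param k_neighbors neighbours for the KNN vote (default 5).
#' @param n_folds cross-validation folds (default 5); fivefold CV is the
#'   headline protocol, a single stratified 80/20 split is available via
#'   `protocol = "split"` with `test_fraction`.
#' @param test_fraction held-out fraction for the split protocol
#'   (default 0.2).
#' @param protocol `"cv"` or `"split"`.
#' @param seed seed for fold assignment / split.
#' @return An `eval_config` object.
#' @export
eval_config <- function(k_neighbors = 5L, n_folds = 5L, test_fraction = 0.2,
                        protocol = c("cv", "split"), seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(k_neighbors >= 1, n_folds >= 2,
            test_fraction > 0, test_fraction < 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_folds = as.integer(n_folds),
                 test_fraction = test_fraction, protocol = protocol,
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Theoretical chance-level accuracy
#'
#' @param n_classes number of classes (>= 1).
#' @return `1 / n_classes`; 0.125 for the default eight-object set.
#' @examples
#' chance_level(8)
#' @export
chance_level <- function(n_classes) {
  stopifnot(length(n_classes) == 1, n_classes >= 1)
  1 / n_classes
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin so every trial lands in exactly one validation fold and
# every class appears in every training fold (given >= n_folds trials/class).
make_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# KNN from a (n_test x n_train) distance matrix. Majority vote among the k
# nearest training trials; a tied vote is broken by the label of the
# smallest-distance neighbour among the tied labels (deterministic).
knn_predict <- function(dist_test_train, train_labels, k) {
  k <- min(k, length(train_labels))
  apply(dist_test_train, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    train_labels[nn[train_labels[nn] %in% top][1]]
  })
}

euclidean_cross_dist <- function(a, b) {
  # n_a x n_b matrix of Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Shared evaluation harness. predict_fun(train_idx, test_idx) -> predicted
# labels for test_idx.
evaluate_protocol <- function(labels, config, predict_fun, condition = "") {
  classes <- sort(unique(labels))
  run_fold <- function(train_idx, test_idx) {
    if (length(test_idx) == 0)
      stop("empty validation fold: reduce n_folds below the smallest ",
           "per-class trial count")
    missing <- setdiff(classes, labels[train_idx])
    if (length(missing) > 0)
      stop("class(es) absent from a training fold: ",
           paste(missing, collapse = ", "))
    predict_fun(train_idx, test_idx)
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  if (config$protocol == "cv") {
    fold <- make_folds(labels, config$n_folds, config$seed)
    per_fold <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(fold == f)
      pred <- run_fold(which(fold != f), test_idx)
      per_fold[f] <- mean(pred == labels[test_idx])
      for (i in seq_along(test_idx))
        confusion[labels[test_idx[i]], pred[i]] <-
          confusion[labels[test_idx[i]], pred[i]] + 1L
    }
  } else {
    # stratified 80/20 split: reuse the fold dealer with 1/test_fraction folds
    fold <- make_folds(labels, max(2L, round(1 / config$test_fraction)),
                       config$seed)
    test_idx <- which(fold == 1L)
    pred <- run_fold(which(fold != 1L), test_idx)
    per_fold <- mean(pred == labels[test_idx])
    for (i in seq_along(test_idx))
      confusion[labels[test_idx[i]], pred[i]] <-
        confusion[labels[test_idx[i]], pred[i]] + 1L
  }
  structure(list(accuracy = mean(per_fold), per_fold = per_fold,
                 confusion = confusion, condition = condition),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.3f (folds: %s)%s\n", x$accuracy,
              paste(sprintf("%.2f", x$per_fold), collapse = " "),
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Rate-code classification: PCA + KNN on spike counts
#'
#' For each training fold a 3-component PCA is fitted on the training
#' spike-count features only (channels standardised to unit training
#' variance first, so high-variance channels cannot monopolise the leading
#' components); training and held-out trials are projected with that fit
#' (no leakage) and the held-out trials are classified by majority vote of
#' their `k_neighbors` nearest (Euclidean) training trials.
#'
#' @param features numeric matrix (trials x channels), e.g. from
#'   [spike_count_features()].
#' @param labels character/factor vector of trial labels.
#' @param config an [eval_config()].
#' @param n_components principal components kept (default 3).
#' @param standardize standardise channels before PCA (default `TRUE`).
#' @param condition free-text descriptor stored in the result.
#' @return An `eval_result`: `accuracy` (mean over folds), `per_fold`,
#'   `confusion` (truth x predicted counts), `condition`.
#' @export
knn_rate <- function(features, labels, config = eval_config(),
                     n_components = 3L, standardize = TRUE,
                     condition = "rate") {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  n_components <- min(n_components, ncol(features))
  evaluate_protocol(labels, config, function(train_idx, test_idx) {
    fit <- suppressWarnings(pca_fit(features[train_idx, , drop = FALSE],
                                    n_components, scale = standardize))
    tr <- pca_project(fit, features[train_idx, , drop = FALSE])
    te <- pca_project(fit, features[test_idx, , drop = FALSE])
    knn_predict(euclidean_cross_dist(te, tr), labels[train_idx],
                config$k_neighbors)
  }, condition = condition)
}

#' Temporal-code classification: KNN on a precomputed distance matrix
#'
#' Same fold protocol as [knn_rate()], but a held-out trial's neighbours are
#' the training trials with the smallest population Victor-Purpura distance.
#'
#' @param distances symmetric `n x n` distance matrix, e.g. from
#'   [population_vp_matrix()].
#' @inheritParams knn_rate
#' @return An `eval_result`.
#' @export
knn_temporal <- function(distances, labels, config = eval_config(),
                         condition = "temporal") {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances),
            nrow(distances) == length(labels))
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  evaluate_protocol(labels, config, function(train_idx, test_idx) {
    knn_predict(distances[test_idx, train_idx, drop = FALSE],
                labels[train_idx], config$k_neighbors)
  }, condition = condition)
}

#' Classification from a channel subpopulation
#'
#' Restricts the population response to the named afferent kinds (any of
#' `"NOC"`, `"SA1"`, `"RA1"` or combinations) before spike-count feature
#' extraction, then runs the rate-code classifier. Used to measure the
#' contribution of each afferent class and their synergies; apply it to the
#' Group-I (cones) and Group-II (cubes) trial subsets separately to mirror
#' the per-group contribution analysis.
#'
#' @param responses list of `population_response`.
#' @param labels trial labels.
#' @param kinds non-empty character vector of channel kinds to keep.
#' @param window_ms spike-count window (default `(0, 500]`).
#' @inheritParams knn_rate
#' @return An `eval_result` with the kinds recorded in `condition`.
#' @export
subpopulation_eval <- function(responses, labels, kinds,
                               window_ms = c(0, 500),
                               config = eval_config(), n_components = 3L) {
  stopifnot(length(kinds) >= 1)
  counts <- spike_count_features(responses, window_ms)
  keep <- attr(counts, "kinds") %in% kinds
  if (!any(keep)) stop("no channels of the requested kind(s): ",
                       paste(kinds, collapse = "+"))
  knn_rate(counts[, keep, drop = FALSE], labels, config,
           n_components = min(n_components, sum(keep)),
           condition = paste(sort(kinds), collapse = "+"))
}
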