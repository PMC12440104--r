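#' K-nearest-neighbor class probabilities
#'
#' Predicted probability of the positive class is the fraction of the k
#' Euclidean-nearest training points that are positive. Distance ties
#' are broken by training-set order (earlier rows win). Features are
#' used as-is (no standardization) unless \code{standardize}.
#'
#' @param train_x numeric matrix of training features.
#' @param train_y logical (or 0/1) training labels.
#' @param test_x numeric matrix with the same columns.
#' @param k number of neighbors (default 5).
#' @param standardize center/scale features by training mean and sd.
#' @return Numeric vector of positive-class probabilities, one per test
#'   row.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5,
                        standardize = FALSE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(train_x)) stop("k exceeds the number of training points")
  y <- as.logical(train_y)
  if (standardize) {
    mu <- colMeans(train_x)
    sd_ <- apply(train_x, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sd_, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sd_, "/")
  }
  apply(test_x, 1, function(p) {
    d <- sqrt(colSums((t(train_x) - p)^2))
    nn <- order(d)[seq_len(k)]  # order() is stable: ties keep row order
    mean(y[nn])
  })
}

.roc_points <- function(prob, truth) {
  ord <- order(prob, decreasing = TRUE)
  truth <- as.logical(truth)[ord]
  prob <- prob[ord]
  npos <- sum(truth); nneg <- sum(!truth)
  # step through distinct thresholds; ties move diagonally in one step
  grp <- cumsum(!duplicated(prob))
  tp <- cumsum(truth); fp <- cumsum(!truth)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / max(nneg, 1)),
             tpr = c(0, tp[last] / max(npos, 1)))
}

.trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' ROC curve and AUC from predicted probabilities
#'
#' @param prob predicted positive-class probabilities.
#' @param truth logical outcome labels.
#' @return List: roc_points (data.frame fpr, tpr, from (0,0) to (1,1)),
#'   auc (trapezoidal area), accuracy (decision rule prob >= 0.5).
#' @export
roc_metrics <- function(prob, truth) {
  truth <- as.logical(truth)
  roc <- .roc_points(prob, truth)
  list(roc_points = roc,
       auc = .trapezoid_auc(roc),
       accuracy = mean((prob >= 0.5) == truth))
}

#' Cross-validated KNN evaluation of feature sets
#'
#' Stratified k-fold assignment is drawn from the seed; out-of-fold
#' predicted probabilities are pooled and one ROC/AUC/accuracy is
#' computed per feature set. Feature sets are ranked by accuracy.
#'
#' @param table data.frame with outcome and feature columns.
#' @param outcome name of the logical outcome column.
#' @param feature_sets list of character vectors of feature names.
#' @param k_folds folds (default 5).
#' @param k neighbors (default 5).
#' @param seed fold-assignment seed.
#' @param standardize passed to \code{\link{knn_predict}}.
#' @return List of per-feature-set results (probabilities, folds,
#'   roc_points, auc, accuracy), ordered as given, with attribute
#'   \code{"ranking"} = feature-set indices by decreasing accuracy.
#' @export
cross_validate <- function(table, outcome, feature_sets, k_folds = 5,
                           k = 5, seed = 1, standardize = FALSE) {
  y <- as.logical(table[[outcome]])
  if (min(table(y)) < k_folds) {
    stop("need at least k_folds samples per class")
  }
  old <- .rng_state_save(); on.exit(.rng_state_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  results <- lapply(feature_sets, function(feats) {
    X <- .feature_matrix(table, feats)
    prob <- numeric(length(y))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      prob[!tr] <- knn_predict(X[tr, , drop = FALSE], y[tr],
                               X[!tr, , drop = FALSE],
                               k = min(k, sum(tr)),
                               standardize = standardize)
    }
    m <- roc_metrics(prob, y)
    list(features = feats, probabilities = prob, folds = fold,
         roc_points = m$roc_points, auc = m$auc, accuracy = m$accuracy)
  })
  names(results) <- vapply(feature_sets, paste, character(1),
                           collapse = "+")
  attr(results, "ranking") <-
    order(vapply(results, `[[`, numeric(1), "accuracy"),
          decreasing = TRUE)
  results
}

#' Train on one cohort, evaluate once on an external cohort
#'
#' The model is fit on all training rows and evaluated a single time on
#' the test rows; no test information enters any fitted quantity.
#'
#' @param train_table,test_table data.frames with the outcome and
#'   feature columns.
#' @param outcome logical outcome column name.
#' @param features character vector of feature names.
#' @param k neighbors (default 5).
#' @param standardize standardize by training statistics.
#' @return List: probabilities, roc_points, auc, accuracy.
#' @export
evaluate_external <- function(train_table, test_table, outcome, features,
                              k = 5, standardize = FALSE) {
  if (nrow(test_table) == 0) stop("external test table is empty")
  missing_f <- setdiff(features, names(test_table))
  if (length(missing_f)) {
    stop("feature(s) missing from test table: ",
         paste(missing_f, collapse = ", "))
  }
  Xtr <- .feature_matrix(train_table, features)
  Xte <- .feature_matrix(test_table, features)
  prob <- knn_predict(Xtr, train_table[[outcome]], Xte, k = k,
                      standardize = standardize)
  m <- roc_metrics(prob, as.logical(test_table[[outcome]]))
  c(list(probabilities = prob), m)
}
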