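test_that("KNN probabilities are neighbor class fractions", {
  train <- matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE)
  expect_equal(knn_predict(train, rep(TRUE, 5),
                           matrix(c(0, 0), 1), k = 5), 1.0)

  # k = n_train: every test point sees the training prevalence
  set.seed(61)
  tr <- matrix(stats::rnorm(20), ncol = 2)
  y <- rep(c(TRUE, FALSE), 5)
  p <- knn_predict(tr, y, matrix(stats::rnorm(6), ncol = 2), k = 10)
  expect_equal(p, rep(0.5, 3))

  # nearest neighbor forced in 1-D
  expect_equal(knn_predict(matrix(c(0, 1, 10)), c(FALSE, FALSE, TRUE),
                           matrix(9), k = 1), 1.0)

  expect_error(knn_predict(tr, y, tr, k = 0), "positive")
  expect_error(knn_predict(tr, y, tr, k = 11), "exceeds")
})

test_that("distance ties break by training-set order", {
  # two training points equidistant from the probe; k = 1 must take the
  # earlier row
  tr <- matrix(c(-1, 1), ncol = 1)
  expect_equal(knn_predict(tr, c(TRUE, FALSE), matrix(0), k = 1), 1.0)
  expect_equal(knn_predict(tr[2:1, , drop = FALSE], c(FALSE, TRUE),
                           matrix(0), k = 1), 0.0)
})

test_that("AUC equals pair counting and ROC is transform-invariant", {
  set.seed(62)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
    prob <- sample(seq(0, 1, 0.2), n, replace = TRUE)  # forces ties
    m <- roc_metrics(prob, truth)
    expect_equal(m$auc, oracle_auc(prob, truth), tolerance = 1e-12)
    expect_equal(m$roc_points$fpr[1], 0)
    expect_equal(m$roc_points$tpr[nrow(m$roc_points)], 1)
    expect_true(all(diff(m$roc_points$fpr) >= 0))
    expect_true(all(diff(m$roc_points$tpr) >= 0))
    # strictly increasing transform leaves the curve unchanged
    m2 <- roc_metrics(stats::qlogis((prob + 0.5) / 2), truth)
    expect_equal(m2$roc_points, m$roc_points)
    expect_equal(m2$auc, m$auc)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  prob <- stats::runif(40)
  truth <- stats::runif(40) < prob
  if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
  m <- roc_metrics(prob, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                        predictor = prob, quiet = TRUE)))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("constant features give AUC exactly 0.5", {
  tab <- data.frame(pe = rep(c(TRUE, FALSE), 20), flat = 1)
  cv <- cross_validate(tab, "pe", list("flat"), seed = 3)
  expect_equal(cv[[1]]$auc, 0.5)
})

test_that("cross-validation is deterministic and separates planted signal", {
  set.seed(64)
  n <- 120
  pe <- rep(c(TRUE, FALSE), n / 2)
  tab <- data.frame(
    pe = pe,
    burden = stats::rnorm(n, ifelse(pe, 3, 0)),   # 3 SD shift
    hypoxia = stats::rnorm(n, ifelse(pe, 1.5, 0)),
    noise = stats::rnorm(n))
  cv1 <- cross_validate(tab, "pe", list(c("burden", "hypoxia"), "noise"),
                        seed = 11)
  cv2 <- cross_validate(tab, "pe", list(c("burden", "hypoxia"), "noise"),
                        seed = 11)
  expect_identical(cv1[[1]]$probabilities, cv2[[1]]$probabilities)
  expect_identical(cv1[[1]]$folds, cv2[[1]]$folds)
  expect_gte(cv1[["burden+hypoxia"]]$auc, 0.95)
  expect_lt(cv1[["noise"]]$auc, 0.75)
  expect_equal(attr(cv1, "ranking")[1], 1)
})

test_that("external evaluation never leaks test information", {
  set.seed(65)
  n <- 80
  pe <- rep(c(TRUE, FALSE), n / 2)
  tab <- data.frame(pe = pe, burden = stats::rnorm(n, ifelse(pe, 3, 0)))
  r_self <- evaluate_external(tab, tab, "pe", "burden")
  prob_resub <- knn_predict(as.matrix(tab["burden"]), tab$pe,
                            as.matrix(tab["burden"]))
  expect_equal(r_self$probabilities, unname(prob_resub))

  # shuffling the feature in the test table only collapses the AUC
  shuffled <- tab
  shuffled$burden <- sample(shuffled$burden)
  r_shuf <- evaluate_external(tab, shuffled, "pe", "burden")
  expect_lt(abs(r_shuf$auc - 0.5), 0.2)
  expect_gte(r_self$auc, 0.95)

  expect_error(evaluate_external(tab, tab[0, ], "pe", "burden"), "empty")
  expect_error(evaluate_external(tab, tab["pe"], "pe", "burden"),
               "missing")
})
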