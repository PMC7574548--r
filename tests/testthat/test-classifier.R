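test_that("ROC AUC equals exhaustive pair counting, with ties and monotone invariance", {
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(51)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    s <- round(rnorm(n), 1)
    expect_equal(roc_auc(s, y), naive_roc_auc(s, y))
    # monotone transform leaves the ranking AUC unchanged
    expect_equal(roc_auc(exp(s), y), roc_auc(s, y))
  }
})

test_that("PR AUC matches the hand-worked example and a fine-grid interpolation oracle", {
  # scores 4,3,2,1 with labels +,-,+,-: segments (0,0)->(1,0)->(1,1)->(2,1)
  # contribute 1/2 and (1 - ln(3/2))/2
  expect_equal(pr_auc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)),
               0.5 + (1 - log(3 / 2)) / 2, tolerance = 1e-9)
  expect_equal(pr_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)

  pr_oracle <- function(s, y) {
    o <- order(s, decreasing = TRUE); y <- y[o]; s <- s[o]
    idx <- c(which(diff(s) != 0), length(s))
    tp <- c(0, cumsum(y)[idx]); fp <- c(0, cumsum(!y)[idx]); P <- sum(y)
    total <- 0
    for (k in 2:length(tp)) {
      dtp <- tp[k] - tp[k - 1]
      if (dtp == 0) next
      ts <- (seq_len(4000) - 0.5) / 4000
      prec <- (tp[k - 1] + ts * dtp) /
        (tp[k - 1] + fp[k - 1] + ts * (dtp + fp[k] - fp[k - 1]))
      total <- total + mean(prec) * dtp / P
    }
    total
  }
  set.seed(52)
  for (i in 1:5) {
    y <- runif(50) < 0.3
    if (!any(y) || all(y)) next
    s <- round(rnorm(50) + y, 1)
    expect_equal(pr_auc(s, y), pr_oracle(s, y), tolerance = 1e-4)
    # trapezoid option stays close but differs in general
    expect_lt(abs(pr_auc(s, y, method = "trapezoid") - pr_auc(s, y)), 0.02)
  }
})

test_that("F-score matches hand arithmetic and is scale invariant", {
  X <- matrix(c(2, 4, 0, 2), ncol = 1)
  y <- c("pos", "pos", "neg", "neg")
  expect_equal(unname(feature_fscore(X, factor(y, c("neg", "pos")))), 0.5)

  set.seed(53)
  X2 <- cbind(a = rnorm(40), b = rnorm(40))
  y2 <- factor(rep(c("neg", "pos"), 20))
  f1 <- feature_fscore(X2, y2)
  f2 <- feature_fscore(X2 %*% diag(c(10, 0.1)), y2)
  expect_equal(unname(f1), unname(f2))
  # identical class distributions give zero F
  X3 <- matrix(rep(c(1, 2), 20), ncol = 1)
  y3 <- factor(rep(c("neg", "pos"), each = 20), c("neg", "pos"))
  expect_equal(unname(feature_fscore(X3, y3)), 0)
})

test_that("stratified folds preserve class balance and partition the data", {
  y <- factor(c(rep("pos", 276), rep("neg", 3036)))
  fold <- stratified_kfold(y, k = 4, seed = 1)
  for (f in 1:4) {
    expect_equal(sum(fold == f & y == "pos"), 69)
    expect_equal(sum(fold == f & y == "neg"), 759)
  }
  expect_setequal(unique(fold), 1:4)

  y2 <- factor(c(rep("pos", 5), rep("neg", 8)))
  fold2 <- stratified_kfold(y2, k = 4, seed = 2)
  expect_equal(sort(table(fold2[y2 == "pos"]), decreasing = TRUE),
               sort(table(c(1, 1, 2, 3, 4)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_identical(stratified_kfold(y2, 4, seed = 9),
                   stratified_kfold(y2, 4, seed = 9))
})

test_that("the SVM separates Gaussian blobs and yields calibrated probabilities", {
  set.seed(54)
  n <- 120
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 6), rnorm(n, 6)))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("neg", "pos"), each = n), c("neg", "pos"))
  m <- origin_svm(X, y, seed = 1)
  p <- predict(m, X, type = "prob")
  expect_true(all(p > 0 & p < 1))
  expect_equal(roc_auc(p, y), 1)
  # probabilities rise with the decision value
  d <- predict(m, X, type = "decision")
  expect_gt(cor(d, p, method = "spearman") * sign(cor(d, as.numeric(y == "pos"))), 0.99)
  expect_error(origin_svm(X, factor(rep("pos", nrow(X)))), "single-class")
})

test_that("repeated CV is deterministic, perfect on separable data and null on permuted labels", {
  set.seed(55)
  n <- 150
  X <- rbind(cbind(rnorm(n, 0), rnorm(n)), cbind(rnorm(n, 8), rnorm(n)))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("neg", "pos"), each = n), c("neg", "pos"))
  cv <- origin_cv(X, y, k = 4, rounds = 3, boot_reps = 200,
                  keep_models = FALSE, seed = 3)
  expect_equal(cv$roc_auc, 1)
  cv2 <- origin_cv(X, y, k = 4, rounds = 3, boot_reps = 200,
                   keep_models = FALSE, seed = 3)
  expect_equal(cv$per_fold, cv2$per_fold)
  expect_equal(cv$oof_prob, cv2$oof_prob)

  yperm <- y[sample(length(y))]
  cvp <- origin_cv(X, yperm, k = 4, rounds = 3, boot_reps = 200,
                   keep_models = FALSE, seed = 4)
  expect_gt(cvp$roc_auc, 0.38)
  expect_lt(cvp$roc_auc, 0.62)
})

test_that("held-out scoring averages the CV models deterministically", {
  set.seed(56)
  n <- 80
  X <- rbind(cbind(rnorm(n, 0), rnorm(n)), cbind(rnorm(n, 6), rnorm(n)))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("neg", "pos"), each = n), c("neg", "pos"))
  cv <- origin_cv(X, y, k = 4, rounds = 2, boot_reps = 100, seed = 5)
  newX <- cbind(f1 = c(-1, 3, 7), f2 = c(0, 0, 0))
  s1 <- score_heldout(cv, newX)
  expect_length(s1, 3)
  expect_true(all(diff(s1) > 0))      # middle blob scores between
  expect_identical(s1, score_heldout(cv, newX))
  expect_length(score_heldout(cv, newX[0, , drop = FALSE]), 0)
})
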