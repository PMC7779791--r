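test_that("balanced accuracy follows its defining formula", {
  expect_equal(balanced_accuracy(10, 0, 10, 0), 1)
  expect_equal(balanced_accuracy(5, 5, 5, 5), 0.5)
  expect_equal(balanced_accuracy(8, 4, 6, 2), 0.7)
  expect_error(balanced_accuracy(0, 3, 0, 0), "empty class")
})

test_that("ROC anchors, symmetry and null behaviour hold", {
  y <- rep(c("healthy", "injured"), each = 20)
  perfect <- roc_curve(as.numeric(y == "injured"), y, "injured")
  expect_equal(perfect$auc, 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  set.seed(51)
  s <- rnorm(40)
  a <- roc_curve(s, y, "injured")
  b <- roc_curve(-s, y, "injured")
  expect_equal(b$auc, 1 - a$auc, tolerance = 1e-12)
  # scores independent of labels, larger n
  y2 <- rep(c("healthy", "injured"), each = 500)
  null_auc <- roc_curve(rnorm(1000), y2, "injured")$auc
  expect_gt(null_auc, 0.4); expect_lt(null_auc, 0.6)
  expect_error(roc_curve(s, rep("injured", 40), "injured"), "both classes")
})

test_that("vertical mean ROC is monotone and averages per-permutation AUCs", {
  set.seed(53)
  y <- rep(c("healthy", "injured"), each = 25)
  scores <- lapply(1:8, function(i) rnorm(50) + (y == "injured"))
  mr <- mean_roc(scores, y, "injured")
  expect_true(all(diff(mr$roc$tpr_mean) >= -1e-12))
  expect_equal(mr$auc_mean, mean(mr$auc))
  expect_equal(mr$roc$tpr_mean[1], mean(vapply(
    scores, function(s) max(roc_curve(s, y, "injured")$tpr[
      roc_curve(s, y, "injured")$fpr <= 1e-12]), numeric(1))))
})

test_that("stratified folds keep class ratios within one subject", {
  set.seed(57)
  y <- c(rep("healthy", 23), rep("injured", 17))
  for (i in 1:10) {
    fold <- stratified_kfold(y, 5)
    for (f in 1:5) {
      n_h <- sum(y[fold == f] == "healthy")
      n_i <- sum(y[fold == f] == "injured")
      expect_true(abs(n_h - 23 / 5) < 1)
      expect_true(abs(n_i - 17 / 5) < 1)
    }
  }
  expect_error(stratified_kfold(c(rep("a", 3), rep("b", 9)), 5), "fewer")
})

test_that("the linear SVM separates a linearly separable problem", {
  set.seed(59)
  X <- rbind(matrix(rnorm(60, mean = -2), 30, 2),
             matrix(rnorm(60, mean = 2), 30, 2))
  y <- rep(c("healthy", "injured"), each = 30)
  fit <- svm_linear(X, y, positive = "injured")
  expect_true(fit$converged)
  expect_equal(predict(fit, X, type = "class"), y)
})

test_that("repeated CV is deterministic and internally consistent", {
  set.seed(61)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(sprintf("s%02d", 1:40),
                                                    paste0("f", 1:6)))
  y <- rep(c("healthy", "injured"), each = 20)
  a <- run_cv_svm(X, y, n_perm = 5, k = 5, seed = 99)
  b <- run_cv_svm(X, y, n_perm = 5, k = 5, seed = 99)
  expect_identical(a$per_perm, b$per_perm)
  expect_identical(a$roc, b$roc)
  # row-wise invariant: balanced accuracy = (sens + spec) / 2
  expect_equal(a$per_perm$balanced_accuracy,
               (a$per_perm$sensitivity + a$per_perm$specificity) / 2)
  expect_true(all(a$per_perm$auc >= 0 & a$per_perm$auc <= 1))
  # per-fold confusions add up to the cohort per permutation
  sums <- aggregate(cbind(tp, fp, tn, fn) ~ perm, a$per_fold, sum)
  expect_true(all(rowSums(sums[, -1]) == 40))
})

test_that("fully separated synthetic classes reach AUC > 0.99", {
  set.seed(63)
  X <- cbind(c(rnorm(30, -4), rnorm(30, 4)), matrix(rnorm(60 * 5), 60, 5))
  rownames(X) <- sprintf("s%02d", 1:60); colnames(X) <- paste0("f", 1:6)
  y <- rep(c("healthy", "injured"), each = 30)
  out <- run_cv_svm(X, y, n_perm = 10, k = 5, seed = 3)
  expect_gt(out$summary$mean[out$summary$metric == "auc"], 0.99)
  expect_gt(out$summary$mean[out$summary$metric == "balanced_accuracy"], 0.95)
})

test_that("degenerate inputs are refused or repaired with a warning", {
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("healthy", "injured"), each = 20)
  expect_error(run_cv_svm(X, rep("healthy", 40), n_perm = 2), "two classes")
  expect_error(run_cv_svm(X, c(rep("healthy", 37), rep("injured", 3)),
                          n_perm = 2, k = 5), "fewer")
  Xc <- cbind(X, d = 1)
  expect_warning(run_cv_svm(Xc, y, n_perm = 2, k = 5, seed = 1), "constant")
})

test_that("standardisation statistics are a pure function of training rows", {
  set.seed(67)
  X <- matrix(rnorm(30 * 4), 30, 4)
  tr <- 1:20; te <- 21:30
  fit1 <- zscore_fit(X[tr, ])
  X_spiked <- X
  X_spiked[te, ] <- X_spiked[te, ] + 1e6   # outliers in the test fold only
  fit2 <- zscore_fit(X_spiked[tr, ])
  expect_identical(fit1, fit2)
  # applying the fit centres the training block exactly
  Z <- zscore_apply(X[tr, ], fit1)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-12)
})
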