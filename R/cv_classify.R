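# ---- standardisation (train-fold only; leakage-guarded) -----------------

#' Feature standardisation fitted on training data only
#'
#' `zscore_fit` computes per-column means and standard deviations;
#' `zscore_apply` applies them to any data. Keeping the two steps separate
#' is what makes the no-leakage property testable: fold statistics are a
#' pure function of the training rows. Zero-sd columns get scale 1 so a
#' constant feature maps to 0 instead of NaN.
#'
#' @param X numeric matrix `[samples x features]`.
#' @return `zscore_fit`: list with `center` and `scale`.
#' @export
zscore_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @rdname zscore_fit
#' @param fit output of `zscore_fit`.
#' @export
zscore_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals members round-robin over folds, so
#' every fold's class ratio is within one subject of the cohort ratio.
#'
#' @param y class labels.
#' @param k number of folds.
#' @return integer fold id (1..k) per sample.
#' @export
stratified_kfold <- function(y, k = 5) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Balanced accuracy from confusion counts
#'
#' `(sensitivity + specificity) / 2 = (TP/(TP+FN) + TN/(TN+FP)) / 2`.
#'
#' @param tp,fp,tn,fn confusion counts; both classes must be represented.
#' @return unitless value in \[0, 1\].
#' @export
balanced_accuracy <- function(tp, fp, tn, fn) {
  if (tp + fn == 0 || tn + fp == 0)
    stop("balanced accuracy undefined with an empty class")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Empirical ROC curve
#'
#' Standard construction from decision scores: thresholds swept over the
#' unique score values (ties grouped), TPR/FPR accumulated from the
#' highest score down, AUC by the trapezoid rule.
#'
#' @param scores numeric decision values, higher = more positive.
#' @param labels true labels.
#' @param positive positive-class label.
#' @return list with `fpr`, `tpr` (starting at (0,0), ending at (1,1)) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels, positive) {
  is_pos <- labels == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) stop("ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  sp <- is_pos[o]
  # group tied scores: step only after the last of a tie block
  s <- scores[o]
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, (cumsum(sp) / np)[last_of_block])
  fpr <- c(0, (cumsum(!sp) / nn)[last_of_block])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Vertically averaged mean ROC over permutations
#'
#' Each permutation's pooled decision scores give one empirical ROC; the
#' TPR is read off on a shared FPR grid (step interpolation: the highest
#' TPR reached at FPR <= grid point) and averaged vertically. AUC is the
#' trapezoid area of each permutation's own curve, then mean +/- STDV.
#'
#' @param scores_by_perm list of score vectors, one per permutation.
#' @param labels_by_perm list of matching label vectors (or one vector
#'   recycled).
#' @param positive positive-class label.
#' @param fpr_grid shared FPR grid, default 101 points.
#' @return list with `roc` (data.frame `fpr`, `tpr_mean`, `tpr_sd`),
#'   `auc_mean`, `auc_sd`, `auc` (per permutation).
#' @export
mean_roc <- function(scores_by_perm, labels_by_perm, positive,
                     fpr_grid = seq(0, 1, by = 0.01)) {
  if (!is.list(scores_by_perm)) scores_by_perm <- list(scores_by_perm)
  if (!is.list(labels_by_perm))
    labels_by_perm <- rep(list(labels_by_perm), length(scores_by_perm))
  stopifnot(length(scores_by_perm) == length(labels_by_perm))
  tpr_mat <- matrix(NA_real_, length(scores_by_perm), length(fpr_grid))
  auc <- numeric(length(scores_by_perm))
  for (i in seq_along(scores_by_perm)) {
    rc <- roc_curve(scores_by_perm[[i]], labels_by_perm[[i]], positive)
    tpr_mat[i, ] <- vapply(fpr_grid,
                           function(g) max(rc$tpr[rc$fpr <= g + 1e-12]),
                           numeric(1))
    auc[i] <- rc$auc
  }
  list(roc = data.frame(fpr = fpr_grid,
                        tpr_mean = colMeans(tpr_mat),
                        tpr_sd = apply(tpr_mat, 2, sd)),
       auc_mean = mean(auc), auc_sd = sd(auc), auc = auc)
}

confusion_counts <- function(pred_pos, is_pos) {
  c(tp = sum(pred_pos & is_pos), fp = sum(pred_pos & !is_pos),
    tn = sum(!pred_pos & !is_pos), fn = sum(!pred_pos & is_pos))
}

#' Repeated stratified cross-validated linear-SVM classification
#'
#' The full evaluation protocol: `n_perm` permutations of stratified
#' `k`-fold cross-validation; per fold, features are z-scored with
#' training-fold statistics only and a class-weighted linear SVM (fixed
#' `C`) is trained; test-fold decision scores are pooled per permutation.
#' Per permutation the pooled scores yield the confusion at threshold 0
#' (balanced accuracy, sensitivity, specificity) and an ROC/AUC; metrics
#' are aggregated as mean +/- STDV over permutations and the ROC is
#' vertically averaged on a fixed FPR grid.
#'
#' @param X feature matrix `[subjects x features]`, no missing values.
#' @param y labels; `positive` (default `"injured"` if present) is the
#'   positive class. Both classes need at least `k` members.
#' @param n_perm,k repetitions and folds (defaults 50 and 5).
#' @param seed RNG seed for the fold draws.
#' @param C SVM soft-margin constant.
#' @param class_weight passed to [svm_linear()].
#' @param positive positive-class label.
#' @param fpr_grid grid for the mean ROC.
#' @return object of class `cv_report`: `per_perm` (metrics incl. AUC per
#'   permutation), `per_fold` (confusion per fold), `roc`, `summary`
#'   (mean/sd per metric), `settings`.
#' @export
run_cv_svm <- function(X, y, n_perm = 50, k = 5, seed = 1, C = 1,
                       class_weight = "balanced", positive = NULL,
                       fpr_grid = seq(0, 1, by = 0.01)) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(X)) stop("X must not contain missing values")
  lev <- sort(unique(y))
  if (length(lev) != 2)
    stop("classification requires exactly two classes, got: ",
         paste(lev, collapse = ", "))
  if (is.null(positive))
    positive <- if ("injured" %in% lev) "injured" else lev[2]
  if (min(table(y)) < k)
    stop("smallest class has fewer members than folds")
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  set.seed(seed)
  is_pos <- y == positive
  per_perm <- vector("list", n_perm)
  per_fold <- vector("list", n_perm)
  scores_by_perm <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    fold <- stratified_kfold(y, k)
    scores <- numeric(length(y))
    fold_rows <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      zs <- zscore_fit(X[tr, , drop = FALSE])
      fit <- svm_linear(zscore_apply(X[tr, , drop = FALSE], zs), y[tr],
                        C = C, class_weight = class_weight,
                        positive = positive)
      sc <- predict(fit, zscore_apply(X[te, , drop = FALSE], zs))
      scores[te] <- sc
      cc <- confusion_counts(sc > 0, is_pos[te])
      fold_rows[[f]] <- data.frame(perm = p, fold = f, t(cc),
                                   balanced_accuracy = unname(balanced_accuracy(
                                     cc["tp"], cc["fp"], cc["tn"], cc["fn"])))
    }
    per_fold[[p]] <- do.call(rbind, fold_rows)
    cc <- confusion_counts(scores > 0, is_pos)
    sens <- cc["tp"] / (cc["tp"] + cc["fn"])
    spec <- cc["tn"] / (cc["tn"] + cc["fp"])
    per_perm[[p]] <- data.frame(perm = p, t(cc),
                                sensitivity = unname(sens),
                                specificity = unname(spec),
                                balanced_accuracy = unname((sens + spec) / 2))
    scores_by_perm[[p]] <- scores
  }
  pp <- do.call(rbind, per_perm)
  mr <- mean_roc(scores_by_perm, y, positive, fpr_grid)
  pp$auc <- mr$auc
  summ <- data.frame(
    metric = c("balanced_accuracy", "sensitivity", "specificity", "auc"),
    mean = c(mean(pp$balanced_accuracy), mean(pp$sensitivity),
             mean(pp$specificity), mr$auc_mean),
    sd = c(sd(pp$balanced_accuracy), sd(pp$sensitivity),
           sd(pp$specificity), mr$auc_sd))
  structure(list(per_perm = pp, per_fold = do.call(rbind, per_fold),
                 roc = mr$roc, summary = summ,
                 settings = list(n_perm = n_perm, k = k, seed = seed, C = C,
                                 class_weight = class_weight,
                                 positive = positive)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d permutations of stratified %d-fold CV (positive: %s)\n",
              x$settings$n_perm, x$settings$k, x$settings$positive))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
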