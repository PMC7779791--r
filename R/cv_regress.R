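#' Pearson correlation coefficient
#'
#' Standard definition; returns `NA` (flagged missing) if either input has
#' zero variance, never a silent 0.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return unitless value in \[-1, 1\] or `NA`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Root-mean-square error
#'
#' @param pred,obs numeric vectors of equal length.
#' @return RMSE in the units of the inputs, >= 0.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  sqrt(mean((pred - obs)^2))
}

# OLS fit with ridge fallback when the training design is rank-deficient;
# returns coefficients [p x n_targets] for design [n x p] (intercept included
# by the caller).
ols_multi <- function(D, Y, ridge_lambda = 1e-3) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    # rank-deficient training fold: small fixed ridge penalty, flagged
    beta <- solve(crossprod(D) + diag(ridge_lambda, ncol(D)), crossprod(D, Y))
    attr(beta, "ridged") <- TRUE
    return(beta)
  }
  beta <- qr.coef(qrD, Y)
  attr(beta, "ridged") <- FALSE
  beta
}

#' Cross-validated multivariate linear prediction of ROI FA
#'
#' For each permutation, a fresh k-fold split of the pooled cohort; per
#' fold the feature matrix is z-scored on training rows only and every
#' ROI's mean FA is predicted by ordinary least squares on the shared
#' design (equivalent to multi-output linear regression). Test predictions
#' are pooled per permutation; Pearson r and RMSE per ROI per permutation
#' are aggregated as plain mean +/- STDV over permutations (no Fisher-z).
#' Rank-deficient training folds fall back to a small fixed ridge penalty
#' and are counted in the report.
#'
#' @param X feature matrix `[subjects x features]` (rownames = subject
#'   ids).
#' @param fa FA table (long data.frame from [simulate_fa()] /
#'   [roi_mean_fa()]) or a subject-by-ROI matrix.
#' @param n_perm,k repetitions and folds (defaults 50 and 5).
#' @param seed RNG seed for the fold draws.
#' @param ridge_lambda fallback penalty for rank-deficient folds.
#' @return object of class `regression_report`: `by_roi` (r and RMSE mean
#'   +/- STDV per ROI), `per_perm` (long data.frame), `n_subjects`,
#'   `n_ridged_folds`, `settings`.
#' @export
run_cv_regression <- function(X, fa, n_perm = 50, k = 5, seed = 1,
                              ridge_lambda = 1e-3) {
  X <- as.matrix(X)
  F <- if (is.matrix(fa)) fa else fa_matrix(fa)
  if (!is.null(rownames(X)) && !is.null(rownames(F))) {
    common <- intersect(rownames(X), rownames(F))
    X <- X[common, , drop = FALSE]
    F <- F[common, , drop = FALSE]
  }
  keep <- stats::complete.cases(X) & stats::complete.cases(F)
  X <- X[keep, , drop = FALSE]; F <- F[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 2 * k) stop("need at least 2*k subjects with complete rows")
  rois <- colnames(F)
  set.seed(seed)
  r_mat <- matrix(NA_real_, n_perm, length(rois),
                  dimnames = list(NULL, rois))
  rmse_mat <- matrix(NA_real_, n_perm, length(rois),
                     dimnames = list(NULL, rois))
  n_ridged <- 0L
  for (p in seq_len(n_perm)) {
    fold <- rep_len(seq_len(k), n)[sample(n)]
    pred <- matrix(NA_real_, n, length(rois))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      zs <- zscore_fit(X[tr, , drop = FALSE])
      Dtr <- cbind(1, zscore_apply(X[tr, , drop = FALSE], zs))
      beta <- ols_multi(Dtr, F[tr, , drop = FALSE], ridge_lambda)
      if (isTRUE(attr(beta, "ridged"))) n_ridged <- n_ridged + 1L
      pred[te, ] <- cbind(1, zscore_apply(X[te, , drop = FALSE], zs)) %*% beta
    }
    for (j in seq_along(rois)) {
      obs <- F[, j]
      r_mat[p, j] <- if (sd(obs) == 0) NA_real_ else pearson_r(pred[, j], obs)
      rmse_mat[p, j] <- rmse(pred[, j], obs)
    }
  }
  by_roi <- data.frame(
    roi = rois,
    r_mean = colMeans(r_mat, na.rm = TRUE),
    r_sd = apply(r_mat, 2, sd, na.rm = TRUE),
    rmse_mean = colMeans(rmse_mat),
    rmse_sd = apply(rmse_mat, 2, sd),
    stringsAsFactors = FALSE, row.names = NULL)
  per_perm <- data.frame(
    perm = rep(seq_len(n_perm), times = length(rois)),
    roi = rep(rois, each = n_perm),
    r = as.vector(r_mat), rmse = as.vector(rmse_mat),
    stringsAsFactors = FALSE)
  structure(list(by_roi = by_roi, per_perm = per_perm, n_subjects = n,
                 n_ridged_folds = n_ridged,
                 settings = list(n_perm = n_perm, k = k, seed = seed,
                                 ridge_lambda = ridge_lambda)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %d ROIs, %d subjects, %d x %d-fold CV\n",
              nrow(x$by_roi), x$n_subjects, x$settings$n_perm, x$settings$k))
  if (x$n_ridged_folds > 0)
    cat(sprintf("  %d rank-deficient training fold(s) used the ridge fallback\n",
                x$n_ridged_folds))
  b <- x$by_roi[order(-x$by_roi$r_mean), ]
  for (i in seq_len(min(6, nrow(b))))
    cat(sprintf("  %-42s r %.2f +/- %.2f  RMSE %.3f +/- %.3f\n",
                b$roi[i], b$r_mean[i], b$r_sd[i], b$rmse_mean[i], b$rmse_sd[i]))
  if (nrow(b) > 6) cat("  ...\n")
  invisible(x)
}
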