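#' Linear support vector machine (L1 hinge loss)
#'
#' Trains a linear SVM by dual coordinate descent on
#' `0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)`. The bias is fitted as
#' an augmented constant feature (so it is mildly regularised, as in
#' common linear-SVM solvers). With `class_weight = "balanced"` the
#' per-sample cost is `C * n / (2 * n_class)` — inverse class frequency —
#' which is how "class priors set to balanced proportions" is
#' operationalised here.
#'
#' @param X numeric matrix `[samples x features]`.
#' @param y two-level factor or character; `positive` names the +1 class.
#' @param C soft-margin constant, default 1 (not tuned).
#' @param class_weight `"balanced"` or `"none"`.
#' @param positive label treated as the positive class (default: last
#'   level).
#' @param tol,max_passes solver stopping controls.
#' @return object of class `linear_svm` with weights `w`, bias `b`,
#'   `levels`, `positive`.
#' @export
svm_linear <- function(X, y, C = 1, class_weight = c("balanced", "none"),
                       positive = NULL, tol = 1e-8, max_passes = 5000L) {
  class_weight <- match.arg(class_weight)
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("svm_linear needs exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  stopifnot(positive %in% lev)
  ys <- ifelse(y == positive, 1, -1)
  n <- nrow(X)
  cw <- if (class_weight == "balanced") {
    tab <- table(ys)
    n / (2 * as.numeric(tab[as.character(ys)]))
  } else rep(1, n)
  Xa <- cbind(X, 1)   # augmented bias feature
  fit <- svm_dcd_fit(Xa, ys, C * cw, tol, as.integer(max_passes))
  w <- fit$w
  structure(list(w = w[-length(w)], b = w[length(w)],
                 levels = lev, positive = positive,
                 passes = fit$passes, converged = fit$max_pg < tol),
            class = "linear_svm")
}

#' @describeIn svm_linear Decision values (`type = "decision"`, default)
#'   or class labels (`type = "class"`) for new data.
#' @param object fitted `linear_svm`.
#' @param newdata matrix `[samples x features]`.
#' @param type `"decision"` or `"class"`.
#' @param ... ignored.
#' @export
predict.linear_svm <- function(object, newdata, type = c("decision", "class"),
                               ...) {
  type <- match.arg(type)
  d <- as.vector(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") return(d)
  neg <- setdiff(object$levels, object$positive)
  ifelse(d > 0, object$positive, neg)
}
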