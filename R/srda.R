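#' Fit a spectral regression discriminant analysis classifier
#'
#' Casts discriminant analysis as regression: class-membership indicator
#' vectors are orthogonalized against the constant vector (Gram-Schmidt via
#' QR), yielding \code{n_classes - 1} response vectors, each regressed on the
#' mean-centered features by ridge-regularized least squares. No dense
#' eigendecomposition is involved. Trials are then embedded by the fitted
#' projection and summarized by per-class centroids.
#'
#' @param features trials x D numeric matrix.
#' @param labels integer class labels, >= 2 trials per class.
#' @param alpha_reg ridge regularizer (>= 0); small values approximate LDA.
#' @return object of class \code{mi_srda}.
#' @export
fit_srda <- function(features, labels, alpha_reg = 0.01) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("one label per feature row required")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("every class needs >= 2 training trials")
  if (alpha_reg < 0) stop("alpha_reg must be >= 0")
  c_n <- length(classes)
  ind <- vapply(classes, function(k) as.numeric(labels == k), numeric(n))
  qd <- qr(cbind(rep(1, n), ind))
  resp <- qr.Q(qd)[, 2:c_n, drop = FALSE]   # constant direction removed
  center <- colMeans(features)
  xc <- sweep(features, 2, center)
  d <- ncol(xc)
  gram <- crossprod(xc) + diag(alpha_reg, d)
  proj <- solve(gram, crossprod(xc, resp))
  z <- xc %*% proj
  centroids <- do.call(rbind, lapply(classes, function(k) {
    colMeans(z[labels == k, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  structure(list(projection = proj, center = center,
                 class_centroids = centroids, classes = classes,
                 alpha_reg = alpha_reg, training_feature_count = d),
            class = "mi_srda")
}

#' @export
print.mi_srda <- function(x, ...) {
  cat(sprintf("<mi_srda> %d features -> %d discriminant dims, %d classes (alpha = %g)\n",
              x$training_feature_count, ncol(x$projection),
              length(x$classes), x$alpha_reg))
  invisible(x)
}

#' Predict class labels with a fitted SRDA model
#'
#' Centers by the training mean, projects into the discriminant space, and
#' assigns each trial to the nearest class centroid (Euclidean); exact ties go
#' to the smallest class label.
#'
#' @param model an \code{mi_srda}.
#' @param features trials x D matrix, D matching training.
#' @return integer vector of predicted labels.
#' @export
predict_srda <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$training_feature_count)
    stop("feature dimension ", ncol(features), " does not match training (",
         model$training_feature_count, ")")
  z <- sweep(features, 2, model$center) %*% model$projection
  d2 <- outer(rowSums(z^2), rowSums(model$class_centroids^2), "+") -
    2 * z %*% t(model$class_centroids)
  model$classes[apply(d2, 1, which.min)]
}

#' F-measure from precision and recall
#'
#' Harmonic mean \code{F = 2PR/(P+R)}, vectorized; 0 where both rates are 0.
#'
#' @param precision,recall rates in [0,1].
#' @export
f_measure <- function(precision, recall) {
  den <- precision + recall
  ifelse(den > 0, 2 * precision * recall / den, 0)
}

#' Classification agreement metrics
#'
#' Accuracy, Cohen's kappa, and per-class precision/recall/F-measure
#' (\code{F = 2PR/(P+R)}) from the confusion matrix. A precision, recall or F
#' with zero denominator is reported as 0 and counted in the
#' \code{undefined_rates} field.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @param n_classes number of classes (labels \code{0..n_classes-1}).
#' @return object of class \code{mi_metrics} with fields \code{accuracy},
#'   \code{kappa}, \code{precision}, \code{recall}, \code{f_measure},
#'   \code{confusion} (rows = true class), \code{undefined_rates}.
#' @export
evaluate <- function(true_labels, pred_labels, n_classes = 4) {
  n <- length(true_labels)
  if (n == 0) stop("empty label vectors")
  if (length(pred_labels) != n) stop("label vectors differ in length")
  lev <- seq_len(n_classes) - 1L
  cm <- table(factor(true_labels, levels = lev),
              factor(pred_labels, levels = lev))
  cm <- unclass(cm)
  acc <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  tp <- diag(cm)
  prec_den <- colSums(cm)
  rec_den <- rowSums(cm)
  precision <- ifelse(prec_den > 0, tp / prec_den, 0)
  recall <- ifelse(rec_den > 0, tp / rec_den, 0)
  fm <- f_measure(precision, recall)
  undefined <- sum(prec_den == 0) + sum(rec_den == 0) +
    sum(precision + recall == 0)
  structure(list(accuracy = acc, kappa = kappa,
                 precision = as.numeric(precision),
                 recall = as.numeric(recall),
                 f_measure = as.numeric(fm),
                 confusion = cm, undefined_rates = undefined),
            class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("<mi_metrics> accuracy %.4f, kappa %.4f\n", x$accuracy, x$kappa))
  tab <- rbind(P = x$precision, R = x$recall, F = x$f_measure)
  colnames(tab) <- colnames(x$confusion)
  print(round(tab, 4))
  invisible(x)
}
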