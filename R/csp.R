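#' Average normalized spatial covariance of a set of trials
#'
#' Each trial contributes \code{X X' / trace(X X')} (trace normalization makes
#' the estimate invariant to per-trial amplitude scaling); the output is the
#' average over trials, symmetric positive-semidefinite.
#'
#' @param trials list of \code{mi_trial} with a common channel count.
#' @return channels x channels covariance matrix.
#' @export
class_covariance <- function(trials) {
  if (length(trials) < 1) stop("need at least one trial")
  n_ch <- nrow(trials[[1]]$x)
  acc <- matrix(0, n_ch, n_ch)
  for (tr in trials) {
    if (nrow(tr$x) != n_ch)
      stop("inconsistent channel counts: ", nrow(tr$x), " vs ", n_ch)
    cc <- tcrossprod(tr$x)
    acc <- acc + cc / sum(diag(cc))
  }
  out <- acc / length(trials)
  dimnames(out) <- list(rownames(trials[[1]]$x), rownames(trials[[1]]$x))
  (out + t(out)) / 2
}

# Deterministic symmetric eigendecomposition: eigenvalues descending and each
# vector's largest-magnitude entry made positive, so filters are reproducible
# across linear-algebra backends.
sym_eigen <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  for (j in seq_len(ncol(e$vectors))) {
    i <- which.max(abs(e$vectors[, j]))
    if (e$vectors[i, j] < 0) e$vectors[, j] <- -e$vectors[, j]
  }
  e
}

#' Whitening transform of a composite covariance
#'
#' \code{P = E^{-1/2} U0'} with \code{(U0, E)} the eigendecomposition of
#' \code{R_sum}, so that \code{P R_sum P' = I}. A rank-deficient input (any
#' eigenvalue at or below tolerance) is ridge-regularized by
#' \code{1e-10 * trace/N} on the diagonal and the result is flagged via
#' attribute \code{"regularized"}.
#'
#' @param r_sum symmetric positive-definite matrix.
#' @return whitening matrix \code{P} (same dimension).
#' @export
whitening_matrix <- function(r_sum) {
  n <- nrow(r_sum)
  e <- sym_eigen(r_sum)
  regularized <- FALSE
  tol <- max(abs(e$values)) * 1e-12
  if (any(e$values <= tol)) {
    r_sum <- r_sum + diag(1e-10 * sum(diag(r_sum)) / n, n)
    e <- sym_eigen(r_sum)
    regularized <- TRUE
  }
  p <- diag(1 / sqrt(e$values), n) %*% t(e$vectors)
  attr(p, "regularized") <- regularized
  p
}

#' Two-class common spatial pattern filters
#'
#' Whitens the composite covariance \code{R_A + R_B}, diagonalizes the
#' whitened class-A covariance, and returns \code{W = U' P}. Rows are ordered
#' by descending eigenvalue of the transformed class-A covariance, so early
#' rows maximize class-A variance and late rows class-B variance
#' (the eigenvalues of the two transformed covariances sum to 1 pairwise).
#'
#' @param r_a,r_b symmetric positive-definite class covariances, same size.
#' @param m optionally keep only the \code{m} first and \code{m} last filters;
#'   default uses all \code{N} rows.
#' @return spatial filter matrix \code{W} (rows = filters).
#' @export
csp_filters <- function(r_a, r_b, m = NULL) {
  if (!all(dim(r_a) == dim(r_b))) stop("covariance size mismatch")
  p <- whitening_matrix(r_a + r_b)
  s_a <- p %*% r_a %*% t(p)
  u <- sym_eigen(s_a)$vectors
  w <- t(u) %*% p
  if (!is.null(m)) {
    n <- nrow(w)
    if (2 * m > n) stop("m too large: 2m must be <= ", n)
    w <- w[c(seq_len(m), seq.int(n - m + 1, n)), , drop = FALSE]
  }
  w
}

#' Log normalized variance features of a projected trial
#'
#' Projects \code{Z = W X} and returns
#' \code{f_p = log(var(z_p) / sum_p var(z_p))} over all filter rows.
#' The normalization makes the features invariant to global rescaling of the
#' trial.
#'
#' @param trial an \code{mi_trial} (or a channels x samples matrix).
#' @param w spatial filter matrix with as many columns as trial channels.
#' @return numeric feature vector, length \code{nrow(w)}.
#' @export
csp_log_variance <- function(trial, w) {
  x <- if (inherits(trial, "mi_trial")) trial$x else as.matrix(trial)
  if (ncol(w) != nrow(x))
    stop("filter expects ", ncol(w), " channels, trial has ", nrow(x))
  z <- w %*% x
  v <- apply(z, 1, stats::var)
  total <- sum(v)
  if (total <= 0) stop("degenerate trial: zero total projected variance")
  log(v / total)
}

#' One-vs-rest CSP filter bank for multiclass trials
#'
#' For every class, fits CSP between that class's trials and all remaining
#' trials. The bank's spatial feature vector for a trial is the concatenation
#' of per-class log-variance features, length \code{n_classes * N} for
#' \code{N} channels (124 for the 31-channel ISC-augmented montage).
#'
#' @param trials labelled list of \code{mi_trial} covering every class.
#' @param n_classes number of classes (labels \code{0..n_classes-1}).
#' @param m optional per-class filter truncation passed to
#'   \code{\link{csp_filters}}.
#' @return object of class \code{mi_csp_bank}.
#' @export
ovr_csp <- function(trials, n_classes = 4, m = NULL) {
  labs <- trial_labels(trials)
  classes <- seq_len(n_classes) - 1L
  missing <- setdiff(classes, unique(labs))
  if (length(missing) > 0)
    stop("classes absent from training labels: ",
         paste(missing, collapse = ", "))
  filters <- lapply(classes, function(k) {
    r_a <- class_covariance(trials[labs == k])
    r_b <- class_covariance(trials[labs != k])
    csp_filters(r_a, r_b, m = m)
  })
  structure(list(filters_per_class = filters, classes = classes,
                 n_channels = nrow(trials[[1]]$x)),
            class = "mi_csp_bank")
}

#' @export
print.mi_csp_bank <- function(x, ...) {
  cat(sprintf("<mi_csp_bank> %d classes x %d filters over %d channels\n",
              length(x$filters_per_class), nrow(x$filters_per_class[[1]]),
              x$n_channels))
  invisible(x)
}

#' Spatial feature block of a trial under a one-vs-rest bank
#'
#' @param bank an \code{mi_csp_bank}.
#' @param trial an \code{mi_trial} with the bank's channel count.
#' @return list of per-class log-variance sub-vectors (one per class), in
#'   class order; \code{unlist()} it for the flat block.
#' @export
csp_feature_blocks <- function(bank, trial) {
  lapply(seq_along(bank$filters_per_class), function(k) {
    f <- csp_log_variance(trial, bank$filters_per_class[[k]])
    names(f) <- sprintf("csp.c%d.f%d", bank$classes[k], seq_along(f))
    f
  })
}
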