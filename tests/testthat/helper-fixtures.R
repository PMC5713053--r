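# Shared fixture builders; everything is generated in code at test time.

# Random band-limited (8-30 Hz) signal: sum of sinusoids with random
# frequencies and phases, the signal family the decomposition targets.
rand_bandlimited <- function(n = 250, fs = 250, n_sin = 6,
                             fmin = 8, fmax = 30) {
  tt <- (seq_len(n) - 1) / fs
  f <- stats::runif(n_sin, fmin, fmax)
  ph <- stats::runif(n_sin, 0, 2 * pi)
  rowSums(vapply(seq_len(n_sin),
                 function(i) sin(2 * pi * f[i] * tt + ph[i]),
                 numeric(n)))
}

# Random symmetric positive-definite matrix with a safe eigenvalue floor.
rand_spd <- function(n) {
  a <- matrix(stats::rnorm(n * n), n)
  crossprod(a) / n + diag(0.5, n)
}

# Small labelled Gaussian-cloud feature sets for classifier tests.
gaussian_clouds <- function(n_per_class, d, n_classes, sep = 3) {
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  centers <- matrix(stats::rnorm(n_classes * d), n_classes) * sep
  x <- centers[labels + 1, , drop = FALSE] + matrix(stats::rnorm(n * d), n)
  list(x = x, labels = labels)
}

# Tiny synthetic MI trial set reused by fusion/pipeline tests (cheap to build
# but full-geometry: 22 channels so the augmented montage has 31 rows).
tiny_mi_trials <- function(n_per_class = 3, n_channels = 22, seed = 42) {
  generate_synthetic_mi(synthetic_config(
    n_trials_per_class = n_per_class, n_channels = n_channels,
    n_informative_channels = 4, snr = 2, seed = seed))
}

# Independent re-implementation of the mean-curve extrema rule, used as the
# brute-force oracle: literal loops, no interpolation helper shared with the
# implementation.
oracle_mean_curve <- function(x, a = 0.5) {
  d <- sign(diff(x))
  nz <- which(d != 0)
  dn <- d[nz]
  idx <- integer(0)
  for (i in seq_len(length(dn) - 1)) {
    if (dn[i] * dn[i + 1] < 0) idx <- c(idx, nz[i] + 1)
  }
  tau <- idx
  X <- x[idx]
  K <- length(tau)
  taus <- c(2 * tau[1] - tau[2], tau, 2 * tau[K] - tau[K - 1])
  Xs <- c(X[2], X, X[K - 1])
  ctrl <- numeric(K)
  for (k in seq_len(K)) {
    t0 <- taus[k]; t1 <- taus[k + 1]; t2 <- taus[k + 2]
    L <- Xs[k] + (Xs[k + 2] - Xs[k]) * (t1 - t0) / (t2 - t0)
    ctrl[k] <- a * L + (1 - a) * Xs[k + 1]
  }
  out <- numeric(length(x))
  for (tt in seq_along(x)) {
    if (tt <= tau[1]) { out[tt] <- ctrl[1]; next }
    if (tt >= tau[K]) { out[tt] <- ctrl[K]; next }
    k <- max(which(tau <= tt))
    w <- (tt - tau[k]) / (tau[k + 1] - tau[k])
    out[tt] <- (1 - w) * ctrl[k] + w * ctrl[k + 1]
  }
  out
}

# Ridge-regularized LDA fitted by explicit eigendecomposition of
# within/between scatter — the independent oracle for SRDA's discriminant
# subspace (never used by the implementation).
eigen_rlda <- function(x, y, alpha = 0.01) {
  classes <- sort(unique(y))
  mu <- colMeans(x)
  sw <- matrix(0, ncol(x), ncol(x))
  sb <- matrix(0, ncol(x), ncol(x))
  for (k in classes) {
    xk <- x[y == k, , drop = FALSE]
    muk <- colMeans(xk)
    sw <- sw + crossprod(sweep(xk, 2, muk))
    sb <- sb + nrow(xk) * tcrossprod(muk - mu)
  }
  e <- eigen(solve(sw + diag(alpha, ncol(x)), sb))
  v <- Re(e$vectors[, seq_len(length(classes) - 1), drop = FALSE])
  z <- sweep(x, 2, mu) %*% v
  cent <- do.call(rbind, lapply(classes, function(k)
    colMeans(z[y == k, , drop = FALSE])))
  list(predict = function(xx) {
    zz <- sweep(xx, 2, mu) %*% v
    d2 <- outer(rowSums(zz^2), rowSums(cent^2), "+") - 2 * zz %*% t(cent)
    classes[apply(d2, 1, which.min)]
  })
}
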