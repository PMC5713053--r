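# Single-pass transfer-function magnitude of the designed band-pass at a
# given frequency, evaluated directly from the polynomial coefficients —
# independent of the filtering code path.
butter_gain <- function(f, fs, low = 8, high = 30, order = 5) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  Mod(sum(bf$b * z) / sum(bf$a * z))
}

test_that("band-pass filter preserves in-band tones and rejects out-of-band ones", {
  fs <- 250
  tt <- (0:999) / fs
  keep <- 126:875  # discard 0.5 s edges

  x20 <- sin(2 * pi * 20 * tt)
  y20 <- bandpass_filter(x20, fs)
  g20 <- butter_gain(20, fs)^2  # forward-backward squares the magnitude
  expect_gt(g20, 0.95)          # oracle: 20 Hz sits flat in the passband
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(y20[keep]) / rms(x20[keep]) - 1), 0.05)

  x50 <- sin(2 * pi * 50 * tt)
  y50 <- bandpass_filter(x50, fs)
  atten_db <- -20 * log10(rms(y50[keep]) / rms(x50[keep]))
  expect_gt(atten_db, 20)
  expect_gt(-20 * log10(butter_gain(50, fs)), 20)  # already true single-pass

  z <- bandpass_filter(matrix(0, 22, 500), fs)
  expect_identical(dim(z), c(22L, 500L))
  expect_true(all(z == 0))
})

test_that("filtering is linear and validates its inputs", {
  fs <- 250
  set.seed(11)
  x <- rnorm(500); y <- rnorm(500)
  lhs <- bandpass_filter(2.5 * x - 1.5 * y, fs)
  rhs <- 2.5 * bandpass_filter(x, fs) - 1.5 * bandpass_filter(y, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  expect_error(bandpass_filter(x, fs, low = 8, high = 130), "Nyquist")
  expect_error(bandpass_filter(rnorm(10), fs), "too short")
})

test_that("causal single-pass mode differs from zero-phase but keeps the band", {
  fs <- 250
  tt <- (0:999) / fs
  x <- sin(2 * pi * 15 * tt)
  yz <- bandpass_filter(x, fs)
  yc <- bandpass_filter(x, fs, zero_phase = FALSE)
  expect_false(isTRUE(all.equal(yz, yc)))
  expect_gt(sqrt(mean(yc[300:900]^2)), 0.5)
})

test_that("epoching cuts the exact cue-locked slice with labels in order", {
  fs <- 250
  set.seed(3)
  data <- matrix(rnorm(4 * 3000), 4)
  rec <- mi_recording(data, fs, paste0("Ch", 1:4),
                      events = data.frame(onset = c(1, 1200), label = c(1, 3)))
  trials <- epoch_extract(rec)
  expect_length(trials, 2)
  expect_identical(vapply(trials, function(t) ncol(t$x), integer(1)),
                   c(250L, 250L))
  expect_identical(trial_labels(trials), c(1L, 3L))
  # sample values are copied verbatim from the half-open window
  first <- 1200 + floor(2.5 * fs)
  expect_identical(unname(trials[[2]]$x), unname(data[, first:(first + 249)]))

  rec0 <- mi_recording(data, fs, paste0("Ch", 1:4),
                       events = data.frame(onset = integer(0),
                                           label = integer(0)))
  expect_length(epoch_extract(rec0), 0)

  rec_bad <- mi_recording(data, fs, paste0("Ch", 1:4),
                          events = data.frame(onset = 2900, label = 0))
  expect_error(epoch_extract(rec_bad), "exceeds")
})

test_that("synthetic generator is reproducible and leaves the caller's RNG alone", {
  cfg <- synthetic_config(n_trials_per_class = 5, n_channels = 6,
                          n_informative_channels = 4, seed = 9)
  a <- generate_synthetic_mi(cfg)
  b <- generate_synthetic_mi(cfg)
  expect_identical(a, b)

  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_synthetic_mi(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("class-conditional covariance matches the configured spatial loading", {
  cfg <- synthetic_config(n_trials_per_class = 200, n_channels = 12,
                          n_informative_channels = 4, snr = 2, seed = 7)
  trials <- generate_synthetic_mi(cfg)
  labs <- trial_labels(trials)
  emp_cov <- function(k) {
    xs <- trials[labs == k]
    Reduce(`+`, lapply(xs, function(t) tcrossprod(t$x) / ncol(t$x))) /
      length(xs)
  }
  c0 <- emp_cov(0); c1 <- emp_cov(1)
  expect_gt(norm(c0 - c1, "F"), 1)

  # convergence to the configured covariance at n >= 500 trials per class is
  # approximated here at 200/class; the relative error bound already holds
  for (k in 0:1) {
    target <- synthetic_covariance(cfg, k)
    expect_lt(norm(emp_cov(k) - target, "F") / norm(target, "F"), 0.10)
  }
  # informative-channel variance ratio: loaded channel var = 1 + snr
  v1 <- mean(vapply(trials[labs == 0], function(t) var(t$x[1, ]), numeric(1)))
  expect_lt(abs(v1 / (1 + cfg$snr) - 1), 0.10)
})

test_that("at vanishing snr the spatial pipeline scores at chance", {
  cfg <- synthetic_config(n_trials_per_class = 120, n_channels = 12,
                          n_informative_channels = 4, snr = 1e-8, seed = 5)
  trials <- generate_synthetic_mi(cfg)
  labs <- trial_labels(trials)
  set.seed(5)
  test_idx <- sort(unlist(lapply(0:3, function(k) sample(which(labs == k), 40))))
  bank <- ovr_csp(trials[-test_idx], 4)
  x <- t(vapply(trials, function(t) unlist(csp_feature_blocks(bank, t)),
                numeric(4 * 12)))
  model <- fit_srda(x[-test_idx, ], labs[-test_idx])
  acc <- mean(predict_srda(model, x[test_idx, ]) == labs[test_idx])
  expect_lt(abs(acc - 0.25), 0.05)
})

test_that("trials written as delimited text round-trip exactly", {
  trials <- tiny_mi_trials(n_per_class = 2, n_channels = 4)
  dir <- withr::local_tempdir()
  write_trials(trials, dir)
  back <- read_trials(dir)
  expect_identical(trial_labels(back), trial_labels(trials))
  for (i in seq_along(trials)) {
    expect_identical(back[[i]]$x, trials[[i]]$x)
  }
})
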