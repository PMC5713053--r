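#' Band-pass filter a multichannel EEG matrix
#'
#' Applies a fifth-order Butterworth band-pass (default 8--30 Hz, the mu/beta
#' range carrying event-related (de)synchronization) to every row of a
#' channels x samples matrix. Offline use defaults to zero-phase
#' forward-backward filtering; set \code{zero_phase = FALSE} for a causal
#' single pass with real-time parity.
#'
#' @param x numeric matrix (channels x samples) or a numeric vector treated as
#'   one channel.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order (default 5).
#' @param zero_phase logical; forward-backward filtering when TRUE.
#' @return filtered matrix (or vector) of the same shape.
#' @export
bandpass_filter <- function(x, fs, low = 8, high = 30, order = 5,
                            zero_phase = TRUE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist)")
  if (ncol(x) < 3 * order)
    stop("signal too short for a stable order-", order, " filter: need >= ",
         3 * order, " samples, got ", ncol(x))
  if (any(!is.finite(x))) stop("non-finite samples in input")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  run <- if (zero_phase) {
    function(v) signal::filtfilt(bf, v)
  } else {
    function(v) as.numeric(signal::filter(bf, v))
  }
  out <- t(apply(x, 1, run))
  dimnames(out) <- dimnames(x)
  if (vec) out <- drop(out)
  out
}

#' Apply a 50 Hz notch filter
#'
#' Optional mains-hum suppression for ingested recordings (second-order IIR
#' notch). Synthetic data carries no line noise, so this is off the default
#' path.
#'
#' @inheritParams bandpass_filter
#' @param freq notch centre frequency in Hz.
#' @param bw notch bandwidth in Hz.
#' @export
notch_filter <- function(x, fs, freq = 50, bw = 2) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (freq >= fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / fs
  r <- 1 - pi * bw / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  out <- t(apply(x, 1, function(v) as.numeric(signal::filter(b, a, v))))
  dimnames(out) <- dimnames(x)
  if (vec) out <- drop(out)
  out
}

#' Construct a raw multichannel recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names unique channel labels, one per row.
#' @param events data.frame with columns \code{onset} (1-based sample index of
#'   each cue) and \code{label} (integer class in 0..3).
#' @return object of class \code{mi_recording}.
#' @export
mi_recording <- function(data, fs, channel_names = rownames(data), events) {
  data <- as.matrix(data)
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (length(channel_names) != nrow(data))
    stop("one channel name per data row required")
  events <- as.data.frame(events)
  if (!all(c("onset", "label") %in% names(events)))
    stop("events needs 'onset' and 'label' columns")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events),
            class = "mi_recording")
}

#' Construct a single labelled trial
#'
#' @param x channels x samples numeric matrix; rownames carry channel labels.
#' @param label integer class label in 0..3.
#' @return object of class \code{mi_trial}.
#' @export
mi_trial <- function(x, label) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("a trial needs at least 2 samples")
  if (any(!is.finite(x))) stop("trial contains non-finite samples")
  structure(list(x = x, label = as.integer(label)), class = "mi_trial")
}

#' @export
print.mi_trial <- function(x, ...) {
  cat(sprintf("<mi_trial> %d channels x %d samples, label %d\n",
              nrow(x$x), ncol(x$x), x$label))
  invisible(x)
}

#' Cut cue-locked epochs out of a recording
#'
#' Extracts, for every event, the window \code{[onset + t_start, onset +
#' t_end)} seconds (half-open; default 2.5--3.5 s after the cue, the window
#' that discriminates imagery classes best). Sample values are copied verbatim.
#'
#' @param rec an \code{mi_recording}.
#' @param t_start_s,t_end_s window start/end in seconds relative to each
#'   event onset.
#' @return list of \code{mi_trial}, one per event, in event order.
#' @export
epoch_extract <- function(rec, t_start_s = 2.5, t_end_s = 3.5) {
  stopifnot(inherits(rec, "mi_recording"), t_end_s > t_start_s)
  n_samp <- round((t_end_s - t_start_s) * rec$fs)
  total <- ncol(rec$data)
  out <- vector("list", nrow(rec$events))
  for (i in seq_len(nrow(rec$events))) {
    first <- rec$events$onset[i] + floor(t_start_s * rec$fs)
    last <- first + n_samp - 1
    if (first < 1 || last > total)
      stop("event ", i, " window [", first, ", ", last,
           "] exceeds recording of ", total, " samples")
    out[[i]] <- mi_trial(rec$data[, first:last, drop = FALSE],
                         rec$events$label[i])
  }
  out
}

# 10-20 labels ordered so the sensorimotor strip comes first: the generator's
# informative channels are always a prefix and so always include C3/C4/Cz.
mi_montage <- function(n_channels) {
  base <- c("C3", "C4", "Cz", "C1", "C2", "CP1", "CP2", "FC1", "FC2",
            "CP3", "CP4", "FC3", "FC4", "CPz", "FCz", "C5", "C6",
            "Fz", "Pz", "P1", "P2", "POz")
  if (n_channels <= length(base)) base[seq_len(n_channels)]
  else c(base, paste0("Ch", seq.int(length(base) + 1, n_channels)))
}

#' Configuration for the synthetic motor-imagery generator
#'
#' @param n_trials_per_class trials generated for each of the four classes.
#' @param n_channels total channel count (montage prefix C3, C4, Cz, ...).
#' @param n_informative_channels channels carrying the class-dependent rhythm.
#' @param fs sampling rate in Hz.
#' @param epoch_seconds epoch length in seconds.
#' @param snr ratio of class-rhythm power to unit background-noise power on the
#'   most strongly loaded channel.
#' @param n_classes number of imagery classes.
#' @param seed integer seed; the generator is a pure function of the config.
#' @export
synthetic_config <- function(n_trials_per_class = 100, n_channels = 22,
                             n_informative_channels = 4, fs = 250,
                             epoch_seconds = 1, snr = 2, n_classes = 4,
                             seed = 1) {
  if (n_informative_channels > n_channels)
    stop("n_informative_channels cannot exceed n_channels")
  if (snr <= 0) stop("snr must be positive")
  if (n_channels < 1 || n_trials_per_class < 1) stop("counts must be >= 1")
  structure(list(n_trials_per_class = n_trials_per_class,
                 n_channels = n_channels,
                 n_informative_channels = n_informative_channels,
                 fs = fs, epoch_seconds = epoch_seconds, snr = snr,
                 n_classes = n_classes, seed = as.integer(seed)),
            class = "mi_synthetic_config")
}

# Class-k spatial loading over the informative channels: channel j gets gain 1
# when j == k (mod n_classes), 0.3 otherwise, so each class concentrates its
# rhythm on a distinct subset and class covariances are rank-one distinct.
synthetic_gains <- function(cfg) {
  g <- matrix(0, cfg$n_classes, cfg$n_channels)
  for (k in seq_len(cfg$n_classes)) {
    for (j in seq_len(cfg$n_informative_channels)) {
      g[k, j] <- if ((j - 1) %% cfg$n_classes == (k - 1)) 1 else 0.3
    }
  }
  colnames(g) <- mi_montage(cfg$n_channels)
  g
}

#' Population spatial covariance implied by a synthetic configuration
#'
#' Returns the channels x channels covariance \eqn{I + snr \, g_k g_k^T} that
#' trials of class \code{label} are drawn around, for checking generator
#' calibration against sample covariances.
#'
#' @param cfg a \code{synthetic_config}.
#' @param label class label in 0..(n_classes-1).
#' @export
synthetic_covariance <- function(cfg, label) {
  g <- synthetic_gains(cfg)[label + 1, ]
  diag(cfg$n_channels) + cfg$snr * tcrossprod(g)
}

#' Generate synthetic four-class motor-imagery trials
#'
#' Each trial is broadband unit-variance Gaussian noise on every channel plus,
#' on the informative channels, a shared band-limited rhythm (sum of sinusoids
#' at random frequencies in 8--30 Hz with random phases, normalized to unit
#' power) scaled per channel by a class-specific loading. The resulting
#' class-conditional covariance is \eqn{I + snr \, g_k g_k^T}
#' (see \code{\link{synthetic_covariance}}). Classes are balanced and trials
#' are emitted in interleaved class order; the output is a pure function of
#' the config (including its seed).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param n_sinusoids sinusoids summed into the rhythm carrier.
#' @return list of \code{mi_trial}.
#' @export
generate_synthetic_mi <- function(cfg, n_sinusoids = 8) {
  stopifnot(inherits(cfg, "mi_synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n_samp <- round(cfg$epoch_seconds * cfg$fs)
  tt <- (seq_len(n_samp) - 1) / cfg$fs
  gains <- synthetic_gains(cfg)
  ch_names <- mi_montage(cfg$n_channels)
  trials <- vector("list", cfg$n_trials_per_class * cfg$n_classes)
  idx <- 1
  for (tr in seq_len(cfg$n_trials_per_class)) {
    for (k in seq_len(cfg$n_classes)) {
      freqs <- stats::runif(n_sinusoids, 8, 30)
      phases <- stats::runif(n_sinusoids, 0, 2 * pi)
      s <- rowSums(vapply(seq_len(n_sinusoids),
                          function(i) sin(2 * pi * freqs[i] * tt + phases[i]),
                          numeric(n_samp)))
      s <- s / stats::sd(s)
      x <- matrix(stats::rnorm(cfg$n_channels * n_samp), cfg$n_channels)
      x <- x + sqrt(cfg$snr) * tcrossprod(gains[k, ], s)
      rownames(x) <- ch_names
      trials[[idx]] <- mi_trial(x, k - 1)
      idx <- idx + 1
    }
  }
  trials
}

# Save/restore the global RNG state so generators with their own seed do not
# perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Labels of a trial list
#' @param trials list of \code{mi_trial}.
#' @return integer vector of class labels.
#' @export
trial_labels <- function(trials) {
  vapply(trials, function(tr) tr$label, integer(1))
}

#' Write trials to a directory of delimited matrices
#'
#' One tab-delimited file per trial (rows = channels, first column the channel
#' name) plus \code{labels.tsv} with columns \code{trial_id}, \code{label}.
#' Values are printed with 17 significant digits so a read round-trips
#' bit-exactly.
#'
#' @param trials list of \code{mi_trial}.
#' @param dir output directory (created if missing).
#' @export
write_trials <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- sprintf("trial_%04d", seq_along(trials))
  for (i in seq_along(trials)) {
    x <- trials[[i]]$x
    lines <- vapply(seq_len(nrow(x)), function(r) {
      paste(c(rownames(x)[r], sprintf("%.17g", x[r, ])), collapse = "\t")
    }, character(1))
    writeLines(lines, file.path(dir, paste0(ids[i], ".tsv")))
  }
  labs <- data.frame(trial_id = ids, label = trial_labels(trials))
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ids)
}

#' Read trials written by \code{\link{write_trials}}
#' @param dir directory containing per-trial .tsv files and labels.tsv.
#' @return list of \code{mi_trial}.
#' @export
read_trials <- function(dir) {
  labs <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labs)), function(i) {
    f <- file.path(dir, paste0(labs$trial_id[i], ".tsv"))
    rows <- strsplit(readLines(f), "\t", fixed = TRUE)
    x <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    rownames(x) <- vapply(rows, `[[`, character(1), 1)
    mi_trial(x, labs$label[i])
  })
}

#' Generate a labelled synthetic feature matrix with planted informative columns
#'
#' Benchmark input for wrapper feature selection: the first
#' \code{n_informative} columns are class-dependent Gaussians (class k's mean
#' pattern is \code{effect} on the informative columns it loads, alternating
#' by column), the remaining \code{n_noise} columns are pure standard normal
#' noise for every class.
#'
#' @param n_per_class trials per class.
#' @param n_informative informative columns (the prefix).
#' @param n_noise uninformative columns.
#' @param n_classes number of classes.
#' @param effect mean separation of the informative columns.
#' @param seed integer seed.
#' @return list with \code{x} (matrix), \code{labels}, \code{informative}
#'   (logical column mask).
#' @export
generate_synthetic_features <- function(n_per_class = 100, n_informative = 6,
                                        n_noise = 24, n_classes = 4,
                                        effect = 1.5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- n_informative + n_noise
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  x <- matrix(stats::rnorm(n * d), n, d)
  # class k pushes the informative columns j with j == k (mod n_classes) up
  # and the rest down, giving every class a distinct mean pattern
  for (k in seq_len(n_classes)) {
    rows <- labels == (k - 1)
    for (j in seq_len(n_informative)) {
      mu <- if ((j - 1) %% n_classes == (k - 1)) effect else -effect / 3
      x[rows, j] <- x[rows, j] + mu
    }
  }
  colnames(x) <- c(sprintf("inf%d", seq_len(n_informative)),
                   sprintf("noise%d", seq_len(n_noise)))
  perm <- sample(n)
  list(x = x[perm, , drop = FALSE], labels = labels[perm],
       informative = c(rep(TRUE, n_informative), rep(FALSE, n_noise)))
}
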