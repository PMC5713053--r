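#' Stack LCD components of selected channels under a trial
#'
#' Decomposes each requested channel (default C3, C4, Cz, the channels most
#' involved in hand/foot/tongue imagery) into up to
#' \code{cfg$max_components} intrinsic scale components and appends them as
#' extra rows below the original channels, channel-major
#' (C3.ISC1..3, C4.ISC1..3, Cz.ISC1..3). If a channel yields fewer components
#' than \code{cfg$max_components} the missing rows are zero, keeping the
#' augmented dimension fixed. With the 22-channel montage and 3 channels this
#' yields the 31-row trial that the spatial filter bank operates on.
#'
#' @param trial an \code{mi_trial} with named channel rows.
#' @param lcd_channels channel names to decompose; may be empty (identity).
#' @param cfg a \code{\link{sift_config}}.
#' @return augmented \code{mi_trial}.
#' @export
augment_channels <- function(trial, lcd_channels = c("C3", "C4", "Cz"),
                             cfg = sift_config()) {
  if (length(lcd_channels) == 0) return(trial)
  missing <- setdiff(lcd_channels, rownames(trial$x))
  if (length(missing) > 0)
    stop("channels not present in trial: ", paste(missing, collapse = ", "))
  n_samp <- ncol(trial$x)
  isc_rows <- lapply(lcd_channels, function(ch) {
    d <- lcd_decompose(trial$x[ch, ], cfg)
    rows <- matrix(0, cfg$max_components, n_samp)
    for (p in seq_along(d$components)) rows[p, ] <- d$components[[p]]
    rownames(rows) <- sprintf("%s.ISC%d", ch, seq_len(cfg$max_components))
    rows
  })
  mi_trial(rbind(trial$x, do.call(rbind, isc_rows)), trial$label)
}

#' Frequency-domain feature block F1 of a trial
#'
#' Concatenates \code{\link{isc_feature_vector}} over the K intrinsic scale
#' components of the selected channels (K = 9 for three channels at three
#' components each), giving \code{K * n_features} descriptors (180 by
#' default).
#'
#' @inheritParams augment_channels
#' @param fs sampling rate in Hz.
#' @param n_features sub-band descriptors per component.
#' @return list of K named per-component sub-vectors, in channel-major order;
#'   \code{unlist()} it for the flat block.
#' @export
extract_f1 <- function(trial, lcd_channels = c("C3", "C4", "Cz"),
                       cfg = sift_config(), fs = 250, n_features = 20) {
  missing <- setdiff(lcd_channels, rownames(trial$x))
  if (length(missing) > 0)
    stop("channels not present in trial: ", paste(missing, collapse = ", "))
  blocks <- list()
  for (ch in lcd_channels) {
    d <- lcd_decompose(trial$x[ch, ], cfg)
    for (p in seq_len(cfg$max_components)) {
      comp <- if (p <= length(d$components)) d$components[[p]]
              else rep(0, ncol(trial$x))
      f <- isc_feature_vector(comp, fs, n_features)
      names(f) <- sprintf("f1.%s.ISC%d.b%d", ch, p, seq_along(f))
      blocks[[paste0(ch, ".ISC", p)]] <- f
    }
  }
  blocks
}

#' Serially fuse frequency-domain and spatial feature blocks
#'
#' Divides every constituent sub-vector by its Euclidean norm and concatenates
#' them: first the K frequency sub-vectors, then the per-class spatial
#' sub-vectors, giving \code{K*P + n_classes*N} fused features (304 for the
#' default K = 9, P = 20, N = 31 four-class geometry).
#'
#' @param f1 list of frequency-domain sub-vectors (or a single numeric vector,
#'   treated as one block).
#' @param f2 list of spatial sub-vectors (or a single numeric vector).
#' @return object of class \code{mi_feature_vector} with fields \code{fused},
#'   \code{f1_block}, \code{f2_block}, \code{block_boundaries}.
#' @export
serial_fuse <- function(f1, f2) {
  as_blocks <- function(f, tag) {
    if (is.numeric(f)) f <- list(f)
    if (length(f) == 0) stop(tag, " block is empty")
    f
  }
  f1 <- as_blocks(f1, "f1")
  f2 <- as_blocks(f2, "f2")
  norm_block <- function(v, id) {
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv == 0)
      stop("sub-vector '", id, "' has zero or non-finite norm")
    v / nv
  }
  ids1 <- if (is.null(names(f1))) sprintf("f1[%d]", seq_along(f1)) else names(f1)
  ids2 <- if (is.null(names(f2))) sprintf("f2[%d]", seq_along(f2)) else names(f2)
  n1 <- mapply(norm_block, f1, ids1, SIMPLIFY = FALSE)
  n2 <- mapply(norm_block, f2, ids2, SIMPLIFY = FALSE)
  f1_flat <- unlist(n1)
  f2_flat <- unlist(n2)
  bounds <- cumsum(c(vapply(n1, length, integer(1)),
                     vapply(n2, length, integer(1))))
  names(bounds) <- c(ids1, ids2)
  structure(list(fused = c(f1_flat, f2_flat),
                 f1_block = f1_flat, f2_block = f2_flat,
                 block_boundaries = bounds),
            class = "mi_feature_vector")
}

#' Fit the feature-extraction stage on training trials
#'
#' Augments every training trial with its LCD components and fits the
#' one-vs-rest CSP bank on the augmented channel set. The returned extractor
#' is then applied unchanged to any trial (training or held out), so no
#' test-set information enters the spatial filters.
#'
#' @param train_trials labelled training trials covering every class.
#' @param lcd_channels channels decomposed by LCD.
#' @param cfg a \code{\link{sift_config}}.
#' @param fs sampling rate in Hz.
#' @param n_isc_features sub-band descriptors per component (P).
#' @param n_classes number of classes.
#' @return object of class \code{mi_extractor}.
#' @export
fit_feature_extractor <- function(train_trials,
                                  lcd_channels = c("C3", "C4", "Cz"),
                                  cfg = sift_config(), fs = 250,
                                  n_isc_features = 20, n_classes = 4) {
  aug <- lapply(train_trials, augment_channels, lcd_channels = lcd_channels,
                cfg = cfg)
  bank <- ovr_csp(aug, n_classes = n_classes)
  out <- structure(list(bank = bank, lcd_channels = lcd_channels, cfg = cfg,
                        fs = fs, n_isc_features = n_isc_features,
                        n_classes = n_classes),
                   class = "mi_extractor")
  attr(out, "train_augmented") <- aug
  out
}

# Fused features of a trial that has already been LCD-augmented; shared by
# the public extractors so each trial is decomposed exactly once.
features_from_augmented <- function(extractor, aug) {
  f1 <- list()
  k <- 1
  for (ch in extractor$lcd_channels) {
    for (p in seq_len(extractor$cfg$max_components)) {
      row <- aug$x[sprintf("%s.ISC%d", ch, p), ]
      f <- isc_feature_vector(row, extractor$fs, extractor$n_isc_features)
      names(f) <- sprintf("f1.%s.ISC%d.b%d", ch, p, seq_along(f))
      f1[[k]] <- f
      names(f1)[k] <- paste0(ch, ".ISC", p)
      k <- k + 1
    }
  }
  f2 <- csp_feature_blocks(extractor$bank, aug)
  names(f2) <- sprintf("csp.c%d", extractor$bank$classes)
  serial_fuse(f1, f2)
}

#' Fused feature vector of one trial under a fitted extractor
#'
#' @param extractor an \code{mi_extractor}.
#' @param trial an \code{mi_trial}.
#' @return an \code{mi_feature_vector}.
#' @export
extract_trial_features <- function(extractor, trial) {
  aug <- augment_channels(trial, extractor$lcd_channels, extractor$cfg)
  features_from_augmented(extractor, aug)
}

#' Fused feature matrix of a trial list
#'
#' @param extractor an \code{mi_extractor}.
#' @param trials list of \code{mi_trial}.
#' @return numeric matrix, one row per trial, named feature columns.
#' @export
extract_features <- function(extractor, trials) {
  rows <- lapply(trials, function(tr) extract_trial_features(extractor, tr)$fused)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as delimited text
#'
#' One row per trial, named feature columns, labels column last.
#'
#' @param features numeric matrix from \code{\link{extract_features}}.
#' @param labels integer labels, one per row.
#' @param path output file.
#' @export
write_feature_table <- function(features, labels, path) {
  df <- as.data.frame(features)
  df$label <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
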