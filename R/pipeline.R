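#' Full pipeline configuration
#'
#' Bundles every stage's settings: preprocessing band and order, epoch window,
#' LCD sifting, CSP, FA-LA selection, SRDA regularization, cross-validation
#' folds, and the run seed.
#'
#' @param fs sampling rate of the trials in Hz.
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param zero_phase forward-backward filtering when TRUE.
#' @param epoch_window cue-relative epoch window in seconds (used when
#'   starting from a recording rather than epoched trials).
#' @param lcd_channels channels decomposed by LCD.
#' @param sift a \code{\link{sift_config}}.
#' @param n_isc_features sub-band descriptors per component.
#' @param fa_la a \code{\link{fa_la_config}} (its seed is overridden by
#'   \code{seed}).
#' @param select run FA-LA selection (TRUE) or classify on all fused features.
#' @param alpha_reg final SRDA ridge regularizer.
#' @param n_classes number of classes.
#' @param test_fraction held-out fraction for \code{\link{run_pipeline}}.
#' @param folds cross-validation folds.
#' @param seed master seed for splits and selection.
#' @export
pipeline_config <- function(fs = 250, band = c(8, 30), filter_order = 5,
                            zero_phase = TRUE, epoch_window = c(2.5, 3.5),
                            lcd_channels = c("C3", "C4", "Cz"),
                            sift = sift_config(), n_isc_features = 20,
                            fa_la = fa_la_config(), select = TRUE,
                            alpha_reg = 0.01, n_classes = 4,
                            test_fraction = 0.25, folds = 10, seed = 1) {
  structure(list(fs = fs, band = band, filter_order = filter_order,
                 zero_phase = zero_phase, epoch_window = epoch_window,
                 lcd_channels = lcd_channels, sift = sift,
                 n_isc_features = n_isc_features, fa_la = fa_la,
                 select = select, alpha_reg = alpha_reg,
                 n_classes = n_classes, test_fraction = test_fraction,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "mi_pipeline_config")
}

preprocess_trials <- function(trials, cfg) {
  lapply(trials, function(tr) {
    mi_trial(bandpass_filter(tr$x, cfg$fs, cfg$band[1], cfg$band[2],
                             cfg$filter_order, cfg$zero_phase), tr$label)
  })
}

fit_stage <- function(train_trials, cfg) {
  extractor <- tryCatch(
    fit_feature_extractor(train_trials, cfg$lcd_channels, cfg$sift,
                          fs = cfg$fs, n_isc_features = cfg$n_isc_features,
                          n_classes = cfg$n_classes),
    error = function(e) stop("feature-extraction stage: ",
                             conditionMessage(e), call. = FALSE))
  aug_tr <- attr(extractor, "train_augmented")
  attr(extractor, "train_augmented") <- NULL
  x_tr <- do.call(rbind, lapply(aug_tr, function(a) {
    features_from_augmented(extractor, a)$fused
  }))
  rownames(x_tr) <- NULL
  y_tr <- trial_labels(train_trials)
  if (cfg$select) {
    fa_cfg <- cfg$fa_la
    fa_cfg$seed <- cfg$seed
    sel <- tryCatch(run_fa_la(x_tr, y_tr, fa_cfg, cfg$n_classes),
                    error = function(e) stop("selection stage: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    mask <- sel$mask
  } else {
    sel <- NULL
    mask <- rep(TRUE, ncol(x_tr))
  }
  model <- tryCatch(
    fit_srda(x_tr[, mask, drop = FALSE], y_tr, cfg$alpha_reg),
    error = function(e) stop("classification stage: ", conditionMessage(e),
                             call. = FALSE))
  list(extractor = extractor, selection = sel, mask = mask, model = model)
}

predict_stage <- function(fit, test_trials, cfg) {
  x_te <- extract_features(fit$extractor, test_trials)
  predict_srda(fit$model, x_te[, fit$mask, drop = FALSE])
}

#' Run the full processing chain on epoched trials
#'
#' Band-passes every trial, splits them into stratified training and test
#' sets, fits feature extraction (LCD augmentation + one-vs-rest CSP), runs
#' FA-LA wrapper selection on the training features, fits the final SRDA on
#' the selected subset, and evaluates on the held-out test set. All fitting
#' uses training data only; the run is deterministic given (trials, cfg).
#'
#' @param trials labelled list of \code{mi_trial} covering every class.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list with \code{metrics} (test-set \code{mi_metrics}),
#'   \code{selection}, \code{mask}, \code{fused_dim}, \code{test_index},
#'   \code{predictions}.
#' @export
run_pipeline <- function(trials, cfg = pipeline_config()) {
  labs <- trial_labels(trials)
  present <- sort(unique(labs))
  expected <- seq_len(cfg$n_classes) - 1L
  if (!all(expected %in% present))
    stop("split stage: classes missing from input: ",
         paste(setdiff(expected, present), collapse = ", "))
  trials <- preprocess_trials(trials, cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  test_idx <- stratified_split(labs, cfg$test_fraction)
  fit <- fit_stage(trials[-test_idx], cfg)
  pred <- predict_stage(fit, trials[test_idx], cfg)
  metrics <- evaluate(labs[test_idx], pred, cfg$n_classes)
  list(metrics = metrics, selection = fit$selection, mask = fit$mask,
       fused_dim = length(fit$mask), test_index = test_idx,
       predictions = pred)
}

# Deterministic stratified fold assignment: within each class, trials are
# dealt round-robin over folds after a seed-driven shuffle.
fold_assignment <- function(labels, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assign <- integer(length(labels))
  for (k in sort(unique(labels))) {
    idx <- sample(which(labels == k))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validation of the full chain
#'
#' All fitting (LCD/CSP extraction, FA-LA selection, SRDA) happens inside each
#' training fold; the fold's test set only ever meets the frozen extractor,
#' mask and model.
#'
#' @param trials labelled list of \code{mi_trial}.
#' @param cfg a \code{\link{pipeline_config}}.
#' @param folds number of folds (default from \code{cfg}).
#' @return object of class \code{mi_cv_report}: per-fold metrics, mean/sd
#'   accuracy and kappa, per-fold selected-feature counts, fold assignment.
#' @export
cross_validate <- function(trials, cfg = pipeline_config(),
                           folds = cfg$folds) {
  labs <- trial_labels(trials)
  counts <- table(labs)
  if (any(counts < folds))
    stop("fold stage: every class needs >= ", folds, " trials; counts: ",
         paste(counts, collapse = ", "))
  trials <- preprocess_trials(trials, cfg)
  assign <- fold_assignment(labs, folds, cfg$seed)
  fold_metrics <- vector("list", folds)
  sel_counts <- integer(folds)
  for (f in seq_len(folds)) {
    fit <- fit_stage(trials[assign != f], cfg)
    pred <- predict_stage(fit, trials[assign == f], cfg)
    fold_metrics[[f]] <- evaluate(labs[assign == f], pred, cfg$n_classes)
    sel_counts[f] <- sum(fit$mask)
  }
  acc <- vapply(fold_metrics, `[[`, numeric(1), "accuracy")
  kap <- vapply(fold_metrics, `[[`, numeric(1), "kappa")
  structure(list(fold_metrics = fold_metrics,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_kappa = mean(kap), sd_kappa = stats::sd(kap),
                 selected_counts = sel_counts, fold_assignment = assign),
            class = "mi_cv_report")
}

#' @export
print.mi_cv_report <- function(x, ...) {
  cat(sprintf("<mi_cv_report> %d folds: accuracy %.4f +/- %.4f, kappa %.4f +/- %.4f\n",
              length(x$fold_metrics), x$mean_accuracy, x$sd_accuracy,
              x$mean_kappa, x$sd_kappa))
  invisible(x)
}
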