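#' Configuration for firefly-automaton feature selection
#'
#' Defaults follow the published setting where one exists: swarm size 50,
#' minimum attractiveness 0.3, random-step coefficient 1, reward/penalty
#' factors a = b = 0.1, and 20 quantized absorption levels on (0, 1].
#'
#' @param pop_size swarm members (N).
#' @param genmax generations.
#' @param alpha random-step coefficient of the firefly move.
#' @param beta_min,beta0 attractiveness bounds (at infinite / zero distance).
#' @param a,b learning-automaton reward and penalty factors in [0,1].
#' @param n_levels quantized absorption-coefficient levels (e).
#' @param alpha_reg ridge regularizer of the wrapped SRDA classifier.
#' @param val_fraction fraction of the data held out as the selection
#'   validation set (stratified, fixed for the whole run).
#' @param fixed_gamma if non-NULL, disables the automaton and runs a plain
#'   firefly search at this absorption coefficient (ablation mode).
#' @param seed integer seed; the run is a pure function of data + config.
#' @export
fa_la_config <- function(pop_size = 50, genmax = 50, alpha = 1,
                         beta_min = 0.3, beta0 = 1, a = 0.1, b = 0.1,
                         n_levels = 20, alpha_reg = 0.01,
                         val_fraction = 0.25, fixed_gamma = NULL, seed = 1) {
  stopifnot(pop_size >= 2, genmax >= 1, n_levels >= 2,
            a >= 0, a <= 1, b >= 0, b <= 1,
            val_fraction > 0, val_fraction < 1, beta0 >= beta_min)
  structure(list(pop_size = as.integer(pop_size), genmax = as.integer(genmax),
                 alpha = alpha, beta_min = beta_min, beta0 = beta0,
                 a = a, b = b, n_levels = as.integer(n_levels),
                 alpha_reg = alpha_reg, val_fraction = val_fraction,
                 fixed_gamma = fixed_gamma, seed = as.integer(seed)),
            class = "mi_fa_la_config")
}

#' Initialize a firefly swarm
#'
#' Positions are i.i.d. uniform on [0,1]^D; entry (i, j) is member i's
#' activation weight for feature j.
#'
#' @param pop_size swarm members.
#' @param d feature dimension.
#' @param seed optional seed set before drawing.
#' @return pop_size x D numeric matrix.
#' @export
init_population <- function(pop_size = 50, d, seed = NULL) {
  if (d < 1) stop("need at least one feature dimension")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(pop_size * d), pop_size, d)
}

#' Feature activation mask of a position vector
#'
#' A feature is active when its weight strictly exceeds 0.5. If no weight
#' does, the single largest weight is activated so the member still encodes a
#' classifiable subset.
#'
#' @param theta numeric position vector with entries in [0,1].
#' @return logical mask of the same length.
#' @export
activate_features <- function(theta) {
  mask <- theta > 0.5
  if (!any(mask)) mask[which.max(theta)] <- TRUE
  mask
}

#' Wrapper fitness of a candidate feature subset
#'
#' Trains SRDA on the training split restricted to the activated features and
#' returns \code{1 / CAv}, the reciprocal of validation accuracy, so better
#' subsets have smaller fitness (minimum 1). Zero validation accuracy maps to
#' a large finite penalty (1e6).
#'
#' @param theta position vector (or a logical mask).
#' @param x_train,y_train training features/labels.
#' @param x_val,y_val validation features/labels (disjoint from training).
#' @param alpha_reg SRDA ridge regularizer.
#' @param n_classes number of classes.
#' @return scalar fitness >= 1.
#' @export
evaluate_fitness <- function(theta, x_train, y_train, x_val, y_val,
                             alpha_reg = 0.01, n_classes = 4) {
  mask <- if (is.logical(theta)) theta else activate_features(theta)
  model <- fit_srda(x_train[, mask, drop = FALSE], y_train, alpha_reg)
  pred <- predict_srda(model, x_val[, mask, drop = FALSE])
  cav <- mean(pred == y_val)
  if (cav <= 0) 1e6 else 1 / cav
}

#' Roulette selection of an absorption level
#'
#' Draws r uniform on (0,1] and returns the first level j whose cumulative
#' probability reaches r: \code{sum(row[1:(j-1)]) < r <= sum(row[1:j])}.
#'
#' @param row probability row over levels (must sum to 1 within 1e-6).
#' @param levels the absorption-coefficient value of each level.
#' @return list with \code{index} and \code{gamma}.
#' @export
select_gamma <- function(row, levels = gamma_levels(length(row))) {
  if (abs(sum(row) - 1) > 1e-6 || any(row < 0))
    stop("malformed probability row (sum = ", format(sum(row)), ")")
  r <- stats::runif(1)
  j <- which(r <= cumsum(row))[1]
  if (is.na(j)) j <- length(row)   # guard against rounding at r ~ 1
  list(index = j, gamma = levels[j])
}

#' Quantized absorption-coefficient levels
#'
#' @param n_levels number of levels; returns the uniform quantization of
#'   (0, 1], i.e. \code{(1:n)/n}.
#' @export
gamma_levels <- function(n_levels = 20) {
  seq_len(n_levels) / n_levels
}

#' Linear reward-penalty update of one automaton row
#'
#' Reward (chosen action j improved the member's fitness):
#' \code{C_j <- C_j + a(1 - C_j)}, all others \code{<- (1-a) C_x}.
#' Penalty: \code{C_j <- (1-b) C_j}, all others
#' \code{<- b/(e-1) + (1-b) C_x}. Both branches preserve row-stochasticity
#' exactly.
#'
#' @param row stochastic probability row.
#' @param j chosen level index.
#' @param improved logical; TRUE applies the reward branch.
#' @param a,b reward/penalty factors.
#' @return updated stochastic row.
#' @export
update_transition_row <- function(row, j, improved, a = 0.1, b = 0.1) {
  e <- length(row)
  if (j < 1 || j > e) stop("invalid level index")
  if (improved) {
    out <- (1 - a) * row
    out[j] <- row[j] + a * (1 - row[j])
  } else {
    out <- b / (e - 1) + (1 - b) * row
    out[j] <- (1 - b) * row[j]
  }
  out
}

#' Firefly attractiveness at a given distance
#'
#' \code{beta(r) = beta_min + (beta0 - beta_min) exp(-gamma r^2)}: full
#' attraction at zero distance, decaying toward the floor \code{beta_min} with
#' rate set by the absorption coefficient.
#'
#' @param r nonnegative distance.
#' @param gamma absorption coefficient (> 0).
#' @param beta_min,beta0 attractiveness bounds.
#' @export
attractiveness <- function(r, gamma, beta_min = 0.3, beta0 = 1) {
  beta_min + (beta0 - beta_min) * exp(-gamma * r^2)
}

#' Move a firefly toward a brighter target
#'
#' \code{theta' = clamp(theta + beta(r) (target - theta) + alpha (u - 0.5))}
#' with u i.i.d. uniform per dimension and r the Euclidean distance measured
#' in units of the expected distance between two uniform random points in
#' [0,1]^D (\code{sqrt(D/6)}). This makes the quantized absorption range
#' dimension-independent while leaving the typical swarm spread at r ~ 1,
#' where the absorption coefficient genuinely modulates the pull strength.
#' The result is clamped back into [0,1]^D.
#'
#' @param theta current position.
#' @param theta_target position of the brighter (better-fitness) member.
#' @param gamma absorption coefficient for this move.
#' @param alpha random-step coefficient.
#' @param beta_min,beta0 attractiveness bounds.
#' @return updated position in [0,1]^D.
#' @export
move_firefly <- function(theta, theta_target, gamma, alpha = 1,
                         beta_min = 0.3, beta0 = 1) {
  d <- length(theta)
  r <- sqrt(sum((theta_target - theta)^2) / (d / 6))
  beta <- attractiveness(r, gamma, beta_min, beta0)
  out <- theta + beta * (theta_target - theta) +
    alpha * (stats::runif(d) - 0.5)
  pmin(pmax(out, 0), 1)
}

# Stratified index split: fraction goes to the second part (validation/test),
# at least one trial per class in each part.
stratified_split <- function(labels, fraction) {
  holdout <- integer(0)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    n_h <- max(1, round(length(idx) * fraction))
    if (n_h >= length(idx))
      stop("class ", k, " has too few trials (", length(idx),
           ") for a ", fraction, " holdout")
    holdout <- c(holdout, sample(idx, n_h))
  }
  sort(holdout)
}

#' Firefly feature selection with automaton-adapted absorption
#'
#' Wrapper feature selection over a feature matrix: each swarm member encodes
#' an activation-weight vector whose thresholded mask is scored by SRDA
#' validation accuracy (fitness = 1/accuracy, minimized). Per generation and
#' member, an absorption coefficient is drawn by roulette from the member's
#' row of the transition matrix, the member moves toward the incumbent best
#' using it, and the row is rewarded when the move improved that member's own
#' previous fitness (linear reward-penalty scheme), penalized otherwise.
#' Elitism re-inserts the incumbent best over the worst member whenever a
#' generation loses it, so the best-fitness history is non-increasing. The
#' whole run is a pure function of (features, labels, config).
#'
#' @param features trials x D numeric matrix.
#' @param labels integer class labels.
#' @param config a \code{\link{fa_la_config}}.
#' @param n_classes number of classes.
#' @return object of class \code{mi_selection} with fields \code{mask},
#'   \code{selected_count}, \code{best_fitness_history} (generation 0 first),
#'   \code{best_member}, \code{best_val_accuracy}, \code{gamma_log}
#'   (genmax x pop_size chosen levels), \code{transition_matrix},
#'   \code{val_index} (rows used for validation).
#' @export
run_fa_la <- function(features, labels, config = fa_la_config(),
                      n_classes = length(unique(labels))) {
  features <- as.matrix(features)
  d <- ncol(features)
  if (d < 2) stop("need at least two features to select from")
  if (length(unique(labels)) < 2) stop("need at least two classes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  val_idx <- stratified_split(labels, config$val_fraction)
  x_tr <- features[-val_idx, , drop = FALSE]
  y_tr <- labels[-val_idx]
  x_va <- features[val_idx, , drop = FALSE]
  y_va <- labels[val_idx]
  fit_of <- function(theta) {
    evaluate_fitness(theta, x_tr, y_tr, x_va, y_va,
                     alpha_reg = config$alpha_reg, n_classes = n_classes)
  }

  pop <- init_population(config$pop_size, d)
  fitness <- apply(pop, 1, fit_of)
  levels <- gamma_levels(config$n_levels)
  cmat <- matrix(1 / config$n_levels, config$pop_size, config$n_levels)
  gamma_log <- matrix(NA_integer_, config$genmax, config$pop_size)

  best_i <- which.min(fitness)
  best_theta <- pop[best_i, ]
  best_fit <- fitness[best_i]
  history <- best_fit

  for (m in seq_len(config$genmax)) {
    target <- best_theta
    for (i in seq_len(config$pop_size)) {
      if (is.null(config$fixed_gamma)) {
        sel <- select_gamma(cmat[i, ], levels)
        gam <- sel$gamma
        gamma_log[m, i] <- sel$index
      } else {
        gam <- config$fixed_gamma
      }
      pop[i, ] <- move_firefly(pop[i, ], target, gam, config$alpha,
                               config$beta_min, config$beta0)
      new_fit <- fit_of(pop[i, ])
      if (is.null(config$fixed_gamma)) {
        cmat[i, ] <- update_transition_row(cmat[i, ], sel$index,
                                           improved = new_fit < fitness[i],
                                           a = config$a, b = config$b)
      }
      fitness[i] <- new_fit
    }
    gen_best <- which.min(fitness)
    if (fitness[gen_best] < best_fit) {
      best_fit <- fitness[gen_best]
      best_theta <- pop[gen_best, ]
    } else {
      worst <- which.max(fitness)   # elitism: restore the incumbent best
      pop[worst, ] <- best_theta
      fitness[worst] <- best_fit
    }
    history <- c(history, best_fit)
  }

  mask <- activate_features(best_theta)
  names(mask) <- colnames(features)
  structure(list(mask = mask, selected_count = sum(mask),
                 best_fitness_history = history, best_member = best_theta,
                 best_val_accuracy = 1 / best_fit,
                 gamma_log = gamma_log, transition_matrix = cmat,
                 val_index = val_idx, config = config),
            class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat(sprintf(paste0("<mi_selection> %d of %d features selected; best ",
                     "validation accuracy %.4f over %d generations\n"),
              x$selected_count, length(x$mask), x$best_val_accuracy,
              length(x$best_fitness_history) - 1))
  invisible(x)
}

#' Write a selection result as structured text
#'
#' Emits \code{mask.tsv} (feature index, name, selected flag),
#' \code{fitness_history.tsv}, and \code{manifest.txt} (all config fields)
#' under \code{dir} for exact replay.
#'
#' @param sel an \code{mi_selection}.
#' @param dir output directory.
#' @export
write_selection <- function(sel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- names(sel$mask)
  if (is.null(nm)) nm <- sprintf("f%d", seq_along(sel$mask))
  utils::write.table(
    data.frame(index = seq_along(sel$mask), name = nm,
               selected = as.integer(sel$mask)),
    file.path(dir, "mask.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(generation = seq_along(sel$best_fitness_history) - 1,
               best_fitness = sel$best_fitness_history),
    file.path(dir, "fitness_history.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- sel$config
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v) paste(format(v), collapse = ","),
                           character(1))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
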