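#' Sifting configuration for local characteristic-scale decomposition
#'
#' @param sd_threshold stop sifting once the iterate-to-iterate standard
#'   deviation criterion falls below this value.
#' @param max_sift_iters hard cap on sifting passes per component.
#' @param max_components components extracted before the rest is declared
#'   residue (three per channel by default).
#' @param baseline_ratio weight of the neighbour-line value in each mean-curve
#'   control point, in (0,1); 0.5 is the standard construction.
#' @export
sift_config <- function(sd_threshold = 0.3, max_sift_iters = 30,
                        max_components = 3, baseline_ratio = 0.5) {
  if (sd_threshold <= 0) stop("sd_threshold must be positive")
  if (max_components < 1) stop("max_components must be >= 1")
  if (baseline_ratio <= 0 || baseline_ratio >= 1)
    stop("baseline_ratio must lie in (0,1)")
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_components = as.integer(max_components),
                 baseline_ratio = baseline_ratio),
            class = "mi_sift_config")
}

# Indices of local extrema: sign changes of the first difference, computed on
# its nonzero entries so flat tops count as a single extremum.
local_extrema_idx <- function(x) {
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  dn <- d[nz]
  ch <- which(dn[-length(dn)] * dn[-1] < 0)
  nz[ch] + 1
}

monotone_error <- function(n_extrema) {
  structure(class = c("mi_monotone_error", "error", "condition"),
            list(message = paste0("signal has ", n_extrema,
                                  " local extrema; need >= 3 to sift"),
                 call = sys.call(-1)))
}

#' Local mean curve of a signal
#'
#' Builds the baseline used by LCD sifting. For each triple of consecutive
#' extrema the control value at the middle extremum is
#' \code{a*L + (1-a)*X} where \code{L} is the straight line joining the two
#' neighbours evaluated there and \code{a = baseline_ratio}; control points are
#' joined by linear interpolation, and the first/last extrema get neighbours by
#' mirror extension of the two nearest extrema.
#'
#' @param x numeric signal with at least 3 local extrema.
#' @param baseline_ratio mixing weight \code{a} in (0,1).
#' @return baseline signal of the same length.
#' @export
local_mean_curve <- function(x, baseline_ratio = 0.5) {
  idx <- local_extrema_idx(x)
  if (length(idx) < 3) stop(monotone_error(length(idx)))
  tau <- idx
  X <- x[idx]
  K <- length(tau)
  taus <- c(2 * tau[1] - tau[2], tau, 2 * tau[K] - tau[K - 1])
  Xs <- c(X[2], X, X[K - 1])
  kk <- 2:(K + 1)
  L <- Xs[kk - 1] + (Xs[kk + 1] - Xs[kk - 1]) *
    (taus[kk] - taus[kk - 1]) / (taus[kk + 1] - taus[kk - 1])
  ctrl <- baseline_ratio * L + (1 - baseline_ratio) * Xs[kk]
  stats::approx(tau, ctrl, xout = seq_along(x), rule = 2)$y
}

#' Sifting stop criterion between consecutive iterates
#'
#' \code{SD = sum_t |h_k(t) - h_km1(t)|^2 / h_km1(t)^2}. Samples where the
#' previous iterate is exactly zero are skipped (the term is undefined there);
#' the number skipped is attached as attribute \code{"skipped"}.
#'
#' @param h_k,h_km1 equal-length numeric signals (current/previous iterate).
#' @return nonnegative scalar with attribute \code{skipped}.
#' @export
compute_sd <- function(h_k, h_km1) {
  if (length(h_k) != length(h_km1)) stop("iterates must have equal length")
  den <- h_km1^2
  keep <- den > 0
  out <- sum((h_k[keep] - h_km1[keep])^2 / den[keep])
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Extract one intrinsic scale component by sifting
#'
#' Repeatedly subtracts the local mean curve until the SD criterion drops below
#' \code{cfg$sd_threshold} or \code{cfg$max_sift_iters} passes are spent.
#'
#' @param x numeric signal with at least 3 local extrema.
#' @param cfg a \code{\link{sift_config}}.
#' @return list with \code{isc}, \code{remainder} (\code{= x - isc}),
#'   \code{sd_trace} (SD per pass) and \code{converged}.
#' @export
sift_isc <- function(x, cfg = sift_config()) {
  h <- x
  sd_trace <- numeric(0)
  converged <- FALSE
  for (k in seq_len(cfg$max_sift_iters)) {
    m <- local_mean_curve(h, cfg$baseline_ratio)
    h_new <- h - m
    sd_k <- as.numeric(compute_sd(h_new, h))
    sd_trace <- c(sd_trace, sd_k)
    h <- h_new
    if (sd_k < cfg$sd_threshold) { converged <- TRUE; break }
    if (length(local_extrema_idx(h)) < 3) break
  }
  list(isc = h, remainder = x - h, sd_trace = sd_trace, converged = converged)
}

#' Local characteristic-scale decomposition
#'
#' Decomposes a signal into up to \code{cfg$max_components} intrinsic scale
#' components (highest local frequency first) plus a residue, by iterated
#' sifting: \code{x = sum(components) + residue} holds to numerical precision
#' by construction. A signal with fewer than 3 extrema yields zero components
#' and \code{residue = x}.
#'
#' @param x numeric signal, length >= 10.
#' @param cfg a \code{\link{sift_config}}.
#' @return object of class \code{mi_lcd} with fields \code{components} (list),
#'   \code{residue}, \code{sd_trace} (list, per component).
#' @export
lcd_decompose <- function(x, cfg = sift_config()) {
  if (length(x) < 10) stop("signal too short to decompose (need >= 10)")
  components <- list()
  traces <- list()
  rem <- x
  for (p in seq_len(cfg$max_components)) {
    if (length(local_extrema_idx(rem)) < 3) break
    s <- sift_isc(rem, cfg)
    components[[p]] <- s$isc
    traces[[p]] <- s$sd_trace
    rem <- s$remainder
  }
  structure(list(components = components, residue = rem, sd_trace = traces),
            class = "mi_lcd")
}

#' @export
print.mi_lcd <- function(x, ...) {
  cat(sprintf("<mi_lcd> %d component(s) + residue, length %d\n",
              length(x$components), length(x$residue)))
  invisible(x)
}

#' Export a decomposition as a plain matrix
#'
#' @param decomp an \code{mi_lcd}.
#' @return matrix with one row per component followed by the residue row.
#' @export
lcd_as_matrix <- function(decomp) {
  m <- do.call(rbind, c(decomp$components, list(decomp$residue)))
  rownames(m) <- c(sprintf("ISC%d", seq_along(decomp$components)), "residue")
  m
}

#' Log sub-band power descriptors of one intrinsic scale component
#'
#' Periodogram power integrated over \code{n_features} equal-width bands
#' spanning \code{band[1]}--\code{band[2]} Hz (default 20 bands over 8--30 Hz,
#' the sensorimotor-rhythm range), reported as log10 with a power floor of
#' 1e-12 so an all-zero component maps to a defined floor value.
#'
#' @param isc numeric signal (one ISC), length >= \code{2 * n_features}.
#' @param fs sampling rate in Hz.
#' @param n_features number of sub-bands.
#' @param band two-element band span in Hz.
#' @return numeric vector of length \code{n_features}.
#' @export
isc_feature_vector <- function(isc, fs, n_features = 20, band = c(8, 30)) {
  n <- length(isc)
  if (n < 2 * n_features)
    stop("ISC too short: need >= ", 2 * n_features, " samples")
  p <- Mod(stats::fft(isc))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  p <- p[half]; freq <- freq[half]
  edges <- seq(band[1], band[2], length.out = n_features + 1)
  out <- vapply(seq_len(n_features), function(b) {
    hi_ok <- if (b == n_features) freq <= edges[b + 1] else freq < edges[b + 1]
    sum(p[freq >= edges[b] & hi_ok])
  }, numeric(1))
  log10(pmax(out, 1e-12))
}
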