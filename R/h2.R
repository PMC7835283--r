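#' Configuration for the nonlinear correlation coefficient h2
#'
#' Tunable parameters of the h2 estimator. `n_bins` equal-width amplitude
#' bins are laid over the observed range of the predictor signal; the
#' piecewise-linear regression curve interpolates the mean target amplitude
#' per bin. The lag scan shifts the target relative to the predictor over
#' `lag_range_ms` in steps of `lag_step_samples` samples and keeps the
#' maximizing lag, which carries the direction-of-coupling information.
#'
#' Defaults (10 bins, at least 10 points per bin, lags within +/-100 ms at
#' every sample) are stable for event windows of 1000 samples or more and
#' cover physiological propagation delays.
#'
#' @param n_bins Number of equal-width amplitude bins (>= 2).
#' @param min_points_per_bin Minimum average points per bin; when a window
#'   is too short, `n_bins` is reduced with a warning.
#' @param lag_range_ms Length-2 numeric, lag scan range in milliseconds
#'   (symmetric about 0 by default).
#' @param lag_step_samples Lag scan step, in samples.
#' @return A list of class `h2_config`.
#' @export
h2_config <- function(n_bins = 10L, min_points_per_bin = 10L,
                      lag_range_ms = c(-100, 100), lag_step_samples = 1L) {
  stopifnot(n_bins >= 2L, min_points_per_bin >= 1L,
            length(lag_range_ms) == 2L, lag_range_ms[1] <= lag_range_ms[2],
            lag_step_samples >= 1L)
  structure(list(n_bins = as.integer(n_bins),
                 min_points_per_bin = as.integer(min_points_per_bin),
                 lag_range_ms = as.numeric(lag_range_ms),
                 lag_step_samples = as.integer(lag_step_samples)),
            class = "h2_config")
}

# reduce bin count when the window is short; shared by regression_curve/h2
effective_bins <- function(n, n_bins, min_points_per_bin) {
  if (n < n_bins * min_points_per_bin) {
    nb <- max(2L, n %/% min_points_per_bin)
    warn(sprintf("window of %d points too short for %d bins; using %d",
                 n, n_bins, nb))
    nb
  } else {
    n_bins
  }
}

#' Piecewise-linear regression curve of y on x
#'
#' Nonparametric predictor underlying h2: the observed range of `x` is
#' partitioned into `n_bins` equal-width bins, and the curve linearly
#' interpolates the points (bin midpoint, mean of `y` in that bin). Empty
#' bins are skipped; beyond the outermost occupied midpoints the curve
#' extrapolates as a constant.
#'
#' @param x,y Equal-length numeric vectors (predictor, target).
#' @param n_bins Number of equal-width bins over the range of `x`.
#' @param min_points_per_bin See [h2_config()].
#' @return An object of class `regression_curve` with fields `midpoints`,
#'   `means` (the knots) and `n_bins`; use `predict()` to evaluate it.
#' @examples
#' x <- seq(-1, 1, length.out = 500)
#' f <- regression_curve(x, x^2, n_bins = 10)
#' predict(f, c(-0.5, 0, 0.5))
#' @export
regression_curve <- function(x, y, n_bins = 10L, min_points_per_bin = 10L) {
  stopifnot(length(x) == length(y))
  n_bins <- effective_bins(length(x), as.integer(n_bins), min_points_per_bin)
  rng <- range(x)
  if (diff(rng) == 0) {
    stop_ictalnet("degenerate predictor: x has zero range",
                  "ictalnet_degenerate_predictor")
  }
  w <- diff(rng) / n_bins
  idx <- pmin(n_bins, floor((x - rng[1]) / w) + 1L)
  cnt <- tabulate(idx, nbins = n_bins)
  sums <- as.vector(rowsum(y, idx, reorder = TRUE))
  occ <- which(cnt > 0L)
  structure(
    list(midpoints = rng[1] + (occ - 0.5) * w,
         means = sums / cnt[occ],
         n_bins = n_bins, range = rng),
    class = "regression_curve")
}

#' @rdname regression_curve
#' @param object A `regression_curve`.
#' @param newdata Numeric vector at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.regression_curve <- function(object, newdata, ...) {
  if (length(object$midpoints) == 1L) {
    return(rep(object$means, length(newdata)))
  }
  approx(object$midpoints, object$means, xout = newdata, rule = 2)$y
}

# fast path used by the lag scan: no object allocation
h2_core <- function(x, y, n_bins) {
  rng <- range(x)
  if (rng[2] == rng[1]) {
    stop_ictalnet("degenerate predictor: x has zero range",
                  "ictalnet_degenerate_predictor")
  }
  w <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(n_bins, floor((x - rng[1]) / w) + 1L)
  cnt <- tabulate(idx, nbins = n_bins)
  sums <- as.vector(rowsum(y, idx, reorder = TRUE))
  occ <- which(cnt > 0L)
  mids <- rng[1] + (occ - 0.5) * w
  means <- sums / cnt[occ]
  pred <- if (length(occ) == 1L) rep(means, length(x)) else {
    approx(mids, means, xout = x, rule = 2)$y
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    stop_ictalnet("zero variance target", "ictalnet_zero_variance")
  }
  clamp01(1 - sum((y - pred)^2) / sst)
}

#' Nonlinear correlation coefficient h2
#'
#' Fraction of the target signal's amplitude variance explained by the
#' piecewise-linear regression of `y` on `x` (see [regression_curve()]):
#' `h2 = max(0, 1 - sum((y - f(x))^2) / sum((y - mean(y))^2))`, clamped to
#' `[0, 1]`. The statistic is asymmetric — `h2(x, y)` generally differs
#' from `h2(y, x)` — which is what lets a pairwise coupling analysis carry
#' direction as well as strength.
#'
#' @param x Predictor amplitudes.
#' @param y Target amplitudes (same length; must have nonzero variance).
#' @param config An [h2_config()].
#' @return A scalar in `[0, 1]`.
#' @examples
#' x <- rnorm(2000)
#' h2(x, x)            # perfect prediction
#' h2(x, x^2 + 0.1 * rnorm(2000))  # strong nonlinear coupling
#' @export
h2 <- function(x, y, config = h2_config()) {
  stopifnot(length(x) == length(y))
  nb <- effective_bins(length(x), config$n_bins, config$min_points_per_bin)
  h2_core(x, y, nb)
}

#' Lag-scanned h2 for one ordered channel pair
#'
#' Computes h2 with the target shifted relative to the predictor for every
#' lag in the configured range and returns the maximum together with the
#' maximizing lag. A positive lag means the target lags the predictor (the
#' pattern expected when the predictor drives the target). Ties are broken
#' toward the smallest absolute lag, then toward the negative lag.
#'
#' @param x Predictor amplitudes.
#' @param y Target amplitudes.
#' @param fs Sampling rate in Hz (converts `lag_range_ms` to samples).
#' @param config An [h2_config()].
#' @return A list with `h2`, `lag_samples` and `lag_ms`.
#' @export
h2_lagged <- function(x, y, fs, config = h2_config()) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  lag_lo <- as.integer(round(config$lag_range_ms[1] * fs / 1000))
  lag_hi <- as.integer(round(config$lag_range_ms[2] * fs / 1000))
  lags <- seq.int(lag_lo, lag_hi, by = config$lag_step_samples)
  if (max(abs(lags)) >= n) {
    stop_ictalnet("window shorter than maximum lag", "ictalnet_lag_error")
  }
  nb <- effective_bins(n - max(abs(lags)), config$n_bins,
                       config$min_points_per_bin)
  vals <- vapply(lags, function(L) {
    if (L >= 0L) h2_core(x[seq_len(n - L)], y[seq.int(1L + L, n)], nb)
    else h2_core(x[seq.int(1L - L, n)], y[seq_len(n + L)], nb)
  }, 1)
  # max h2; ties -> smallest |lag|, then negative lag
  ord <- order(-vals, abs(lags), lags)
  best <- ord[1]
  list(h2 = vals[best], lag_samples = lags[best],
       lag_ms = lags[best] * 1000 / fs)
}

#' Per-event coupling matrix of pairwise h2 values
#'
#' Computes one lag-scanned h2 per ordered channel pair over the whole event
#' window — the temporal bin for individual h2 values is the duration of the
#' clinically defined event, with no sub-windowing. Entry `[i, j]` of the
#' matrix is `h2` predicting channel `j` from channel `i`.
#'
#' @param rec A [seeg_recording()] (the full recording).
#' @param event A one-row [event_annotations()] tibble; the window
#'   `[start_s, end_s)` is extracted with [extract_event()]. Pass `NULL` to
#'   use the whole recording.
#' @param config An [h2_config()].
#' @return An object of class `coupling_matrix`: fields `labels`,
#'   `h2` (n-by-n matrix, `NA` diagonal), `lags` (maximizing lag in
#'   samples), `event` (the annotation row). See [tidy.coupling_matrix()].
#' @export
event_coupling_matrix <- function(rec, event = NULL, config = h2_config()) {
  win <- if (is.null(event)) rec else extract_event(rec, event)
  labs <- win$channel_labels
  n <- length(labs)
  H <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  L <- matrix(NA_integer_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      est <- h2_lagged(win$samples[i, ], win$samples[j, ], win$fs, config)
      H[i, j] <- est$h2
      L[i, j] <- est$lag_samples
    }
  }
  structure(list(labels = labs, h2 = H, lags = L,
                 event = if (is.null(event)) NULL else event),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  ev <- if (is.null(x$event)) "whole recording" else
    sprintf("seizure %s %s [%g, %g) s", x$event$seizure_id[1],
            x$event$phase[1], x$event$start_s[1], x$event$end_s[1])
  cat(sprintf("<coupling_matrix> %d channels, %s\n", length(x$labels), ev))
  print(round(x$h2, 3))
  invisible(x)
}

#' @export
as.matrix.coupling_matrix <- function(x, ...) x$h2

#' Tidy a coupling matrix into a long table
#'
#' @param x A `coupling_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per ordered channel pair: `src`, `dst`,
#'   `h2`, `lag_samples`, plus `seizure_id` and `phase` when the matrix was
#'   computed for an annotated event.
#' @export
tidy.coupling_matrix <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(row(x$h2) != col(x$h2))
  out <- tibble(
    src = x$labels[row(x$h2)[idx]],
    dst = x$labels[col(x$h2)[idx]],
    h2 = x$h2[idx],
    lag_samples = x$lags[idx]
  )
  if (!is.null(x$event)) {
    out <- dplyr::mutate(out,
                         seizure_id = x$event$seizure_id[1],
                         phase = x$event$phase[1],
                         .before = 1)
  }
  dplyr::arrange(out, .data$src, .data$dst)
}

#' Coupling matrices for every annotated event
#'
#' Maps [event_coupling_matrix()] over an annotations table and binds the
#' tidied results, giving the long coupling table used by the group-level
#' statistics.
#'
#' @param rec A [seeg_recording()].
#' @param annotations An [event_annotations()] tibble.
#' @param config An [h2_config()].
#' @param keep_matrices Also return the `coupling_matrix` objects.
#' @return A tibble `seizure_id, phase, src, dst, h2, lag_samples`; when
#'   `keep_matrices` is `TRUE`, that tibble with the matrices attached as
#'   attribute `"matrices"` (a list, in annotation order).
#' @export
event_coupling <- function(rec, annotations, config = h2_config(),
                           keep_matrices = FALSE) {
  mats <- lapply(seq_len(nrow(annotations)), function(i) {
    event_coupling_matrix(rec, annotations[i, ], config)
  })
  out <- dplyr::bind_rows(lapply(mats, tidy))
  if (keep_matrices) attr(out, "matrices") <- mats
  out
}

#' Heat-map of a coupling matrix
#'
#' @param object A `coupling_matrix`.
#' @param ... Unused.
#' @return A ggplot object: tiles coloured by h2, predictor channel on the
#'   y axis, predicted channel on the x axis.
#' @export
autoplot.coupling_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dst, y = .data$src,
                                  fill = .data$h2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted contact", y = "predictor contact",
                  fill = expression(h^2)) +
    ggplot2::theme_minimal()
}
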