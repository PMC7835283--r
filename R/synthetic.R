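# Synthetic SEEG with planted directed coupling, plus streamline phantoms.
#
# The generator exists so that every downstream stage — h2 estimation,
# baseline thresholding, graph construction, clustering, phase statistics,
# tract counting — can be exercised against a known ground truth. Source
# channels are 1-40 Hz band-limited Gaussian noise; a coupled channel is a
# (possibly nonlinear) function of a lagged source plus independent noise,
# so the asymmetric h2 statistic has something real to detect.

#' Directed coupling specification
#'
#' Ground-truth edge list for the signal generator: each row plants one
#' directed dependency `dst = gain * f(src delayed by lag_ms) + noise`.
#'
#' @param src,dst Channel labels (distinct).
#' @param lag_ms Propagation delay in milliseconds (>= 0).
#' @param fun Coupling function: `"linear"` (identity), `"quadratic"`
#'   (squared, standardized) or `"sigmoid"` (`tanh(3 x)` of the
#'   standardized source — bounded and monotone, distinct from the
#'   quadratic).
#' @param gain Coupling strength in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive independent noise,
#'   relative to the unit-variance coupled component.
#' @return A tibble of class `coupling_spec`.
#' @examples
#' coupling_spec("A", "B", lag_ms = 50, fun = "linear", gain = 0.9)
#' @export
coupling_spec <- function(src = character(), dst = character(),
                          lag_ms = numeric(), fun = character(),
                          gain = numeric(), noise_sd = numeric()) {
  n <- length(src)
  if (length(fun) == 0L) fun <- rep("linear", n)
  if (length(lag_ms) == 0L) lag_ms <- rep(0, n)
  if (length(noise_sd) == 0L) noise_sd <- rep(0.1, n)
  if (length(gain) == 0L) gain <- rep(1, n)
  tbl <- tibble(src = as.character(src), dst = as.character(dst),
                lag_ms = as.numeric(lag_ms), fun = as.character(fun),
                gain = as.numeric(gain), noise_sd = as.numeric(noise_sd))
  if (any(tbl$src == tbl$dst)) {
    stop_ictalnet("coupling src must differ from dst", "ictalnet_invalid_spec")
  }
  if (any(tbl$lag_ms < 0)) {
    stop_ictalnet("lag_ms must be >= 0", "ictalnet_invalid_spec")
  }
  if (any(tbl$gain < 0 | tbl$gain > 1)) {
    stop_ictalnet("gain must be in [0, 1]", "ictalnet_invalid_spec")
  }
  if (!all(tbl$fun %in% c("linear", "quadratic", "sigmoid"))) {
    stop_ictalnet("fun must be linear, quadratic or sigmoid",
                  "ictalnet_invalid_spec")
  }
  class(tbl) <- unique(c("coupling_spec", class(tbl)))
  tbl
}

# 1-40 Hz band-limited unit-variance Gaussian noise
band_noise <- function(n, fs, band = c(1, 40)) {
  x <- stats::rnorm(n + 400)
  ny <- fs / 2
  bf <- signal::butter(4, pmin(0.99, band / ny), type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x[201:(200 + n)]
  x / sd(x)
}

apply_coupling_fun <- function(x, fun) {
  z <- (x - mean(x)) / sd(x)
  out <- switch(fun,
    linear = z,
    quadratic = z^2,
    sigmoid = tanh(3 * z),
    stop_ictalnet(sprintf("unknown coupling function '%s'", fun),
                  "ictalnet_invalid_spec"))
  out <- out - mean(out)
  s <- sd(out)
  if (s > 0) out / s else out
}

#' Generate multichannel signals with planted directed coupling
#'
#' Channels without an incoming planted edge are independent 1-40 Hz
#' band-limited Gaussian noise (unit variance, scaled to `amplitude_uv`
#' microvolts). A channel targeted by an edge is
#' `gain * f(src delayed by lag_ms) + noise_sd * noise`, so with gain `g`
#' and noise standard deviation `s` the expected h2 of the true direction
#' is about `g^2 / (g^2 + s^2)`. The edge set must be acyclic (channels are
#' evaluated in dependency order).
#'
#' @param spec A [coupling_spec()] (may have zero rows).
#' @param channel_labels Channels to generate; defaults to the labels in
#'   `spec`.
#' @param duration_s Signal duration in seconds (`duration_s * fs >= 256`).
#' @param fs Sampling rate in Hz; default 200.
#' @param amplitude_uv Physical scale of unit variance, microvolts.
#' @param seed Integer seed; identical seeds give byte-identical samples.
#' @return A [seeg_recording()].
#' @examples
#' spec <- coupling_spec("A", "B", lag_ms = 50, gain = 0.9, noise_sd = 0.1)
#' rec <- generate_coupled_signals(spec, duration_s = 10, seed = 1)
#' @export
generate_coupled_signals <- function(spec = coupling_spec(),
                                     channel_labels = NULL,
                                     duration_s, fs = 200,
                                     amplitude_uv = 50, seed = NULL) {
  if (is.null(channel_labels)) channel_labels <- unique(c(spec$src, spec$dst))
  if (length(channel_labels) == 0L) {
    stop_ictalnet("no channels to generate", "ictalnet_invalid_spec")
  }
  unknown <- setdiff(unique(c(spec$src, spec$dst)), channel_labels)
  if (length(unknown)) {
    stop_ictalnet(sprintf("unknown label in edges: %s",
                          paste(unknown, collapse = ", ")),
                  "ictalnet_invalid_spec")
  }
  n <- round(duration_s * fs)
  if (n < 256) {
    stop_ictalnet("duration_s * fs must be at least 256 samples",
                  "ictalnet_invalid_spec")
  }
  if (anyDuplicated(spec$dst)) {
    stop_ictalnet("at most one planted edge per destination channel",
                  "ictalnet_invalid_spec")
  }
  if (!is.null(seed)) set.seed(seed)
  pad <- if (nrow(spec)) max(round(spec$lag_ms * fs / 1000)) else 0L
  ntot <- n + pad

  # dependency order: sources before their destinations
  order_labels <- character()
  remaining <- channel_labels
  repeat {
    free <- remaining[!remaining %in% spec$dst |
                        vapply(remaining, function(ch) {
                          s <- spec$src[spec$dst == ch]
                          length(s) == 0L || all(s %in% order_labels)
                        }, TRUE)]
    free <- setdiff(free, order_labels)
    if (!length(free)) break
    order_labels <- c(order_labels, free)
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) {
    stop_ictalnet("planted coupling edges form a cycle", "ictalnet_invalid_spec")
  }

  sig <- matrix(0, length(channel_labels), ntot,
                dimnames = list(channel_labels, NULL))
  for (ch in order_labels) {
    k <- which(spec$dst == ch)
    if (length(k) == 0L) {
      sig[ch, ] <- band_noise(ntot, fs)
    } else {
      lag <- round(spec$lag_ms[k] * fs / 1000)
      src <- sig[spec$src[k], ]
      delayed <- c(rep(src[1], lag), src)[seq_len(ntot)]
      coupled <- apply_coupling_fun(delayed, spec$fun[k])
      sig[ch, ] <- spec$gain[k] * coupled +
        spec$noise_sd[k] * band_noise(ntot, fs)
    }
  }
  sig <- sig[, (pad + 1L):ntot, drop = FALSE]
  seeg_recording(sig * amplitude_uv, channel_labels, fs)
}

#' Seizure scenario specification
#'
#' An ordered list of phases — starting with a pre-ictal baseline — each
#' with its own duration, planted coupling and, for the onset phase, a
#' superimposed rhythmic-delta oscillation on the involved contacts (the
#' 4-5 Hz onset pattern typical of insular-onset seizures).
#'
#' @param phases A list of phase descriptions, each a list with elements
#'   `phase` (see [phase_levels()]), `duration_s`, `coupling` (a
#'   [coupling_spec()]), and optionally `rhythm_hz` (numeric; superimposed
#'   sinusoid frequency) and `rhythm_contacts` (labels carrying the rhythm).
#' @param channel_labels Channels of the simulated implantation.
#' @param fs Sampling rate in Hz.
#' @param seizure_id Seizure identifier stamped on the annotations.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(phases, channel_labels, fs = 200, seizure_id = 1L) {
  stopifnot(length(phases) >= 1L)
  if (phases[[1]]$phase != "baseline") {
    stop_ictalnet("scenario must start with a baseline phase",
                  "ictalnet_invalid_spec")
  }
  for (p in phases) {
    if (!p$phase %in% phase_levels()) {
      stop_ictalnet(sprintf("unknown phase '%s'", p$phase),
                    "ictalnet_invalid_spec")
    }
    if (p$duration_s <= 0) {
      stop_ictalnet("phase durations must be > 0", "ictalnet_invalid_spec")
    }
  }
  structure(list(phases = phases, channel_labels = channel_labels,
                 fs = fs, seizure_id = as.integer(seizure_id)),
            class = "scenario_spec")
}

#' Default demonstration scenario
#'
#' A single simulated seizure patterned on a typical insular-onset event:
#' a 20 s pre-ictal baseline with no planted coupling, a 45 s onset with a
#' 4.5 Hz rhythmic-delta oscillation and directed coupling among the
#' anterior-insula contacts (LJ, LK), and an ictal-1 phase in which the
#' coupling spreads to the perisylvian/opercular contacts (LF).
#'
#' The baseline phase is not silent: it carries weak background coupling
#' (low-gain edges drowned in noise), emulating the pre-ictal background
#' functional connectivity of real SEEG. That spread is what the
#' mean-plus-k-sd threshold model is built from; a baseline of perfectly
#' independent channels would give it a degenerate, near-zero standard
#' deviation unlike anything seen in recordings.
#'
#' @param gain Coupling gain of the planted onset/ictal edges.
#' @param noise_sd Additive noise standard deviation of coupled channels.
#' @param seizure_id Seizure identifier.
#' @param ictal1_duration_s Duration of the ictal-1 phase, seconds.
#' @return A [scenario_spec()].
#' @export
demo_scenario <- function(gain = 0.9, noise_sd = 0.1, seizure_id = 1L,
                          ictal1_duration_s = 40) {
  chans <- c("LJ1", "LJ2", "LJ3", "LK1", "LK2", "LF1", "LF2", "LF3")
  onset_edges <- coupling_spec(
    src = c("LJ1", "LJ1", "LJ1", "LK1"),
    dst = c("LJ2", "LJ3", "LK1", "LK2"),
    lag_ms = c(15, 25, 20, 15),
    fun = rep("linear", 4),
    gain = rep(gain, 4), noise_sd = rep(noise_sd, 4))
  ictal1_edges <- coupling_spec(
    src = c("LF1", "LF1"), dst = c("LF2", "LF3"),
    lag_ms = c(15, 25), fun = rep("linear", 2),
    gain = rep(gain, 2), noise_sd = rep(noise_sd, 2))
  baseline_bg <- background_coupling(chans)
  scenario_spec(
    phases = list(
      list(phase = "baseline", duration_s = 20, coupling = baseline_bg),
      list(phase = "onset", duration_s = 45, coupling = onset_edges,
           rhythm_hz = 4.5,
           rhythm_contacts = c("LJ1", "LJ2", "LJ3", "LK1", "LK2")),
      list(phase = "ictal1", duration_s = ictal1_duration_s,
           coupling = ictal1_edges)
    ),
    channel_labels = chans, seizure_id = seizure_id)
}

#' Generate a full seizure scenario
#'
#' Concatenates the phases of a [scenario_spec()] into one recording, with
#' per-phase planted coupling, annotations that tile the phases exactly,
#' and the per-phase ground-truth directed edge sets for recovery scoring.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed; identical seeds give identical samples.
#' @param amplitude_uv Microvolt scale of unit variance.
#' @return A list with elements `recording` (a [seeg_recording()]),
#'   `annotations` (an [event_annotations()] tibble, one row per phase) and
#'   `truth` (named list mapping phase to a tibble of planted `src`, `dst`
#'   edges).
#' @examples
#' sc <- generate_seizure_scenario(demo_scenario(), seed = 1)
#' sc$annotations
#' @export
generate_seizure_scenario <- function(spec, seed = NULL, amplitude_uv = 50) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  blocks <- list(); starts <- numeric(); ends <- numeric()
  truth <- list()
  t0 <- 0
  for (p in spec$phases) {
    rec <- generate_coupled_signals(
      p$coupling, channel_labels = spec$channel_labels,
      duration_s = p$duration_s, fs = spec$fs,
      amplitude_uv = 1, seed = NULL)
    sig <- rec$samples
    if (!is.null(p$rhythm_hz) && length(p$rhythm_contacts %||% character())) {
      tt <- seq_len(ncol(sig)) / spec$fs
      rhythm <- 1.5 * sin(2 * pi * p$rhythm_hz * tt)
      for (ch in p$rhythm_contacts) sig[ch, ] <- sig[ch, ] + rhythm
    }
    blocks[[length(blocks) + 1L]] <- sig
    starts <- c(starts, t0)
    ends <- c(ends, t0 + p$duration_s)
    t0 <- t0 + p$duration_s
    truth[[p$phase]] <- tibble(src = p$coupling$src, dst = p$coupling$dst)
  }
  samples <- do.call(cbind, blocks) * amplitude_uv
  ann <- event_annotations(
    seizure_id = rep(spec$seizure_id, length(spec$phases)),
    phase = vapply(spec$phases, function(p) p$phase, ""),
    start_s = starts, end_s = ends,
    contacts = lapply(spec$phases, function(p) {
      unique(c(p$coupling$src, p$coupling$dst,
               p$rhythm_contacts %||% character()))
    }))
  list(recording = seeg_recording(samples, spec$channel_labels, spec$fs),
       annotations = ann, truth = truth)
}

#' Synthetic streamline phantom with known pairwise counts
#'
#' Builds a labeled region-of-interest volume (E disjoint cubes, labels
#' `1..E`) plus a streamline set in world millimetres in which, for every
#' pair `i < j`, exactly `counts[i, j]` streamlines have one endpoint
#' inside ROI `i` and the other inside ROI `j`. Optional distractor
#' streamlines begin and end in background voxels and must not be counted.
#'
#' @param counts Symmetric E-by-E integer matrix of desired pairwise
#'   streamline counts (zero diagonal).
#' @param n_distractors Number of background-to-background streamlines.
#' @param roi_size Edge length of each cubic ROI in voxels.
#' @param gap Gap between neighbouring ROIs in voxels (>= 2 keeps
#'   nearest-voxel endpoint assignment unambiguous).
#' @param voxel_mm Isotropic voxel size in millimetres.
#' @param seed Integer seed.
#' @return A list of class `streamline_phantom`: `label_volume` (a
#'   [label_volume()]), `streamlines` (list of n-by-3 matrices, world mm),
#'   and `truth_counts`.
#' @export
generate_streamline_phantom <- function(counts, n_distractors = 0L,
                                        roi_size = 3L, gap = 3L,
                                        voxel_mm = 2, seed = NULL) {
  counts <- as.matrix(counts)
  E <- nrow(counts)
  stopifnot(ncol(counts) == E)
  if (any(diag(counts) != 0)) {
    stop_ictalnet("counts must have zero diagonal", "ictalnet_invalid_spec")
  }
  if (any(counts != t(counts))) {
    stop_ictalnet("counts must be symmetric", "ictalnet_invalid_spec")
  }
  if (any(counts < 0)) {
    stop_ictalnet("counts must be nonnegative", "ictalnet_invalid_spec")
  }
  if (!is.null(seed)) set.seed(seed)

  # ROIs laid out on a square lattice with `gap` background voxels between
  ncol_lat <- ceiling(sqrt(E))
  pitch <- roi_size + gap
  dims <- c(ncol_lat * pitch + gap, ncol_lat * pitch + gap, roi_size + 2L * gap)
  vol <- array(0L, dim = dims)
  origins <- matrix(0, E, 3)   # 0-based voxel origin of each ROI cube
  for (e in seq_len(E)) {
    r <- (e - 1L) %/% ncol_lat
    c <- (e - 1L) %% ncol_lat
    o <- c(gap + c * pitch, gap + r * pitch, gap)
    origins[e, ] <- o
    vol[o[1] + seq_len(roi_size), o[2] + seq_len(roi_size),
        o[3] + seq_len(roi_size)] <- e
  }
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- 10  # arbitrary world offset, exercises the affine path
  lv <- label_volume(vol, affine)

  roi_point <- function(e) {
    # world coordinates of a random voxel centre strictly inside ROI e
    v <- origins[e, ] + sapply(seq_len(3), function(k) {
      sample.int(roi_size, 1L) - 1L
    })
    as.vector(affine %*% c(v, 1))[1:3]
  }
  make_streamline <- function(p, q) {
    tt <- seq(0, 1, length.out = 5)
    pts <- outer(1 - tt, p) + outer(tt, q)
    jit <- matrix(stats::runif(length(tt) * 3, -0.2, 0.2) * voxel_mm,
                  length(tt), 3)
    jit[c(1, length(tt)), ] <- 0   # endpoints exact
    pts + jit
  }
  streamlines <- list()
  for (i in seq_len(E)) {
    for (j in seq_len(E)) {
      if (j <= i || counts[i, j] == 0) next
      for (k in seq_len(counts[i, j])) {
        streamlines[[length(streamlines) + 1L]] <-
          make_streamline(roi_point(i), roi_point(j))
      }
    }
  }
  if (n_distractors > 0L) {
    # background corner voxels (first gap slab is label 0 everywhere)
    bg_point <- function() {
      v <- c(sample.int(dims[1], 1L) - 1L, sample.int(dims[2], 1L) - 1L, 0L)
      while (vol[v[1] + 1L, v[2] + 1L, v[3] + 1L] != 0L) {
        v <- c(sample.int(dims[1], 1L) - 1L, sample.int(dims[2], 1L) - 1L, 0L)
      }
      as.vector(affine %*% c(v, 1))[1:3]
    }
    for (k in seq_len(n_distractors)) {
      streamlines[[length(streamlines) + 1L]] <-
        make_streamline(bg_point(), bg_point())
    }
  }
  if (length(streamlines)) {
    streamlines <- streamlines[sample.int(length(streamlines))]
  }
  structure(list(label_volume = lv, streamlines = streamlines,
                 truth_counts = counts),
            class = "streamline_phantom")
}

# weak pre-ictal background connectivity: a few low-gain edges buried in
# noise, enough to give the baseline h2 pool a realistic spread
background_coupling <- function(channel_labels, gains = c(0.25, 0.2, 0.15)) {
  n_edges <- min(length(gains), length(channel_labels) %/% 2)
  src <- channel_labels[seq_len(n_edges) * 2 - 1]
  dst <- channel_labels[seq_len(n_edges) * 2]
  g <- gains[seq_len(n_edges)]
  coupling_spec(src = src, dst = dst, lag_ms = rep(20, n_edges),
                fun = rep("linear", n_edges), gain = g,
                noise_sd = sqrt(1 - g^2))
}

#' Scenario for planted-edge recovery scoring
#'
#' A two-phase scenario built for measuring how well the whole pipeline
#' (h2 estimation, baseline thresholding, graph construction) recovers a
#' known directed edge set: a baseline with weak background connectivity
#' (see [demo_scenario()]) followed by an event phase planting directed
#' linear coupling on disjoint channel pairs. Pairs are disjoint on
#' purpose — a hub topology induces genuine transitive correlations
#' between co-driven channels that no pairwise thresholding can reject,
#' so it cannot separate detector error from model limitation.
#'
#' @param gain Planted coupling gain (the regime of interest is
#'   `gain >= 0.8`).
#' @param noise_sd Additive noise sd on coupled channels (at or below 0.2
#'   of the signal sd).
#' @param duration_s Duration of each phase in seconds; the default 25 s
#'   at 200 Hz gives 5000 samples per event window.
#' @return A [scenario_spec()] whose `truth` (after
#'   [generate_seizure_scenario()]) holds the planted `onset` edges.
#' @export
recovery_scenario <- function(gain = 0.9, noise_sd = 0.1, duration_s = 25) {
  chans <- c("LJ1", "LJ2", "LK1", "LK2", "LF1", "LF2")
  planted <- coupling_spec(
    src = c("LJ1", "LK1", "LF1"), dst = c("LJ2", "LK2", "LF2"),
    lag_ms = c(15, 25, 20), fun = rep("linear", 3),
    gain = rep(gain, 3), noise_sd = rep(noise_sd, 3))
  scenario_spec(
    phases = list(
      list(phase = "baseline", duration_s = duration_s,
           coupling = background_coupling(chans)),
      list(phase = "onset", duration_s = duration_s, coupling = planted)),
    channel_labels = chans)
}
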