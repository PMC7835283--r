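#' Multichannel SEEG recording
#'
#' Container for a block of intracranial EEG: a channels-by-time matrix of
#' amplitudes in microvolts, the contact labels, the sampling rate and the
#' time offset of the first sample from the recording origin.
#'
#' @param samples Numeric matrix, channels in rows, time in columns.
#' @param channel_labels Character vector of unique contact labels
#'   (electrode name plus contact index, e.g. `"LJ1"`), one per row of
#'   `samples`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param start_time Offset in seconds of the first sample from the
#'   recording origin. Default 0.
#'
#' @return An object of class `seeg_recording` with fields
#'   `samples`, `channel_labels`, `fs`, `start_time`.
#' @examples
#' rec <- seeg_recording(matrix(rnorm(400), 2), c("A1", "A2"), fs = 200)
#' rec
#' @export
seeg_recording <- function(samples, channel_labels, fs, start_time = 0) {
  samples <- as.matrix(samples)
  channel_labels <- as.character(channel_labels)
  if (nrow(samples) != length(channel_labels)) {
    stop_ictalnet("`channel_labels` must name every row of `samples`",
                  "ictalnet_invalid_recording")
  }
  if (anyDuplicated(channel_labels)) {
    stop_ictalnet("channel_labels unique violated",
                  "ictalnet_invalid_recording")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_ictalnet("`fs` must be a positive scalar (Hz)",
                  "ictalnet_invalid_recording")
  }
  if (!all(is.finite(samples))) {
    stop_ictalnet("`samples` must be finite", "ictalnet_invalid_recording")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, channel_labels = channel_labels,
         fs = fs, start_time = start_time),
    class = "seeg_recording"
  )
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf(
    "<seeg_recording> %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
    nrow(x$samples), ncol(x$samples), x$fs,
    ncol(x$samples) / x$fs, x$start_time))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname seeg_recording
#' @param rec A `seeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname seeg_recording
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname seeg_recording
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Event annotations table
#'
#' Builds (and validates) the table of clinically delineated events used to
#' window a recording: one row per event with the seizure it belongs to, the
#' phase label, the start and end time in seconds from the recording origin,
#' and the set of involved contacts.
#'
#' @param seizure_id Integer vector of seizure identifiers.
#' @param phase Character vector of phase labels; see [phase_levels()].
#' @param start_s,end_s Event window in seconds, `start_s < end_s`.
#' @param contacts List of character vectors of involved contact labels
#'   (may be empty).
#'
#' @return A tibble of class `event_annotations` with columns `seizure_id`,
#'   `phase`, `start_s`, `end_s`, `contacts` (list-column).
#' @examples
#' event_annotations(1, "onset", 20, 65, list(c("LJ1", "LK1")))
#' @export
event_annotations <- function(seizure_id, phase, start_s, end_s,
                              contacts = NULL) {
  n <- length(phase)
  if (is.null(contacts)) contacts <- rep(list(character()), n)
  tbl <- tibble(
    seizure_id = as.integer(seizure_id),
    phase = as.character(phase),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    contacts = contacts
  )
  validate_annotations(tbl)
}

validate_annotations <- function(tbl, rec = NULL) {
  bad <- setdiff(unique(tbl$phase), phase_levels())
  if (length(bad)) {
    stop_ictalnet(
      sprintf("unknown phase label(s): %s", paste(bad, collapse = ", ")),
      "ictalnet_invalid_annotation")
  }
  if (any(tbl$start_s >= tbl$end_s)) {
    stop_ictalnet("annotation start_s must be < end_s",
                  "ictalnet_invalid_annotation")
  }
  if (!is.null(rec)) {
    extra <- setdiff(unique(unlist(tbl$contacts)), rec$channel_labels)
    if (length(extra)) {
      stop_ictalnet(
        sprintf("annotation contacts not in recording: %s",
                paste(extra, collapse = ", ")),
        "ictalnet_invalid_annotation")
    }
  }
  class(tbl) <- unique(c("event_annotations", class(tbl)))
  tbl
}

#' Read or write an annotations sidecar file
#'
#' Event annotations travel as a sidecar JSON file next to the signal file:
#' a list of objects with fields `seizure_id`, `phase`, `start_s`, `end_s`
#' and `contacts`. Times are seconds from the recording start.
#'
#' @param path File path of the JSON sidecar.
#' @return `read_annotations()` returns an `event_annotations` tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_ictalnet(sprintf("annotation file not found: %s", path),
                  "ictalnet_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  event_annotations(
    seizure_id = vapply(raw, function(e) as.integer(e$seizure_id), 1L),
    phase = vapply(raw, function(e) as.character(e$phase), ""),
    start_s = vapply(raw, function(e) as.numeric(e$start_s), 1),
    end_s = vapply(raw, function(e) as.numeric(e$end_s), 1),
    contacts = lapply(raw, function(e) as.character(unlist(e$contacts)))
  )
}

#' @rdname read_annotations
#' @param annotations An `event_annotations` tibble.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(seq_len(nrow(annotations)), function(i) {
    list(seizure_id = annotations$seizure_id[i],
         phase = annotations$phase[i],
         start_s = annotations$start_s[i],
         end_s = annotations$end_s[i],
         contacts = as.list(annotations$contacts[[i]]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Segment a recording into fixed-duration windows
#'
#' Splits a recording into consecutive, non-overlapping windows of
#' `segment_duration_s` seconds (a segment store in the style of
#' event-oriented signal archives), optionally grouped into sets of at most
#' `segments_per_set` segments. A trailing window shorter than the segment
#' duration is dropped, so every retained segment has equal length.
#'
#' @param rec A [seeg_recording()].
#' @param segment_duration_s Window length in seconds (> 0).
#' @param segments_per_set Maximum number of segments per set; default
#'   `Inf` puts all segments in one set.
#'
#' @return A tibble with one row per segment: `set`, `segment`, `offset_s`,
#'   `duration_s` and `samples` (list-column of channels-by-time matrices).
#'   A recording shorter than one segment yields a zero-row tibble with a
#'   warning.
#' @examples
#' rec <- seeg_recording(matrix(rnorm(2 * 1300), 2), c("A1", "A2"), fs = 20)
#' segment_recording(rec, 10, segments_per_set = 4)
#' @export
segment_recording <- function(rec, segment_duration_s, segments_per_set = Inf) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (!is.numeric(segment_duration_s) || segment_duration_s <= 0) {
    stop_ictalnet("`segment_duration_s` must be > 0", "ictalnet_invalid_segment")
  }
  seg_len <- round(segment_duration_s * rec$fs)
  n <- ncol(rec$samples)
  n_seg <- n %/% seg_len
  if (n_seg == 0L) {
    warn("recording shorter than one segment; returning no segments")
    return(tibble(set = integer(), segment = integer(),
                  offset_s = numeric(), duration_s = numeric(),
                  samples = list()))
  }
  idx <- seq_len(n_seg)
  tibble(
    set = as.integer((idx - 1L) %/% segments_per_set + 1L),
    segment = as.integer(idx),
    offset_s = (idx - 1L) * segment_duration_s,
    duration_s = segment_duration_s,
    samples = lapply(idx, function(i) {
      rec$samples[, ((i - 1L) * seg_len + 1L):(i * seg_len), drop = FALSE]
    })
  )
}

#' Extract one event window from a recording
#'
#' Slices a recording to the half-open window `[start_s, end_s)` of an
#' annotation (seconds from the recording origin). The channel set is
#' unchanged; sample indices are 0-based internally so an event of `d`
#' seconds yields exactly `round(d * fs)` samples per channel.
#'
#' @param rec A [seeg_recording()].
#' @param event One event: a one-row [event_annotations()] tibble (or any
#'   list with `start_s` and `end_s`).
#' @return A `seeg_recording` restricted in time, with `start_time` set to
#'   the event start.
#' @export
extract_event <- function(rec, event) {
  stopifnot(inherits(rec, "seeg_recording"))
  start_s <- as.numeric(event$start_s)[1]
  end_s <- as.numeric(event$end_s)[1]
  rec_end <- rec$start_time + duration_s(rec)
  if (start_s < rec$start_time - 1e-9 || end_s > rec_end + 1e-9) {
    stop_ictalnet(
      sprintf("event [%g, %g) outside recording extent [%g, %g)",
              start_s, end_s, rec$start_time, rec_end),
      "ictalnet_event_outside_recording")
  }
  i0 <- floor((start_s - rec$start_time) * rec$fs + 1e-9)
  len <- round((end_s - start_s) * rec$fs)
  cols <- (i0 + 1L):(i0 + len)
  seeg_recording(rec$samples[, cols, drop = FALSE], rec$channel_labels,
                 rec$fs, start_time = start_s)
}
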