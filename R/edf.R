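# European Data Format (EDF/EDF+) input/output.
#
# EDF is a fixed-layout format: a 256-byte ASCII global header, 256 ASCII
# bytes per signal, then data records of 16-bit little-endian integers that
# map linearly from the digital range to the physical range declared in the
# header. The layout is simple enough to read and write directly; the writer
# is the exact inverse of the reader up to 16-bit quantization.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop_ictalnet(
    sprintf("EDF header field too wide: '%s' (> %d chars)", s, width),
    "ictalnet_edf_error")
  formatC(s, width = -width)  # left-justified, space padded
}

# encode a numeric so it fits an 8-char EDF field; returns the string whose
# parsed value is what the writer actually uses for scaling
edf_num_field <- function(x) {
  for (d in 7:1) {
    s <- sprintf(paste0("%.", d, "g"), x)
    if (nchar(s) <= 8L) return(s)
  }
  stop_ictalnet(sprintf("cannot encode %g in 8 chars", x), "ictalnet_edf_error")
}

#' Write a recording to an EDF file
#'
#' Encodes each channel as a 16-bit EDF signal. The physical range of each
#' signal is chosen from the observed amplitude range (slightly widened so
#' the extremes are representable), giving a quantization step of
#' `(phys_max - phys_min) / 65535` microvolts. Values round-trip through
#' [read_edf()] to within half of that step.
#'
#' Data records are 1 s long when the recording duration is a whole number
#' of seconds, otherwise a single record spanning the recording is written.
#' The sampling rate must make the samples-per-record count an integer.
#'
#' @param rec A [seeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "seeg_recording"))
  ns <- ncol(rec$samples)
  nchan <- nrow(rec$samples)
  dur <- ns / rec$fs
  if (abs(dur - round(dur)) < 1e-9 && abs(rec$fs - round(rec$fs)) < 1e-9) {
    record_dur <- 1
    n_records <- as.integer(round(dur))
    spr <- as.integer(round(rec$fs))
  } else {
    record_dur <- dur
    n_records <- 1L
    spr <- ns
  }
  if (n_records * spr != ns) {
    stop_ictalnet("recording length not divisible into EDF records",
                  "ictalnet_edf_error")
  }

  # per-channel physical limits, re-parsed from their 8-char encodings so the
  # scaling used for quantization is exactly what a reader will see
  pmin_enc <- character(nchan); pmax_enc <- character(nchan)
  for (i in seq_len(nchan)) {
    r <- range(rec$samples[i, ])
    if (diff(r) == 0) r <- r + c(-1, 1)
    pad <- diff(r) * 1e-3
    pmin_enc[i] <- edf_num_field(r[1] - pad)
    pmax_enc[i] <- edf_num_field(r[2] + pad)
  }
  pmin <- as.numeric(pmin_enc); pmax <- as.numeric(pmax_enc)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256L * (nchan + 1L), 8),
    edf_field("", 44),
    edf_field(n_records, 8),
    edf_field(edf_num_field(record_dur), 8),
    edf_field(nchan, 4)
  )
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  per_sig(rec$channel_labels, 16)
  per_sig(rep("", nchan), 80)                 # transducer
  per_sig(rep("uV", nchan), 8)                # physical dimension
  per_sig(pmin_enc, 8)
  per_sig(pmax_enc, 8)
  per_sig(rep("-32768", nchan), 8)
  per_sig(rep("32767", nchan), 8)
  per_sig(rep("", nchan), 80)                 # prefiltering
  per_sig(rep(spr, nchan), 8)
  per_sig(rep("", nchan), 32)                 # reserved

  scale <- (pmax - pmin) / 65535
  dig <- matrix(0L, nchan, ns)
  for (i in seq_len(nchan)) {
    d <- round((rec$samples[i, ] - pmin[i]) / scale[i]) - 32768
    dig[i, ] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  # interleave: per record, all samples of signal 1, then signal 2, ...
  out <- integer(ns * nchan)
  pos <- 0L
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nchan)) {
      out[(pos + 1L):(pos + spr)] <- dig[i, cols]
      pos <- pos + spr
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Parses the header, converts each signal's digital values to physical
#' units (microvolts) using the declared physical/digital ranges, and
#' returns a [seeg_recording()]. EDF+ `"EDF Annotations"` signals are
#' skipped with a warning (event annotations travel in a sidecar JSON file,
#' see [read_annotations()]). All retained signals must share one sampling
#' rate; mixed rates raise an error since resampling is not performed.
#'
#' @param path Path to an EDF file.
#' @return A [seeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    stop_ictalnet(sprintf("file not found: %s", path), "ictalnet_io_error")
  }
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) {
    stop_ictalnet("malformed header: file shorter than EDF global header",
                  "ictalnet_edf_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  g <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, a, b) trimws(substr(s, a, b))
  n_records <- as.integer(fld(g, 237, 244))
  record_dur <- as.numeric(fld(g, 245, 252))
  nchan <- as.integer(fld(g, 253, 256))
  if (is.na(nchan) || nchan < 1L || is.na(n_records) || is.na(record_dur)) {
    stop_ictalnet("malformed header: unparsable EDF fields",
                  "ictalnet_edf_error")
  }
  sig_hdr <- readChar(con, 256L * nchan, useBytes = TRUE)
  grab <- function(width, offset) {
    vapply(seq_len(nchan), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1L) * width + 1L,
                    offset + i * width))
    }, "")
  }
  off <- 0L
  labels <- grab(16, off); off <- off + 16L * nchan
  off <- off + 80L * nchan                        # transducer
  off <- off + 8L * nchan                         # phys dim
  pmin <- as.numeric(grab(8, off)); off <- off + 8L * nchan
  pmax <- as.numeric(grab(8, off)); off <- off + 8L * nchan
  dmin <- as.numeric(grab(8, off)); off <- off + 8L * nchan
  dmax <- as.numeric(grab(8, off)); off <- off + 8L * nchan
  off <- off + 80L * nchan                        # prefiltering
  spr <- as.integer(grab(8, off))

  keep <- labels != "EDF Annotations"
  if (any(!keep)) warn("skipping EDF+ annotation signal(s)")
  if (!any(keep)) {
    stop_ictalnet("no data signals in EDF file", "ictalnet_edf_error")
  }
  if (anyDuplicated(labels[keep])) {
    stop_ictalnet("channel_labels unique violated", "ictalnet_edf_error")
  }
  if (length(unique(spr[keep])) > 1L) {
    stop_ictalnet("mixed sampling rates across signals; resampling not supported",
                  "ictalnet_edf_error")
  }

  total_per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = n_records * total_per_rec,
                 size = 2L, endian = "little", signed = TRUE)
  if (length(raw) < n_records * total_per_rec) {
    stop_ictalnet("malformed header: data shorter than declared records",
                  "ictalnet_edf_error")
  }
  starts <- c(0L, cumsum(spr))
  chans <- which(keep)
  ns <- n_records * spr[chans[1]]
  samples <- matrix(0, length(chans), ns)
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * total_per_rec
    for (k in seq_along(chans)) {
      i <- chans[k]
      d <- raw[(base + starts[i] + 1L):(base + starts[i] + spr[i])]
      samples[k, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- d
    }
  }
  scale <- (pmax[chans] - pmin[chans]) / (dmax[chans] - dmin[chans])
  samples <- (samples - dmin[chans]) * scale + pmin[chans]
  fs <- spr[chans[1]] / record_dur
  seeg_recording(samples, labels[chans], fs)
}
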