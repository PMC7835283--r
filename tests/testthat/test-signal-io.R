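test_that("recording invariants are enforced", {
  m <- matrix(rnorm(40), 2)
  expect_s3_class(seeg_recording(m, c("A1", "A2"), 200), "seeg_recording")
  expect_error(seeg_recording(m, c("A1", "A1"), 200), "unique")
  expect_error(seeg_recording(m, c("A1", "A2"), -1), "positive")
  m[1, 1] <- NA
  expect_error(seeg_recording(m, c("A1", "A2"), 200), "finite")
})

test_that("segmentation arithmetic follows the drop-tail rule", {
  rec <- toy_recording(n = 60 * 20, fs = 20)

  segs <- segment_recording(rec, 10, segments_per_set = 6)
  expect_equal(nrow(segs), 6)
  expect_equal(unique(segs$set), 1L)

  # 65 s recording: 6 segments, 5 s tail dropped
  rec65 <- toy_recording(n = 65 * 20, fs = 20)
  segs65 <- segment_recording(rec65, 10)
  expect_equal(nrow(segs65), 6)

  # sets of 4: 60 s / 10 s -> sets of 4 + 2
  segs4 <- segment_recording(rec, 10, segments_per_set = 4)
  expect_equal(as.vector(table(segs4$set)), c(4L, 2L))
})

test_that("segment sample counts plus dropped tail conserve the recording", {
  rec <- toy_recording(n = 1337, fs = 20)
  for (dur in c(5, 7.5, 10, 66.85, 100)) {
    segs <- suppressWarnings(segment_recording(rec, dur))
    seg_total <- sum(vapply(segs$samples, ncol, 1L))
    tail_len <- n_samples(rec) - seg_total
    expect_true(tail_len >= 0 && tail_len < round(dur * rec$fs))
  }
})

test_that("segment longer than the recording warns and returns no segments", {
  rec <- toy_recording(n = 100, fs = 20)
  expect_warning(out <- segment_recording(rec, 10), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("extract_event slices half-open windows in samples", {
  rec <- toy_recording(n = 2000, fs = 200)  # 10 s
  full <- extract_event(rec, list(start_s = 0, end_s = 10))
  expect_equal(full$samples, rec$samples)

  one_s <- extract_event(rec, list(start_s = 3, end_s = 4))
  expect_equal(n_samples(one_s), 200)
  expect_equal(one_s$start_time, 3)
  expect_equal(one_s$samples[, 1], rec$samples[, 601])

  expect_error(extract_event(rec, list(start_s = 5, end_s = 11)),
               "outside")
})

test_that("annotations validate and round-trip through sidecar JSON", {
  ann <- event_annotations(c(1, 1), c("baseline", "onset"), c(0, 20),
                           c(20, 65), list(character(), c("LJ1", "LK1")))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$seizure_id, ann$seizure_id)
  expect_equal(back$phase, ann$phase)
  expect_equal(back$start_s, ann$start_s)
  expect_equal(back$contacts, ann$contacts)

  expect_error(event_annotations(1, "preictal", 0, 10), "unknown phase")
  expect_error(event_annotations(1, "onset", 10, 10), "start_s")
  rec <- toy_recording()
  expect_error(validate_annotations(
    event_annotations(1, "onset", 0, 1, list("ZZ9")), rec), "not in recording")
})

test_that("EDF round-trip preserves labels, fs and samples within quantization", {
  for (seed in 1:3) {
    spec <- coupling_spec("A", "B", lag_ms = 50, gain = 0.9, noise_sd = 0.1)
    rec <- generate_coupled_signals(spec, duration_s = 10, fs = 200,
                                    seed = seed)
    path <- withr::local_tempfile(fileext = ".edf")
    write_edf(rec, path)
    back <- read_edf(path)
    expect_equal(back$channel_labels, rec$channel_labels)
    expect_equal(back$fs, rec$fs)
    qstep <- vapply(seq_len(2), function(i) {
      diff(range(rec$samples[i, ])) * 1.002 / 65535
    }, 1)
    for (i in 1:2) {
      expect_lt(max(abs(back$samples[i, ] - rec$samples[i, ])), qstep[i])
    }
  }
})

test_that("EDF edge cases: constant channel, many channels, bad files", {
  rec <- seeg_recording(rbind(rep(5, 400), rnorm(400)), c("C1", "C2"), 200)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_lt(max(abs(back$samples[1, ] - 5)), 1e-3)

  many <- seeg_recording(matrix(rnorm(20 * 400), 20),
                         sprintf("CH%02d", 1:20), 200)
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(many, p2)
  expect_equal(read_edf(p2)$channel_labels, many$channel_labels)

  empty <- withr::local_tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_edf(empty), "malformed header")
  expect_error(read_edf(withr::local_tempfile()), "not found")
})

test_that("EDF reader rejects duplicate labels and mixed sampling rates", {
  rec <- toy_recording(n_chan = 2, n = 400, fs = 200)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # forge the second signal label to equal the first (offset 256, 16 chars each)
  raw[256 + 16 + seq_len(16)] <- raw[256 + seq_len(16)]
  writeBin(raw, path)
  expect_error(read_edf(path), "unique")

  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # forge samples-per-record of signal 2 (offset 256 + 216*2 + 8)
  spr_off <- 256 + (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) * 2 + 8
  raw[spr_off + seq_len(8)] <- charToRaw(formatC("100", width = -8))
  writeBin(raw, path)
  expect_error(read_edf(path), "mixed sampling rates")
})

test_that("EDF files written here are readable by an independent EDF stack", {
  rec <- generate_coupled_signals(
    coupling_spec("A", "B", gain = 0.8, noise_sd = 0.2),
    duration_s = 5, fs = 200, seed = 7)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  out_csv <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(r'%s', preload=True, verbose='ERROR')\n",
    "d = raw.get_data() * 1e6\n",
    "hdr = ','.join(raw.ch_names) + ',' + str(raw.info['sfreq'])\n",
    "np.savetxt(r'%s', d, delimiter=',', header=hdr, comments='')\n"),
    path, out_csv)
  status <- system2("python", c("-c", shQuote(script)),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_csv) && file.info(out_csv)$size > 0,
              info = paste(status, collapse = "\n"))
  lines <- readLines(out_csv)
  hdr <- strsplit(lines[1], ",")[[1]]
  expect_equal(hdr[1:2], c("A", "B"))
  expect_equal(as.numeric(hdr[3]), 200)
  vals <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, ",")[[1]])
  }))
  qstep <- diff(range(rec$samples)) * 1.002 / 65535
  expect_lt(max(abs(vals - rec$samples)), 2 * qstep)
})
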