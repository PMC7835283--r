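# Structural connectivity: counting streamlines whose endpoints fall in
# distinct labeled electrode ROIs. Registration, segmentation and the
# tractography itself are upstream (published tools); this module consumes
# their outputs — a labeled NIfTI volume and a streamline file.

#' Labeled region-of-interest volume
#'
#' A 3D integer grid (0 = background, 1..E = electrode/gyrus labels)
#' together with the affine mapping 0-based voxel indices to world
#' millimetres.
#'
#' @param data 3D integer array of labels.
#' @param affine 4x4 voxel-to-world affine (invertible).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) {
    stop_ictalnet("affine must be invertible", "ictalnet_tract_error")
  }
  if (any(data < 0) || any(data != round(data))) {
    stop_ictalnet("labels must be nonnegative integers",
                  "ictalnet_tract_error")
  }
  structure(list(data = data, affine = affine,
                 inverse = solve(affine),
                 labels = sort(unique(as.integer(data[data > 0])))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d labels\n",
              paste(dim(x$data), collapse = " x "), length(x$labels)))
  invisible(x)
}

#' Read a labeled volume from a NIfTI file
#'
#' @param path Path to a NIfTI file of integer labels.
#' @return A [label_volume()] using the image's sform/qform affine.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(round(as.array(img)), RNifti::xform(img))
}

#' @rdname read_label_volume
#' @param vol A [label_volume()].
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world mm -> 1-based voxel index (nearest voxel), or NULL when outside
world_to_voxel <- function(p, vol) {
  v <- round((vol$inverse %*% c(p, 1))[1:3]) + 1L
  if (any(v < 1L) || any(v > dim(vol$data))) return(NULL)
  v
}

#' Labels at the two endpoints of a streamline
#'
#' Maps each endpoint of a polyline (world mm) to its nearest voxel via
#' the inverse affine and returns the label there; endpoints outside the
#' grid or in background get label 0.
#'
#' @param streamline n-by-3 numeric matrix of world-mm points (n >= 2).
#' @param vol A [label_volume()].
#' @return Integer vector of length 2.
#' @export
endpoint_labels <- function(streamline, vol) {
  streamline <- as.matrix(streamline)
  stopifnot(ncol(streamline) == 3L, nrow(streamline) >= 2L)
  ends <- streamline[c(1L, nrow(streamline)), , drop = FALSE]
  vapply(1:2, function(i) {
    v <- world_to_voxel(ends[i, ], vol)
    if (is.null(v)) 0L else as.integer(vol$data[v[1], v[2], v[3]])
  }, 1L)
}

# labels intersected anywhere along the path (vertices, no densification)
path_labels <- function(streamline, vol) {
  streamline <- as.matrix(streamline)
  labs <- apply(streamline, 1L, function(p) {
    v <- world_to_voxel(p, vol)
    if (is.null(v)) 0L else as.integer(vol$data[v[1], v[2], v[3]])
  })
  unique(labs[labs > 0L])
}

#' Pairwise streamline counts between labeled ROIs
#'
#' Applies the label volume to a streamline set: in the default
#' `"endpoint"` mode a streamline whose two endpoints carry distinct
#' nonzero labels `(a, b)` increments `counts[a, b]` and `counts[b, a]`
#' once (tracts carry no direction, so all connections are bidirectional);
#' streamlines touching background or connecting a label to itself are
#' ignored, and the diagonal is identically zero. Mode `"path"` instead
#' links every pair of distinct labels whose voxels the polyline's
#' vertices visit — a sensitivity check for the endpoint semantics.
#'
#' @param streamlines List of n-by-3 world-mm matrices (e.g. from
#'   [read_tck()] or a [generate_streamline_phantom()]).
#' @param vol A [label_volume()].
#' @param mode `"endpoint"` (default) or `"path"`.
#' @return A symmetric integer matrix of class `tract_count_matrix` with
#'   one row/column per label `1..E`.
#' @export
tract_count_matrix <- function(streamlines, vol,
                               mode = c("endpoint", "path")) {
  mode <- match.arg(mode)
  E <- max(vol$labels, 0L)
  counts <- matrix(0L, E, E, dimnames = list(seq_len(E), seq_len(E)))
  for (s in streamlines) {
    if (mode == "endpoint") {
      lab <- endpoint_labels(s, vol)
      if (lab[1] > 0L && lab[2] > 0L && lab[1] != lab[2]) {
        counts[lab[1], lab[2]] <- counts[lab[1], lab[2]] + 1L
        counts[lab[2], lab[1]] <- counts[lab[2], lab[1]] + 1L
      }
    } else {
      labs <- path_labels(s, vol)
      if (length(labs) >= 2L) {
        prs <- utils::combn(sort(labs), 2L)
        for (k in seq_len(ncol(prs))) {
          a <- prs[1, k]; b <- prs[2, k]
          counts[a, b] <- counts[a, b] + 1L
          counts[b, a] <- counts[b, a] + 1L
        }
      }
    }
  }
  structure(counts, mode = mode, class = c("tract_count_matrix", "matrix"))
}

#' @export
print.tract_count_matrix <- function(x, ...) {
  cat(sprintf("<tract_count_matrix> %d labels (%s mode)\n",
              nrow(x), attr(x, "mode") %||% "endpoint"))
  print(unclass(x))
  invisible(x)
}

#' Entrywise difference of patient counts against a control mean
#'
#' @param patient Square tract-count matrix (or `tract_count_matrix`).
#' @param control_mean Square matrix of mean control counts with the same
#'   dimnames.
#' @return A signed numeric matrix `patient - control_mean`.
#' @examples
#' p <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' difference_vs_controls(p, 0.5 * p)
#' @export
difference_vs_controls <- function(patient, control_mean) {
  patient <- as.matrix(unclass(patient))
  control_mean <- as.matrix(unclass(control_mean))
  if (!identical(dim(patient), dim(control_mean)) ||
      !identical(dimnames(patient), dimnames(control_mean))) {
    stop_ictalnet("patient and control matrices must share labels",
                  "ictalnet_tract_error")
  }
  patient - control_mean
}

#' Tidy long table of a pairwise count or difference matrix
#'
#' @param x A symmetric matrix with dimnames (counts or differences).
#' @param value_name Name for the value column.
#' @return A tibble `roi_a, roi_b, <value_name>` over unordered pairs.
#' @export
tract_pairs <- function(x, value_name = "n_tracts") {
  x <- as.matrix(unclass(x))
  ut <- which(upper.tri(x), arr.ind = TRUE)
  out <- tibble(roi_a = rownames(x)[ut[, 1]], roi_b = colnames(x)[ut[, 2]])
  out[[value_name]] <- x[ut]
  out
}

# --- TCK streamline file I/O -------------------------------------------

#' Read or write MRtrix TCK streamline files
#'
#' TCK stores a text header (key-value lines between `mrtrix tracks` and
#' `END`) followed by little-endian float32 point triplets in world
#' millimetres, with `(NaN, NaN, NaN)` separating streamlines and
#' `(Inf, Inf, Inf)` terminating the stream.
#'
#' @param path File path.
#' @return `read_tck()` returns a list of n-by-3 matrices (world mm).
#' @export
read_tck <- function(path) {
  if (!file.exists(path)) {
    stop_ictalnet(sprintf("file not found: %s", path), "ictalnet_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", magic)) {
    stop_ictalnet("not a TCK file (missing 'mrtrix tracks' magic)",
                  "ictalnet_io_error")
  }
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop_ictalnet("TCK header missing END", "ictalnet_io_error")
    }
    if (trimws(line) == "END") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(sub("^\\. ", "", val))
    if (key == "datatype") datatype <- val
  }
  if (is.na(offset)) {
    stop_ictalnet("TCK header missing 'file' offset", "ictalnet_io_error")
  }
  if (datatype != "Float32LE") {
    stop_ictalnet(sprintf("unsupported TCK datatype '%s'", datatype),
                  "ictalnet_io_error")
  }
  seek(con, offset)
  raw <- readBin(con, "numeric", size = 4L,
                 n = (file.info(path)$size - offset) / 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  out <- list()
  cur_start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (is.nan(pts[i, 1]) || is.infinite(pts[i, 1])) {
      if (i > cur_start) {
        out[[length(out) + 1L]] <- pts[cur_start:(i - 1L), , drop = FALSE]
      }
      if (is.infinite(pts[i, 1])) break
      cur_start <- i + 1L
    }
  }
  out
}

#' @rdname read_tck
#' @param streamlines List of n-by-3 numeric matrices in world mm.
#' @export
write_tck <- function(streamlines, path) {
  header1 <- "mrtrix tracks\ndatatype: Float32LE\n"
  count_line <- sprintf("count: %d\n", length(streamlines))
  # the 'file: . N' line's own width feeds into N; fix the field width
  stub <- function(off) sprintf("file: . %d\nEND\n", off)
  base <- nchar(header1) + nchar(count_line)
  off <- base
  repeat {
    new_off <- base + nchar(stub(off))
    if (new_off == off) break
    off <- new_off
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header1, count_line, stub(off)), con, eos = NULL)
  for (s in streamlines) {
    s <- as.matrix(s)
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3L)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3L)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Example insula gyri tract-count comparison
#'
#' A worked example dataset for [difference_vs_controls()]: streamline
#' counts between the five insular gyri of each hemisphere (short
#' anterior/middle/posterior, long anterior/posterior; `L`/`R` prefix for
#' hemisphere) for one refractory insular-epilepsy patient alongside the
#' mean of three healthy controls.
#'
#' @return A tibble `gyrus_a, gyrus_b, patient, control_mean`.
#' @export
insula_tract_example <- function() {
  as_tibble(utils::read.csv(system.file("extdata",
                                        "insula_tract_counts.csv",
                                        package = "ictalnet"),
                            stringsAsFactors = FALSE))
}

#' Build a symmetric count matrix from a long pair table
#'
#' @param tbl Tibble with columns `gyrus_a`/`roi_a`, `gyrus_b`/`roi_b` and
#'   one numeric value column.
#' @param value Name of the value column.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pair_table_to_matrix <- function(tbl, value) {
  a_col <- intersect(c("gyrus_a", "roi_a", "pair_a"), names(tbl))[1]
  b_col <- intersect(c("gyrus_b", "roi_b", "pair_b"), names(tbl))[1]
  labs <- sort(unique(c(tbl[[a_col]], tbl[[b_col]])))
  M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  M[cbind(tbl[[a_col]], tbl[[b_col]])] <- tbl[[value]]
  M[cbind(tbl[[b_col]], tbl[[a_col]])] <- tbl[[value]]
  M
}
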