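# Data model and file I/O: decay cubes, masks/ROIs, result tables.
#
# A decay cube stores the TCSPC photon histogram F(x, y, t) as an integer
# array [row, col, time_bin] together with acquisition metadata.  On disk a
# cube is a multi-page unsigned 16-bit TIFF (one page per time bin) plus a
# JSON metadata sidecar sharing the file stem.

#' Acquisition metadata for a TCSPC decay cube
#'
#' Describes the timing geometry of a TCSPC acquisition.  The measurement
#' window (`period`) covers exactly one excitation period of the pulsed
#' laser when the "one complete period" phasor convention is used, i.e.
#' `period == 1 / rep_frequency`.
#'
#' @param n_bins Number of time bins (>= 8).
#' @param period Full measurement window in seconds (default 10 ns, one
#'   period of a 100 MHz laser).
#' @param bin_width Seconds per time bin; defaults to `period / n_bins`.
#' @param rep_frequency Laser repetition rate in Hz (default 1e8).
#' @param n_frames Number of repeat scans accumulated into the cube.
#' @param pixel_size Lateral pixel size in meters.
#' @param field_id,treatment Free-text labels carried into result tables.
#'
#' @return An object of class `acquisition_meta`.
#' @export
#' @examples
#' acquisition_meta(n_bins = 256)
acquisition_meta <- function(n_bins = 256L, period = 10e-9, bin_width = NULL,
                             rep_frequency = 1e8, n_frames = 1L,
                             pixel_size = 1.08e-6, field_id = "",
                             treatment = "") {
  n_bins <- as.integer(n_bins)
  bin_width <- bin_width %||% (period / n_bins)
  assert_that(n_bins >= 8L, "n_bins must be >= 8, got %d", n_bins)
  assert_that(bin_width > 0, "bin_width must be positive")
  assert_that(rel_diff(n_bins * bin_width, period) < 1e-9,
              "n_bins * bin_width must equal period (got %.4g != %.4g)",
              n_bins * bin_width, period)
  meta <- structure(
    list(n_bins = n_bins, bin_width = bin_width, period = period,
         rep_frequency = rep_frequency, n_frames = as.integer(n_frames),
         pixel_size = pixel_size, field_id = field_id, treatment = treatment),
    class = "acquisition_meta")
  meta
}

#' Time-bin centers of an acquisition, in nanoseconds
#'
#' Bin `k` spans `[(k-1) * dt, k * dt)`; centers are used wherever a time
#' value enters a computation.
#' @param meta An [acquisition_meta()].
#' @return Numeric vector of length `n_bins` (ns).
#' @export
bin_centers_ns <- function(meta) {
  dt <- meta$bin_width * 1e9
  (seq_len(meta$n_bins) - 0.5) * dt
}

#' Construct a decay cube
#'
#' @param counts Non-negative integer array `[row, col, time_bin]`.
#' @param meta An [acquisition_meta()]; `meta$n_bins` must match `dim(counts)[3]`.
#' @param frame_intensity Optional numeric vector of per-frame mean
#'   intensities (length `meta$n_frames`) used for bleaching correction.
#' @return An object of class `decay_cube` with elements `counts`, `meta`,
#'   `frame_intensity`.
#' @export
decay_cube <- function(counts, meta, frame_intensity = NULL) {
  assert_that(length(dim(counts)) == 3L, "counts must be a 3-d array")
  assert_that(dim(counts)[3] == meta$n_bins,
              "counts has %d time pages but meta$n_bins = %d",
              dim(counts)[3], meta$n_bins, class = "shape_error")
  assert_that(all(counts >= 0), "counts must be non-negative",
              class = "format_error")
  assert_that(all(counts == round(counts)), "counts must be integral",
              class = "format_error")
  if (!is.null(frame_intensity)) {
    assert_that(length(frame_intensity) == meta$n_frames,
                "frame_intensity length %d != n_frames %d",
                length(frame_intensity), meta$n_frames)
  }
  structure(list(counts = counts, meta = meta,
                 frame_intensity = frame_intensity),
            class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_cube> %d x %d pixels, %d time bins, %.3g photons\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Total-intensity image of a cube (photons per pixel)
#' @param cube A [decay_cube()].
#' @return Numeric matrix `[row, col]` of photon totals.
#' @export
intensity_image <- function(cube) {
  rowSums(cube$counts, dims = 2L)
}

#' Compartment label masks
#'
#' Integer image with 0 = background, 1 = cytoplasm, 2 = nucleus.  A pixel
#' carries exactly one label, so the nuclear and cytoplasmic compartments
#' are disjoint by construction.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param provenance One of `"manual"`, `"synthetic-truth"`, `"threshold"`.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(labels, provenance = c("manual", "synthetic-truth",
                                            "threshold")) {
  provenance <- match.arg(provenance)
  assert_that(all(labels %in% 0:2), "mask labels must be in {0, 1, 2}")
  structure(list(labels = labels, provenance = provenance),
            class = "mask_set")
}

#' A nuclear region-of-interest polygon
#'
#' Vertices are 0-based `(row, col)` pixel-center coordinates.  Polygons
#' must be simple (non-self-intersecting).
#'
#' @param vertices Numeric matrix or list of `(row, col)` pairs, >= 3 rows.
#' @param label Compartment label the polygon encodes (2 = nucleus).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = 2L) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  assert_that(nrow(vertices) >= 3L, "a polygon needs at least 3 vertices")
  assert_that(!polygon_self_intersects(vertices[, 1], vertices[, 2]),
              "polygon is self-intersecting", class = "roi_error")
  structure(list(vertices = vertices, label = as.integer(label)),
            class = "roi_polygon")
}

#' Rasterize nuclear ROI polygons into a compartment mask
#'
#' Pixels whose centers fall inside any nuclear polygon (boundary included)
#' and are not background become nucleus (2); remaining non-background
#' pixels become cytoplasm (1); background stays 0.  The background
#' threshold takes precedence over ROI membership, mirroring the analysis
#' order of thresholding first and drawing nuclear ROIs second.
#'
#' @param rois List of [roi_polygon()] objects (possibly empty).
#' @param shape Integer vector `c(rows, cols)`.
#' @param background_mask Logical matrix, `TRUE` where background.
#' @return A [mask_set()] with provenance `"manual"`.
#' @export
rasterize_rois <- function(rois, shape, background_mask = NULL) {
  rows <- shape[1]; cols <- shape[2]
  if (is.null(background_mask)) {
    background_mask <- matrix(FALSE, rows, cols)
  }
  assert_that(all(dim(background_mask) == shape),
              "background_mask shape mismatch", class = "shape_error")
  labels <- matrix(1L, rows, cols)
  if (length(rois)) {
    # pixel-center coordinates, 0-based
    pr <- as.vector(row(labels)) - 1
    pc <- as.vector(col(labels)) - 1
    in_any <- logical(length(pr))
    for (roi in rois) {
      if (!inherits(roi, "roi_polygon")) roi <- roi_polygon(roi$vertices, roi$label)
      in_any <- in_any |
        points_in_polygon(pr, pc, roi$vertices[, 1], roi$vertices[, 2])
    }
    labels[matrix(in_any, rows, cols)] <- 2L
  }
  labels[background_mask] <- 0L
  mask_set(labels, "manual")
}

# ---- cube file I/O -----------------------------------------------------

sidecar_path <- function(path) {
  sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
}

#' Write a decay cube as multi-page TIFF + JSON sidecar
#'
#' Page `k` of the TIFF holds time bin `k` as unsigned 16-bit integers
#' (lossless for counts up to 65535).  All acquisition metadata and any
#' per-frame intensity series go to a JSON sidecar with the same stem.
#'
#' @param cube A [decay_cube()].
#' @param path Output TIFF path (`.tif`); the sidecar replaces the
#'   extension with `.json`.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_decay_cube <- function(cube, path) {
  assert_that(max(cube$counts) <= 65535,
              "counts exceed the uint16 range of the cube container",
              class = "format_error")
  pages <- lapply(seq_len(cube$meta$n_bins),
                  function(k) cube$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  m <- cube$meta
  sidecar <- list(
    n_bins = m$n_bins, bin_width_ps = m$bin_width * 1e12,
    period_ns = m$period * 1e9, rep_frequency_MHz = m$rep_frequency / 1e6,
    n_frames = m$n_frames, pixel_size_um = m$pixel_size * 1e6,
    field_id = m$field_id, treatment = m$treatment)
  if (!is.null(cube$frame_intensity)) {
    sidecar$frame_intensity <- cube$frame_intensity
  }
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, sidecar_path(path)))
}

#' Read a decay cube written by [write_decay_cube()]
#'
#' @param path Path to the multi-page TIFF; the JSON sidecar with matching
#'   stem must be present.
#' @return A validated [decay_cube()]; the round trip
#'   `read_decay_cube(write_decay_cube(cube))` is the identity on counts
#'   and metadata.
#' @export
read_decay_cube <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path,
              class = "io_error")
  sp <- sidecar_path(path)
  assert_that(file.exists(sp), "missing metadata sidecar: %s", sp,
              class = "metadata_error")
  sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
  meta <- acquisition_meta(
    n_bins = sc$n_bins, bin_width = sc$bin_width_ps * 1e-12,
    period = sc$period_ns * 1e-9, rep_frequency = sc$rep_frequency_MHz * 1e6,
    n_frames = sc$n_frames, pixel_size = sc$pixel_size_um * 1e-6,
    field_id = sc$field_id %||% "", treatment = sc$treatment %||% "")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  assert_that(length(pages) == meta$n_bins,
              "TIFF has %d pages but sidecar says n_bins = %d",
              length(pages), meta$n_bins, class = "shape_error")
  counts <- array(0L, dim = c(dim(pages[[1]]), meta$n_bins))
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  decay_cube(counts, meta, frame_intensity = sc$frame_intensity)
}

#' Write a mask set as a single-page 8-bit TIFF
#' @param masks A [mask_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_set <- function(masks, path) {
  tiff::writeTIFF(masks$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a mask set written by [write_mask_set()]
#' @param path TIFF path.
#' @param provenance Provenance label to attach.
#' @return A [mask_set()].
#' @export
read_mask_set <- function(path, provenance = "manual") {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  mask_set(matrix(as.integer(labels), nrow(labels), ncol(labels)),
           provenance)
}

#' Read ROI polygons from a JSON file
#'
#' Expected schema: `[{"label": 2, "vertices": [[row, col], ...]}, ...]`
#' with 0-based pixel-center coordinates.
#' @param path JSON path.
#' @return List of [roi_polygon()] objects.
#' @export
read_rois <- function(path) {
  assert_that(file.exists(path), "no such ROI file: %s", path,
              class = "io_error")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    roi_polygon(do.call(rbind, lapply(r$vertices, unlist)),
                label = r$label %||% 2L)
  })
}

#' Write ROI polygons to JSON
#' @param rois List of [roi_polygon()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r) list(label = r$label,
                                  vertices = unname(r$vertices))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- result tables -----------------------------------------------------

result_columns <- c("field_id", "compartment", "treatment", "mean_lifetime",
                    "bound_fraction", "raw_intensity", "corrected_intensity",
                    "normalized_intensity", "concentration_proxy", "n_pixels")

#' Write a field-result table to CSV
#'
#' One row per (field, compartment) with a fixed, documented column order.
#' Rows containing non-finite values in numeric columns are refused.
#'
#' @param table Data frame with (a subset of) the standard result columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  for (col in setdiff(result_columns, names(table))) table[[col]] <- NA
  table <- table[result_columns]
  num <- vapply(table, is.numeric, logical(1))
  if (nrow(table)) {
    bad <- vapply(which(num), function(j) any(is.infinite(table[[j]]) |
                                                is.nan(table[[j]])), logical(1))
    assert_that(!any(bad), "refusing to write non-finite result values",
                class = "format_error")
  }
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a field-result table written by [write_results()]
#' @param path CSV path.
#' @return Data frame in the standard column order.
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
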