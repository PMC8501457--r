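# Compartment analysis: background thresholding, photobleaching
# correction, intensity normalization to vehicle control, the
# intensity/lifetime concentration proxy, and per-compartment aggregation.

#' Background mask from a total-intensity image
#'
#' Pixels with total photon count below the threshold are background and
#' excluded from all downstream analysis.  With `threshold = NULL` an
#' automatic Otsu threshold (maximal between-class variance) is used.
#'
#' @param intensity Numeric matrix of photons per pixel
#'   (see [intensity_image()]).
#' @param threshold Count threshold, or `NULL` for automatic.
#' @return Logical matrix, `TRUE` where background.
#' @export
background_mask <- function(intensity, threshold = NULL) {
  threshold <- threshold %||% otsu_threshold(intensity)
  assert_that(threshold >= 0, "threshold must be >= 0")
  intensity < threshold
}

#' Photobleaching correction factor
#'
#' `b = mean(frame_means) / frame_means[1]` — the ratio of the average
#' frame intensity over the acquisition to the first-frame intensity.
#' Measured intensities are divided by `b`, so a decaying series
#' (`b < 1`) is corrected upward.  In practice this correction is small
#' (typically under 10%).
#'
#' @param frame_means Numeric vector of per-frame mean intensities
#'   (>= 1 frame; first frame positive).
#' @return An object of class `bleaching_series` with `frame_means` and
#'   `factor`.
#' @export
#' @examples
#' bleaching_factor(c(100, 90, 80))$factor  # 0.9
bleaching_factor <- function(frame_means) {
  assert_that(length(frame_means) >= 1, "need at least one frame")
  assert_that(frame_means[1] > 0, "first-frame intensity must be positive")
  structure(list(frame_means = frame_means,
                 factor = mean(frame_means) / frame_means[1]),
            class = "bleaching_series")
}

#' Bleaching-corrected intensity
#'
#' @param raw Measured mean intensity.
#' @param bleach A [bleaching_factor()] result (or a bare numeric factor).
#' @return `raw / b`.
#' @export
corrected_intensity <- function(raw, bleach) {
  b <- if (inherits(bleach, "bleaching_series")) bleach$factor else bleach
  assert_that(b > 0, "bleaching factor must be positive")
  raw / b
}

#' Normalize intensity to same-replicate vehicle control
#'
#' Treated-field intensities are expressed relative to the mean corrected
#' intensity of vehicle-control fields acquired in the same replicate
#' (day).  A missing control for a replicate is an error, never a silent
#' fallback.
#'
#' @param treated Corrected intensity (scalar or vector).
#' @param control Corrected control intensity for the same replicate
#'   (scalar mean, or vector averaged here).
#' @return `treated / mean(control)`.
#' @export
normalize_to_control <- function(treated, control) {
  assert_that(length(control) >= 1 && all(is.finite(control)),
              "missing vehicle control for this replicate",
              class = "pairing_error")
  m <- mean(control)
  assert_that(m > 0, "control intensity must be positive",
              class = "pairing_error")
  treated / m
}

#' NAD(P)H concentration proxy
#'
#' Fluorescence intensity is proportional to concentration times quantum
#' yield, and quantum yield is proportional to lifetime; the ratio
#' `intensity / mean lifetime` therefore tracks relative concentration
#' independent of enzyme-binding shifts.
#'
#' @param corrected Bleaching-corrected intensity.
#' @param mean_tau_m Mean fluorescence lifetime (ns, > 0).
#' @return Concentration proxy in arbitrary units.
#' @export
concentration_proxy <- function(corrected, mean_tau_m) {
  assert_that(all(mean_tau_m > 0), "mean lifetime must be positive")
  corrected / mean_tau_m
}

#' Per-compartment summary of a field
#'
#' Aggregates pixel-level results into one row per compartment (nucleus,
#' cytoplasm) plus a pixel-count-weighted whole-cell row: mean bound
#' fraction, mean lifetime (where fits are available), raw and
#' bleaching-corrected mean intensity, optional control-normalized
#' intensity, and the concentration proxy.  SEMs are across pixels within
#' the field; cross-field SEMs belong to [experiment_sem()].
#'
#' @param cube The (unbinned) [decay_cube()] of the field.
#' @param masks A [mask_set()].
#' @param bound_map A [bound_fraction()] map (may be `NULL`).
#' @param tau_map Matrix of per-pixel mean lifetimes from
#'   [fit_pixel_map()] (may be `NULL`).
#' @param bleach A [bleaching_factor()] result, or `NULL` (no correction).
#' @param control Mean corrected control intensity for normalization, or
#'   `NULL` to leave `normalized_intensity` `NA`.
#' @return Data frame with one row per non-empty compartment; empty
#'   compartments are dropped with a warning.
#' @export
summarize_regions <- function(cube, masks, bound_map = NULL, tau_map = NULL,
                              bleach = NULL, control = NULL) {
  labels <- masks$labels
  assert_that(all(dim(labels) == dim(cube$counts)[1:2]),
              "masks and cube are not aligned", class = "shape_error")
  intensity <- intensity_image(cube)
  b <- if (is.null(bleach)) 1 else bleach$factor
  comp_rows <- list(nucleus = labels == 2L, cytoplasm = labels == 1L,
                    `whole-cell` = labels > 0L)
  rows <- list()
  for (name in names(comp_rows)) {
    sel <- comp_rows[[name]]
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("compartment '%s' is empty; omitted", name))
      next
    }
    f_vals <- if (!is.null(bound_map)) bound_map$fraction[sel] else NA_real_
    t_vals <- if (!is.null(tau_map)) tau_map[sel] else NA_real_
    t_vals <- t_vals[is.finite(t_vals)]
    mean_tau <- if (length(t_vals)) mean(t_vals) else NA_real_
    raw <- mean(intensity[sel])
    corr <- raw / b
    rows[[name]] <- data.frame(
      field_id = cube$meta$field_id, compartment = name,
      treatment = cube$meta$treatment,
      mean_lifetime = mean_tau,
      sem_lifetime = if (length(t_vals)) sem(t_vals) else NA_real_,
      bound_fraction = mean(f_vals, na.rm = TRUE),
      sem_bound_fraction = sem(f_vals),
      raw_intensity = raw,
      corrected_intensity = corr,
      normalized_intensity = if (is.null(control)) NA_real_ else
        normalize_to_control(corr, control),
      concentration_proxy = if (is.finite(mean_tau)) corr / mean_tau else
        NA_real_,
      n_pixels = n, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
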