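# Model-independent phasor analysis.
#
# The phasor of a decay F(t) at angular frequency omega is
#   g = int F(t) cos(omega t) dt / int F(t) dt
#   s = int F(t) sin(omega t) dt / int F(t) dt
# with the numerical integral taken over exactly one excitation period
# (rectangle rule at bin centers).  Noise-free single exponentials land on
# the universal semicircle (g - 1/2)^2 + s^2 = 1/4; mixtures lie inside it
# on the convex hull of their component phasors.  Convolution with the IRF
# is multiplication in phasor space (z = g + i s), so IRF correction is a
# complex division by the IRF phasor.

#' Phasor transform configuration
#'
#' @param frequency Transform frequency in Hz (default 100 MHz, the laser
#'   fundamental); `omega = 2 pi frequency`.
#' @param meta An [acquisition_meta()]; the acquisition period must equal
#'   one transform period `T = 2 pi / omega`.
#' @return An object of class `transform_config` with `omega` (rad/s),
#'   `period` (s), `n_bins`, `bin_width` (s).
#' @export
transform_config <- function(frequency = 1e8,
                             meta = acquisition_meta(n_bins = 256L)) {
  omega <- 2 * pi * frequency
  period <- 1 / frequency
  assert_that(rel_diff(period * omega, 2 * pi) < 1e-9,
              "period * omega must equal 2 pi")
  assert_that(rel_diff(meta$period, period) < 1e-6,
              "acquisition window (%.4g s) must span one transform period (%.4g s)",
              meta$period, period)
  structure(list(omega = omega, period = period, n_bins = meta$n_bins,
                 bin_width = meta$bin_width),
            class = "transform_config")
}

cfg_trig <- function(cfg) {
  tc <- (seq_len(cfg$n_bins) - 0.5) * cfg$bin_width  # seconds
  list(cosw = cos(cfg$omega * tc), sinw = sin(cfg$omega * tc))
}

#' Phasor transform of a decay histogram or cube
#'
#' Discrete sine/cosine transform at the bin centers over one period.
#'
#' @param x Either a counts vector (length `n_bins`) or a [decay_cube()].
#' @param cfg A [transform_config()].
#' @return For a vector, a named numeric `c(g, s)`.  For a cube, an object
#'   of class `phasor_field` with matrices `g`, `s`, `total` and the flag
#'   `corrected = FALSE`.
#' @export
phasor_transform <- function(x, cfg) {
  trig <- cfg_trig(cfg)
  if (inherits(x, "decay_cube")) {
    d <- dim(x$counts)
    flat <- matrix(x$counts, d[1] * d[2], d[3])
    tot <- rowSums(flat)
    g <- matrix((flat %*% trig$cosw) / tot, d[1], d[2])
    s <- matrix((flat %*% trig$sinw) / tot, d[1], d[2])
    return(structure(list(g = g, s = s,
                          total = matrix(tot, d[1], d[2]),
                          corrected = FALSE, cfg = cfg),
                     class = "phasor_field"))
  }
  tot <- sum(x)
  assert_that(tot > 0, "cannot transform an empty decay",
              class = "undefined_phasor_error")
  c(g = sum(x * trig$cosw) / tot, s = sum(x * trig$sinw) / tot)
}

#' Analytic phasor of a multi-exponential decay
#'
#' For components with amplitudes `A_i` and lifetimes `tau_i`,
#' `g = (1/N) sum A_i tau_i / (1 + (omega tau_i)^2)` and
#' `s = (1/N) sum A_i tau_i (omega tau_i) / (1 + (omega tau_i)^2)` with
#' `N = sum A_i tau_i`.  A single exponential gives the universal
#' semicircle point `(1, omega tau) / (1 + (omega tau)^2)`.
#'
#' @param components A [synth_components()] data frame (lifetimes in ns).
#' @param cfg A [transform_config()] (only `omega` is used).
#' @return Named numeric `c(g, s)`.
#' @export
#' @examples
#' cfg <- transform_config()
#' analytic_phasor(synth_components(0.4), cfg)   # free NADH endpoint
#' analytic_phasor(synth_components(3.4), cfg)   # bound NADH endpoint
analytic_phasor <- function(components, cfg) {
  wt <- cfg$omega * components$lifetime * 1e-9
  aitaui <- components$amplitude * components$lifetime
  N <- sum(aitaui)
  assert_that(N > 0, "sum of A_i tau_i must be positive")
  c(g = sum(aitaui / (1 + wt^2)) / N,
    s = sum(aitaui * wt / (1 + wt^2)) / N)
}

#' Estimate the IRF phasor from the brightest pixel
#'
#' The brightest pixel (after spatial binning; ties broken by smallest
#' row, then column) is assumed to carry a clean decay.  Its tail — from
#' the histogram maximum onward — is fit to one or two exponentials
#' (chosen by F-test), and the IRF phasor is the measured phasor of the
#' pixel complex-divided by the analytic phasor of the fitted model.
#'
#' @param cube A [decay_cube()] (unbinned; `bin` controls internal
#'   binning, `bin = 1` to disable).
#' @param cfg A [transform_config()].
#' @param bin Spatial binning applied before choosing the pixel.
#' @param alpha F-test level for the reference fit.
#' @return Named numeric `c(g, s)` — the IRF phasor.  Falls back to the
#'   unit IRF `(1, 0)` with a warning if the reference fit fails.
#' @export
estimate_irf_phasor <- function(cube, cfg, bin = 3L, alpha = 0.05) {
  b <- bin_spatial(cube, bin)
  tot <- intensity_image(b)
  assert_that(max(tot) > 0, "flat dark image; cannot estimate IRF")
  # ties: which.max on the transposed-index order; R arrays are
  # column-major so ordering by (col, row) — enforce (row, col) explicitly
  mx <- which(tot == max(tot), arr.ind = TRUE)
  mx <- mx[order(mx[, 1], mx[, 2])[1], , drop = FALSE]
  h <- b$counts[mx[1], mx[2], ]
  z_meas <- phasor_transform(h, cfg)
  ref <- tryCatch(tail_fit_reference(h, b$meta, alpha),
                  error = function(e) NULL)
  if (is.null(ref)) {
    warning("reference fit on brightest pixel failed; using unit IRF")
    return(c(g = 1, s = 0))
  }
  z_model <- analytic_phasor(ref, cfg)
  complex_divide(z_meas, z_model)
}

# Fit A_i exp(-t/tau_i) + b to the bins from the decay maximum onward
# (plain, unwrapped exponentials: past the peak the broadened decay is a
# clean exponential sum).  Returns synth_components of the chosen order.
tail_fit_reference <- function(h, meta, alpha = 0.05) {
  tc <- bin_centers_ns(meta)
  p <- which.max(h)
  idx <- p:length(h)
  y <- as.numeric(h[idx]); t <- tc[idx]
  wts <- 1 / sqrt(pmax(y, 1))
  fit_k <- function(k, par0) {
    fn <- function(par) {
      m <- numeric(length(t))
      for (j in seq_len(k)) {
        m <- m + par[2 * j - 1] * exp(-t / max(par[2 * j], 1e-3))
      }
      (m + par[2 * k + 1] - y) * wts
    }
    minpack.lm::nls.lm(par = par0, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  a0 <- max(y)
  f1 <- fit_k(1, c(a0, 2, 0))
  # seed the two-component fit from the converged single-component one so
  # its chi2 can only improve
  a1 <- f1$par[1]; t1 <- max(f1$par[2], 0.05); b1 <- f1$par[3]
  f2 <- fit_k(2, c(0.6 * a1, 0.7 * t1, 0.4 * a1, 1.6 * t1, b1))
  mk <- function(f, k) list(chi2 = sum(f$fvec^2),
                            dof = length(t) - (2 * k + 1), model_order = k)
  sel <- select_model(mk(f1, 1), mk(f2, 2), alpha)
  par <- if (sel$chosen_order == 2) f2$par else f1$par
  k <- sel$chosen_order
  amps <- par[seq(1, 2 * k, 2)]; taus <- par[seq(2, 2 * k, 2)]
  keep <- amps > 0 & taus > 0
  assert_that(any(keep), "degenerate reference fit")
  synth_components(taus[keep], amps[keep])
}

complex_divide <- function(z1, z2) {
  z <- complex(real = z1[["g"]], imaginary = z1[["s"]]) /
    complex(real = z2[["g"]], imaginary = z2[["s"]])
  c(g = Re(z), s = Im(z))
}

#' Correct a phasor field (or point) for the IRF
#'
#' Per-pixel complex division `z_corrected = z_measured / z_irf` with
#' `z = g + i s`; exactly inverts the phasor-space effect of convolution
#' with the IRF.
#'
#' @param field A `phasor_field` or a named `c(g, s)` point.
#' @param irf_phasor Named `c(g, s)` from [estimate_irf_phasor()] or
#'   [gaussian_irf_phasor()].
#' @return The corrected field/point (fields get `corrected = TRUE`).
#' @export
correct_irf <- function(field, irf_phasor) {
  mod2 <- irf_phasor[["g"]]^2 + irf_phasor[["s"]]^2
  assert_that(mod2 > 0, "IRF phasor has zero magnitude")
  if (!inherits(field, "phasor_field")) {
    return(complex_divide(field, irf_phasor))
  }
  zg <- field$g; zs <- field$s
  field$g <- (zg * irf_phasor[["g"]] + zs * irf_phasor[["s"]]) / mod2
  field$s <- (zs * irf_phasor[["g"]] - zg * irf_phasor[["s"]]) / mod2
  field$corrected <- TRUE
  field
}

#' Free/bound NAD(P)H phasor axis calibration
#'
#' Endpoints are the analytic single-species phasors of the free
#' (`tau_free`, default 0.4 ns) and enzyme-bound (`tau_bound`, default
#' 3.4 ns) NADH lifetimes.  The axis length is computed both as the
#' Euclidean distance between the endpoints and by the closed form
#' `L = sqrt(1/(1+x1^2) + 1/(1+x2^2) - 2 (1 + x1 x2) /
#' ((1+x1^2)(1+x2^2)))` with `x_i = omega tau_i`; the two must agree.
#'
#' @param tau_free,tau_bound Calibration lifetimes in ns (distinct).
#' @param cfg A [transform_config()].
#' @return An object of class `phasor_calibration` with `p1` (free
#'   endpoint), `p2` (bound endpoint), `L`, `tau_free`, `tau_bound`,
#'   `omega`.
#' @export
phasor_axis <- function(tau_free = 0.4, tau_bound = 3.4,
                        cfg = transform_config()) {
  assert_that(abs(tau_free - tau_bound) > 1e-12,
              "calibration lifetimes must be distinct")
  p1 <- analytic_phasor(synth_components(tau_free), cfg)
  p2 <- analytic_phasor(synth_components(tau_bound), cfg)
  L_euclid <- sqrt(sum((p2 - p1)^2))
  x1 <- cfg$omega * tau_free * 1e-9
  x2 <- cfg$omega * tau_bound * 1e-9
  L_closed <- sqrt(1 / (1 + x1^2) + 1 / (1 + x2^2) -
                     2 * (1 + x1 * x2) / ((1 + x1^2) * (1 + x2^2)))
  assert_that(abs(L_euclid - L_closed) < 1e-9,
              "axis-length closed form disagrees with Euclidean distance")
  structure(list(p1 = p1, p2 = p2, L = L_euclid, tau_free = tau_free,
                 tau_bound = tau_bound, omega = cfg$omega),
            class = "phasor_calibration")
}

#' Project phasors onto the free/bound axis: bound NAD(P)H fraction
#'
#' Each pixel phasor is orthogonally projected onto the line through `p1`
#' and `p2`; the signed distance `l_i` from `p1`, normalized by the axis
#' length `L`, is the bound fraction `f = l_i / L` (0 = pure free, 1 =
#' pure bound).  For any two-species mixture of the calibration lifetimes
#' the phasor lies on the chord and `f = A2 tau2 / (A1 tau1 + A2 tau2)`
#' exactly.  The unclamped values are kept for statistics; `fraction_clamped`
#' is a `[0, 1]`-clipped copy for display.
#'
#' @param field A `phasor_field` or named `c(g, s)` point.
#' @param calib A [phasor_axis()] calibration.
#' @return For a field, an object of class `bound_fraction_map` with
#'   matrices `l`, `fraction`, `fraction_clamped`; for a point, the scalar
#'   fraction.
#' @export
bound_fraction <- function(field, calib) {
  ux <- (calib$p2[["g"]] - calib$p1[["g"]]) / calib$L
  uy <- (calib$p2[["s"]] - calib$p1[["s"]]) / calib$L
  if (!inherits(field, "phasor_field")) {
    l <- (field[["g"]] - calib$p1[["g"]]) * ux +
      (field[["s"]] - calib$p1[["s"]]) * uy
    return(l / calib$L)
  }
  l <- (field$g - calib$p1[["g"]]) * ux + (field$s - calib$p1[["s"]]) * uy
  f <- l / calib$L
  structure(list(l = l, fraction = f,
                 fraction_clamped = pmin(pmax(f, 0), 1), calib = calib),
            class = "bound_fraction_map")
}

#' Two-dimensional phasor histogram
#'
#' Counts over a `g in [0, 1] x s in [0, 0.6]` grid (the region containing
#' the universal semicircle); pixels falling outside are tallied in
#' `overflow` so that in-range counts plus overflow equal the pixel count.
#'
#' @param field A `phasor_field`.
#' @param mask Optional logical matrix selecting pixels.
#' @param n_g,n_s Number of grid cells per axis.
#' @param g_range,s_range Axis ranges.
#' @return List with `counts` (`n_g x n_s` matrix), `g_edges`, `s_edges`,
#'   `overflow`, `n`.
#' @export
phasor_histogram_2d <- function(field, mask = NULL, n_g = 256L, n_s = 256L,
                                g_range = c(0, 1), s_range = c(0, 0.6)) {
  sel <- if (is.null(mask)) is.finite(field$g) else mask & is.finite(field$g)
  g <- field$g[sel]; s <- field$s[sel]
  assert_that(length(g) >= 1, "no pixels selected", class = "empty_roi_error")
  gi <- floor((g - g_range[1]) / diff(g_range) * n_g) + 1
  si <- floor((s - s_range[1]) / diff(s_range) * n_s) + 1
  ok <- gi >= 1 & gi <= n_g & si >= 1 & si <= n_s
  counts <- matrix(0L, n_g, n_s)
  if (any(ok)) {
    counts <- matrix(tabulate((si[ok] - 1L) * n_g + gi[ok],
                              nbins = n_g * n_s), n_g, n_s)
  }
  list(counts = counts,
       g_edges = seq(g_range[1], g_range[2], length.out = n_g + 1),
       s_edges = seq(s_range[1], s_range[2], length.out = n_s + 1),
       overflow = sum(!ok), n = length(g))
}

#' Bound-fraction histogram and Gaussian population fit
#'
#' Histograms the per-pixel bound fraction over `[-0.1, 1.1]` (unclamped
#' values, so shot noise around the endpoints stays symmetric) and fits
#' one or two Gaussian populations ([fit_gaussian_populations()]); the
#' image's mean bound fraction is the weight-averaged population mean.
#'
#' @param map A [bound_fraction()] map.
#' @param mask Optional logical matrix selecting pixels.
#' @param bin_width Histogram bin width (default 0.005).
#' @param alpha F-test level for the two-population model.
#' @return List with `histogram` (a `value_histogram`), `populations`
#'   (a `gaussian_populations`), and `mean_bound_fraction`.
#' @export
bound_fraction_histogram <- function(map, mask = NULL, bin_width = 0.005,
                                     alpha = 0.05) {
  vals <- if (is.null(mask)) as.vector(map$fraction) else map$fraction[mask]
  vals <- vals[is.finite(vals)]
  assert_that(length(vals) >= 1, "no eligible pixels",
              class = "empty_roi_error")
  hist <- value_histogram(vals, bin_width, lo = -0.1, hi = 1.1,
                          source = "bound_fraction")
  pops <- fit_gaussian_populations(hist, alpha)
  mean_f <- weighted.mean(pops$populations$mean, pops$populations$weight)
  list(histogram = hist, populations = pops, mean_bound_fraction = mean_f)
}

#' Plot a 2-d phasor histogram with the universal semicircle
#'
#' @param hist2d Result of [phasor_histogram_2d()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_phasor_histogram <- function(hist2d, ...) {
  gx <- hist2d$g_edges; sx <- hist2d$s_edges
  graphics::image(x = gx, y = sx, z = log1p(hist2d$counts),
                  xlab = "g", ylab = "s", useRaster = TRUE, ...)
  th <- seq(0, pi, length.out = 200)
  graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), lty = 2)
  invisible(NULL)
}
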