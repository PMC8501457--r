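# Shared fixtures: everything is generated in code, nothing on disk.

meta256 <- acquisition_meta(n_bins = 256L)
cfg100 <- transform_config(1e8, meta256)

# the literature free/bound NADH lifetimes used throughout
nadh_free <- 0.4
nadh_bound <- 3.4
nadh_mix <- synth_components(c(nadh_free, nadh_bound), c(1, 1))

# closed-form single-exponential phasor (independent of the package's
# transform code path)
semicircle_point <- function(tau_ns, omega = 2 * pi * 1e8) {
  x <- omega * tau_ns * 1e-9
  c(g = 1 / (1 + x^2), s = x / (1 + x^2))
}

# small single-cell phantom used by several suites
tiny_phantom <- function(seed, shape = c(24L, 24L), photons = 800,
                         bleach_rate = 0, n_frames = 3L,
                         nuclear_components = synth_components(nadh_free, 1),
                         cytoplasm_components = nadh_mix) {
  field_phantom(
    shape = shape,
    cells = list(list(center = (shape - 1) / 2, radii = shape * 0.42,
                      nuclear_radii = shape * 0.18)),
    cytoplasm_components = cytoplasm_components,
    nuclear_components = nuclear_components,
    photons_per_pixel = c(cytoplasm = photons, nucleus = 0.6 * photons),
    n_frames = n_frames, bleach_rate = bleach_rate,
    meta = meta256, seed = seed)
}

# standard-error of a phasor coordinate estimated from the histogram
# itself (photon-count delta method)
phasor_se <- function(hist, cfg) {
  tc <- (seq_along(hist) - 0.5) * cfg$bin_width
  n <- sum(hist)
  se_of <- function(w) {
    m <- sum(hist * w) / n
    sqrt(sum(hist * (w - m)^2) / n / n)
  }
  c(g = se_of(cos(cfg$omega * tc)), s = se_of(sin(cfg$omega * tc)))
}
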