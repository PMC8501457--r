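# Phasor transform, analytic phasors, IRF correction, axis calibration,
# bound-fraction projection, and histograms.

test_that("the transform reproduces closed-form single-exponential phasors", {
  # delta at the first bin center: phase is half a bin, nearly (1, 0)
  one_hot <- c(1000, rep(0, 255))
  z0 <- phasor_transform(one_hot, cfg100)
  expect_equal(z0[["g"]], 1, tolerance = 1e-3)
  expect_equal(z0[["s"]], 0, tolerance = 0.02)

  for (tau in c(nadh_free, nadh_bound)) {
    h <- decay_model_histogram(synth_components(tau), meta256,
                               n_photons = 1e6)
    z <- phasor_transform(h, cfg100)
    target <- semicircle_point(tau)
    expect_lt(abs(z[["g"]] - target[["g"]]), 1e-3)
    expect_lt(abs(z[["s"]] - target[["s"]]), 1e-3)
  }
  expect_error(phasor_transform(rep(0, 256), cfg100),
               class = "undefined_phasor_error")
})

test_that("analytic phasors honor limits, worked values, and linearity", {
  expect_equal(analytic_phasor(synth_components(1e-6), cfg100),
               c(g = 1, s = 0), tolerance = 1e-6)
  expect_equal(analytic_phasor(synth_components(1e6), cfg100),
               c(g = 0, s = 0), tolerance = 1e-3)

  z <- analytic_phasor(nadh_mix, cfg100)
  # hand evaluation: N = 3.8, weights (0.4, 3.4)/3.8 on the endpoints
  p1 <- semicircle_point(0.4); p2 <- semicircle_point(3.4)
  expect_equal(z, (0.4 * p1 + 3.4 * p2) / 3.8, tolerance = 1e-12)
  expect_equal(unname(z), c(0.2598, 0.3684), tolerance = 1e-4)

  # linearity for random component sets
  set.seed(12)
  for (i in 1:20) {
    taus <- runif(3, 0.1, 6); amps <- runif(3, 0.1, 2)
    mix <- analytic_phasor(synth_components(taus, amps), cfg100)
    w <- amps * taus / sum(amps * taus)
    comb <- Reduce(`+`, lapply(1:3, function(j)
      w[j] * analytic_phasor(synth_components(taus[j]), cfg100)))
    expect_equal(mix, comb, tolerance = 1e-12)
  }
})

test_that("noise-free single exponentials land on the universal semicircle", {
  for (tau in exp(seq(log(0.05), log(10), length.out = 15))) {
    z <- analytic_phasor(synth_components(tau), cfg100)
    expect_lt(abs((z[["g"]] - 0.5)^2 + z[["s"]]^2 - 0.25), 1e-12)
    zd <- phasor_transform(decay_model_histogram(synth_components(tau),
                                                 meta256, n_photons = 1),
                           cfg100)
    expect_lt(abs(sqrt((zd[["g"]] - 0.5)^2 + zd[["s"]]^2) - 0.5), 1e-3)
  }
})

test_that("IRF correction inverts phasor-space convolution exactly", {
  z <- analytic_phasor(nadh_mix, cfg100)
  irf <- gaussian_irf_phasor(irf_model("gaussian", center = 1, fwhm = 0.2))
  blurred <- c(g = z[["g"]] * irf[["g"]] - z[["s"]] * irf[["s"]],
               s = z[["g"]] * irf[["s"]] + z[["s"]] * irf[["g"]])
  restored <- correct_irf(blurred, irf)
  expect_equal(restored, z, tolerance = 1e-12)
  expect_equal(correct_irf(z, c(g = 1, s = 0)), z, tolerance = 1e-15)
  expect_error(correct_irf(z, c(g = 0, s = 0)), "magnitude")
})

test_that("the IRF phasor is estimated from the brightest pixel", {
  counts <- array(0L, dim = c(6, 6, 256))
  g <- irf_model("gaussian", center = 1, fwhm = 0.2)
  set.seed(3)
  for (r in 1:6) for (c in 1:6) {
    n <- if (r == 3 && c == 3) 3e5 else 3e3
    counts[r, c, ] <- simulate_decay(synth_components(2.0), n, g, meta256,
                                     seed = r * 31 + c)
  }
  cube <- decay_cube(counts, meta256)
  z <- estimate_irf_phasor(cube, cfg100, bin = 1L)
  target <- gaussian_irf_phasor(g)
  expect_lt(sqrt(sum((z - target)^2)), 0.01)

  # delta-IRF cube: estimated IRF phasor near (1, 0)
  counts0 <- array(0L, dim = c(4, 4, 256))
  for (r in 1:4) for (c in 1:4) {
    n <- if (r == 2 && c == 2) 2e5 else 2e3
    counts0[r, c, ] <- simulate_decay(synth_components(2.0), n,
                                      irf_model("delta"), meta256,
                                      seed = r * 17 + c)
  }
  z0 <- estimate_irf_phasor(decay_cube(counts0, meta256), cfg100, bin = 1L)
  expect_lt(sqrt(sum((z0 - c(1, 0))^2)), 0.01)
})

test_that("estimate-then-correct returns broadened single exponentials to the semicircle", {
  g <- irf_model("gaussian", center = 1, fwhm = 0.2)
  counts <- array(0L, dim = c(4, 4, 256))
  set.seed(9)
  for (r in 1:4) for (c in 1:4) {
    n <- if (r == 2 && c == 2) 3e5 else 3e4
    counts[r, c, ] <- simulate_decay(synth_components(2.0), n, g, meta256,
                                     seed = 500 + r * 19 + c)
  }
  cube <- decay_cube(counts, meta256)
  z_irf <- estimate_irf_phasor(cube, cfg100, bin = 1L)
  field <- correct_irf(phasor_transform(cube, cfg100), z_irf)
  resid <- abs(sqrt((field$g - 0.5)^2 + field$s^2) - 0.5)
  expect_lt(max(resid), 0.01)
  expect_true(field$corrected)
})

test_that("the axis calibration matches the closed-form length and endpoint phasors", {
  ax <- phasor_axis(0.4, 3.4, cfg100)
  expect_equal(ax$p1, analytic_phasor(synth_components(0.4), cfg100))
  expect_equal(ax$p2, analytic_phasor(synth_components(3.4), cfg100))
  expect_equal(ax$L, sqrt(sum((ax$p2 - ax$p1)^2)), tolerance = 1e-12)
  expect_equal(ax$L, 0.7750, tolerance = 1e-4)
  expect_error(phasor_axis(1.2, 1.2, cfg100), "distinct")
})

test_that("bound-fraction projection hits the endpoints and the mixture formula", {
  ax <- phasor_axis(0.4, 3.4, cfg100)
  expect_equal(bound_fraction(ax$p1, ax), 0)
  expect_equal(bound_fraction(ax$p2, ax), 1)
  z <- analytic_phasor(nadh_mix, cfg100)
  expect_equal(bound_fraction(z, ax), 3.4 / 3.8, tolerance = 1e-12)

  # projection equals A2 tau2 / (A1 tau1 + A2 tau2) for random mixtures
  set.seed(88)
  for (i in 1:200) {
    a <- runif(2, 0.01, 5)
    zm <- analytic_phasor(synth_components(c(0.4, 3.4), a), cfg100)
    f_geo <- bound_fraction(zm, ax)
    f_formula <- a[2] * 3.4 / (a[1] * 0.4 + a[2] * 3.4)
    expect_lt(abs(f_geo - f_formula), 1e-9)
  }

  # swapping calibration lifetimes flips f to 1 - f
  ax_swap <- phasor_axis(3.4, 0.4, cfg100)
  expect_equal(bound_fraction(z, ax_swap), 1 - 3.4 / 3.8, tolerance = 1e-12)

  # monotone in the intensity-weighted bound share
  shares <- seq(0.05, 0.95, by = 0.1)
  fs <- vapply(shares, function(p) {
    a2 <- p / (1 - p) * 0.4 / 3.4
    bound_fraction(analytic_phasor(synth_components(c(0.4, 3.4), c(1, a2)),
                                   cfg100), ax)
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("2-d phasor histograms conserve pixels and localize clusters", {
  g <- matrix(c(0.26, 0.26, 0.94, 0.94), 2, 2)
  s <- matrix(c(0.37, 0.37, 0.24, 0.24), 2, 2)
  field <- structure(list(g = g, s = s, corrected = TRUE), class = "phasor_field")
  h <- phasor_histogram_2d(field, n_g = 64, n_s = 64)
  expect_equal(sum(h$counts) + h$overflow, 4)
  expect_equal(sum(h$counts > 0), 2)

  # out-of-range values land in the overflow tally
  field$g[1, 1] <- 1.7
  h2 <- phasor_histogram_2d(field, n_g = 64, n_s = 64)
  expect_equal(h2$overflow, 1)
  expect_equal(sum(h2$counts) + h2$overflow, 4)
})

test_that("bound-fraction histograms recover the per-compartment truth", {
  # constant field: population mean equals the constant
  ax <- phasor_axis(0.4, 3.4, cfg100)
  const_map <- structure(list(fraction = matrix(0.42, 5, 5)),
                         class = "bound_fraction_map")
  bf <- bound_fraction_histogram(const_map)
  expect_equal(bf$mean_bound_fraction, 0.42, tolerance = 1e-9)

  # simulated phantom, unbinned phasors so compartments stay pure
  ph <- tiny_phantom(seed = 202, shape = c(20L, 20L), photons = 3000)
  sim <- simulate_field(ph)
  field <- phasor_transform(sim$cube, cfg100)
  bmap <- bound_fraction(field, ax)
  cyto <- bound_fraction_histogram(bmap, sim$truth$labels == 1L)
  nuc <- bound_fraction_histogram(bmap, sim$truth$labels == 2L)
  sem_c <- max(cyto$populations$populations$sem[1], 5e-3)
  sem_n <- max(nuc$populations$populations$sem[1], 5e-3)
  expect_lt(abs(cyto$mean_bound_fraction - 3.4 / 3.8), 3 * sem_c)
  expect_lt(abs(nuc$mean_bound_fraction - 0), 3 * sem_n)
  expect_gt(cyto$mean_bound_fraction, nuc$mean_bound_fraction)
})
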