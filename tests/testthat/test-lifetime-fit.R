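# Spatial binning, gating, decay fitting, model selection, mean lifetime,
# and Gaussian population fitting.

test_that("sliding-window binning sums neighborhoods with zero-padded edges", {
  m <- acquisition_meta(n_bins = 8, period = 10e-9)
  d <- c(5L, 3L, 1L, 0L, 0L, 0L, 0L, 0L)
  counts <- array(rep(d, each = 25), dim = c(5, 5, 8))
  cube <- decay_cube(counts, m)
  b3 <- bin_spatial(cube, 3L)
  expect_equal(b3$counts[3, 3, ], 9L * d)     # interior
  expect_equal(b3$counts[1, 1, ], 4L * d)     # corner: 4 in-bounds neighbors
  expect_equal(b3$counts[1, 3, ], 6L * d)     # edge: 6 in-bounds neighbors
  expect_identical(bin_spatial(cube, 1L)$counts, cube$counts)
  expect_error(bin_spatial(cube, 2L), class = "parameter_error")
})

test_that("binning commutes with time summation", {
  ph <- tiny_phantom(seed = 101, shape = c(12L, 12L), photons = 150)
  cube <- simulate_field(ph)$cube
  b <- bin_spatial(cube, 3L)
  img <- intensity_image(cube)
  # bin the intensity image directly with the same sliding window
  binned_img <- matrix(0, 12, 12)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(12, 12 + dr); rd <- max(1, 1 - dr):min(12, 12 - dr)
    cs <- max(1, 1 + dc):min(12, 12 + dc); cd <- max(1, 1 - dc):min(12, 12 - dc)
    binned_img[rd, cd] <- binned_img[rd, cd] + img[rs, cs]
  }
  expect_equal(intensity_image(b), binned_img)
})

test_that("photon gating applies the exact threshold", {
  m <- acquisition_meta(n_bins = 8, period = 10e-9)
  counts <- array(0L, dim = c(1, 3, 8))
  counts[1, 1, 1] <- 19999L
  counts[1, 2, 1] <- 20000L
  cube <- decay_cube(counts, m)
  expect_equal(as.vector(gate_pixels(cube)), c(FALSE, TRUE, FALSE))
})

test_that("noise-free decays are recovered to 0.1% across the lifetime range", {
  for (tau in c(0.2, 0.5, 1, 2, 3.4, 5)) {
    h <- decay_model_histogram(synth_components(tau), meta256,
                               n_photons = 1e5)
    f <- fit_decay(h, meta256, order = 1L)
    expect_lt(abs(f$lifetimes - tau) / tau, 1e-3)
    expect_lt(abs(f$areas - 1e5) / 1e5, 1e-3)
  }
  # two components: lifetimes and the amplitude ratio recovered exactly
  h2 <- decay_model_histogram(nadh_mix, meta256, n_photons = 1e5)
  f2 <- fit_decay(h2, meta256, order = 2L)
  expect_equal(f2$lifetimes, c(0.4, 3.4), tolerance = 1e-4)
  expect_equal(f2$amplitudes[1] / f2$amplitudes[2], 1, tolerance = 1e-3)
  expect_equal(f2$tau_m, 1.9, tolerance = 1e-3)
})

test_that("an order-2 fit on single-exponential data degenerates and the F-test prefers order 1", {
  # noise-free: the second component collapses (equal lifetimes or
  # vanishing amplitude)
  h <- decay_model_histogram(synth_components(2.0), meta256, n_photons = 1e5)
  f2 <- fit_decay(h, meta256, order = 2L)
  degenerate <- abs(diff(f2$lifetimes)) < 0.2 ||
    min(f2$areas) / max(f2$areas) < 1e-3
  expect_true(degenerate)

  # with shot noise the F-test keeps the single-exponential model in the
  # overwhelming majority of realizations
  orders <- vapply(1:10, function(s) {
    hh <- simulate_decay(synth_components(2.0), 20000, irf_model("delta"),
                         meta256, seed = 9000 + s)
    select_model(fit_decay(hh, meta256, 1L),
                 fit_decay(hh, meta256, 2L))$chosen_order
  }, integer(1))
  expect_gte(sum(orders == 1L), 8)
})

test_that("the F statistic and p-value follow the stated formula", {
  mk <- function(chi2, dof, order) {
    structure(list(chi2 = chi2, dof = dof, model_order = order),
              class = "decay_fit")
  }
  sel <- select_model(mk(2 * 100, 202, 1L), mk(100, 200, 2L))
  expect_equal(sel$f_statistic, 100, tolerance = 1e-12)
  expect_lt(sel$p_value, 1e-10)
  expect_equal(sel$chosen_order, 2L)

  tie <- select_model(mk(100, 202, 1L), mk(100, 200, 2L))
  expect_equal(tie$f_statistic, 0)
  expect_equal(tie$chosen_order, 1L)

  # worked case: chi2_1 = 2 chi2_2, df1 = 2, dof2 = 200
  # -> F = (chi2_2 / 2) / (chi2_2 / 200) = 100
  sel100 <- select_model(mk(2 * 300, 202, 1L), mk(300, 200, 2L))
  expect_equal(sel100$f_statistic, 100, tolerance = 1e-12)
})

test_that("double-exponential fits at the photon gate recover both NADH lifetimes", {
  taus <- vapply(1:25, function(s) {
    h <- simulate_decay(nadh_mix, 20000, irf_model("delta"), meta256,
                        seed = 1000 + s)
    fit_decay(h, meta256, order = 2L)$lifetimes
  }, numeric(2))
  expect_lt(abs(mean(taus[2, ]) - 3.4) / 3.4, 0.05)
  expect_lt(abs(mean(taus[1, ]) - 0.4) / 0.4, 0.10)
})

test_that("mean lifetime follows the amplitude-weighted formula", {
  mk <- function(a, tau) structure(list(amplitudes = a, lifetimes = tau),
                                   class = "decay_fit")
  expect_equal(mean_lifetime(mk(c(1, 1), c(0.4, 3.4))), 1.9)
  expect_equal(mean_lifetime(mk(c(1, 0), c(0.4, 3.4))), 0.4)
  expect_equal(mean_lifetime(mk(c(1, 3), c(0.4, 3.4))), 2.65)
  # invariant under joint rescaling
  expect_equal(mean_lifetime(mk(c(7, 21), c(0.4, 3.4))), 2.65)
  expect_error(mean_lifetime(mk(c(0, 0), c(0.4, 3.4))), "undefined")
})

test_that("IRF-convolution fitting recovers lifetimes from broadened decays", {
  g <- irf_model("gaussian", center = 1, fwhm = 0.3)
  gh <- irf_histogram(g, meta256)
  h <- simulate_decay(synth_components(2.0), 1e5, g, meta256, seed = 404)
  f <- fit_decay(h, meta256, order = 1L, irf = gh)
  expect_lt(abs(f$lifetimes - 2.0) / 2.0, 0.01)
})

test_that("lifetime histograms count every fitted pixel at 50 ps resolution", {
  tau_map <- matrix(NA_real_, 4, 4)
  tau_map[1:2, 1:2] <- 1.9
  tau_map[3:4, 3:4] <- c(0.8, 0.83, 0.86, 0.89)
  h <- lifetime_histogram(tau_map)
  expect_equal(sum(h$counts), 8)
  expect_equal(h$bin_width, 0.05)
  single <- lifetime_histogram(matrix(1.9, 3, 3))
  expect_equal(sum(single$counts > 0), 1)
  expect_error(lifetime_histogram(matrix(NA_real_, 2, 2)),
               class = "empty_roi_error")
})

test_that("Gaussian population fitting recovers means and picks k by F-test", {
  set.seed(71)
  vals <- rnorm(10000, mean = 2.0, sd = 0.2)
  h <- value_histogram(vals, 0.05, lo = 1, hi = 3)
  gp <- fit_gaussian_populations(h)
  # the weight-averaged population mean is robust to an occasional
  # spurious split (mixture selection is not exactly chi-square nested)
  mu_hat <- weighted.mean(gp$populations$mean, gp$populations$weight)
  expect_lt(abs(mu_hat - 2.0), 0.01)

  # two well-separated populations (10 sigma apart, equal weights)
  vals2 <- c(rnorm(5000, 1.0, 0.1), rnorm(5000, 2.0, 0.1))
  h2 <- value_histogram(vals2, 0.05, lo = 0.5, hi = 2.5)
  gp2 <- fit_gaussian_populations(h2)
  expect_equal(gp2$k, 2L)
  expect_lt(abs(gp2$populations$mean[1] - 1.0), 3 * gp2$populations$sem[1])
  expect_lt(abs(gp2$populations$mean[2] - 2.0), 3 * gp2$populations$sem[2])
  expect_equal(gp2$populations$weight,  c(0.5, 0.5), tolerance = 0.1)

  # near-constant histogram degenerates to the empirical mean
  hc <- value_histogram(rep(1.9, 50), 0.05, lo = 1, hi = 3)
  gpc <- fit_gaussian_populations(hc)
  expect_equal(gpc$k, 1L)
  expect_equal(gpc$populations$mean[1], 1.9, tolerance = 0.05)
})
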