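# Background thresholding, bleaching correction, normalization,
# concentration proxy, and region summaries.

test_that("background thresholding follows the threshold exactly", {
  img <- matrix(c(0, 5, 10, 200, 300, 400), 2, 3)
  expect_false(any(background_mask(img, 0)))
  expect_true(all(background_mask(img, 1000)))
  expect_equal(sum(background_mask(img, 50)), 3)
})

test_that("the automatic Otsu threshold separates a bimodal intensity image", {
  set.seed(5)
  img <- matrix(c(rpois(200, 5), rpois(200, 300)), 20, 20)
  bg <- background_mask(img)      # NULL threshold -> Otsu
  expect_equal(sum(bg), 200, tolerance = 0.02)
  expect_true(all(img[bg] < min(img[!bg])))
})

test_that("phantom border pixels are background at any threshold below the cell intensity", {
  ph <- tiny_phantom(seed = 61, shape = c(16L, 16L), photons = 500)
  sim <- simulate_field(ph)
  img <- intensity_image(sim$cube)
  bg <- background_mask(img, threshold = 50)
  expect_identical(bg, sim$truth$labels == 0L)
})

test_that("the bleaching factor is the mean-to-first-frame ratio", {
  expect_equal(bleaching_factor(c(100, 100, 100))$factor, 1.0)
  expect_equal(bleaching_factor(c(100, 90, 80))$factor, 0.9)
  expect_equal(bleaching_factor(42)$factor, 1.0)
  expect_error(bleaching_factor(c(0, 10)), "positive")
  # non-increasing frames give b <= 1, so correction never shrinks
  for (i in 1:5) {
    fm <- sort(runif(4, 10, 100), decreasing = TRUE)
    b <- bleaching_factor(fm)
    expect_lte(b$factor, 1)
    expect_gte(corrected_intensity(fm[1], b), fm[1])
  }
})

test_that("corrected intensity divides by the factor", {
  expect_equal(corrected_intensity(90, bleaching_factor(c(100, 90, 80))), 100)
  expect_equal(corrected_intensity(55, bleaching_factor(c(7, 7))), 55)
})

test_that("control normalization is a strict same-replicate ratio", {
  expect_equal(normalize_to_control(100, 100), 1.0)
  expect_equal(normalize_to_control(100, c(150, 250)), 0.5)
  expect_equal(normalize_to_control(100, 400), 0.25)
  expect_error(normalize_to_control(100, numeric(0)), class = "pairing_error")
  expect_error(normalize_to_control(100, NA_real_), class = "pairing_error")
})

test_that("the concentration proxy is intensity over lifetime", {
  expect_equal(concentration_proxy(2, 1), 2)
  expect_equal(concentration_proxy(100, 2.5), 40)
  expect_error(concentration_proxy(10, 0), "positive")
})

test_that("corrected intensity is invariant under pure bleaching", {
  # same phantom, same seed, with and without bleaching: after correction
  # the mean intensities agree within Poisson counting error
  base <- tiny_phantom(seed = 91, shape = c(16L, 16L), photons = 1000,
                       n_frames = 4L, bleach_rate = 0)
  bleached <- tiny_phantom(seed = 91, shape = c(16L, 16L), photons = 1000,
                           n_frames = 4L, bleach_rate = 0.12)
  s0 <- simulate_field(base)
  s1 <- simulate_field(bleached)
  cell <- s0$truth$labels > 0L
  i0 <- mean(intensity_image(s0$cube)[cell])
  i1 <- mean(intensity_image(s1$cube)[cell])
  c0 <- corrected_intensity(i0, bleaching_factor(s0$cube$frame_intensity))
  c1 <- corrected_intensity(i1, bleaching_factor(s1$cube$frame_intensity))
  expect_gt(i0, i1)   # bleaching removed photons
  se <- sqrt(i0 / sum(cell))
  expect_lt(abs(c0 - c1), 5 * se)
})

test_that("region summaries aggregate compartments and compose whole-cell means", {
  ph <- tiny_phantom(seed = 111, shape = c(20L, 20L), photons = 1200)
  sim <- simulate_field(ph)
  ax <- phasor_axis(0.4, 3.4, cfg100)
  bmap <- bound_fraction(phasor_transform(sim$cube, cfg100), ax)
  bl <- bleaching_factor(sim$cube$frame_intensity)
  tab <- summarize_regions(sim$cube, sim$truth, bmap, bleach = bl)

  expect_setequal(tab$compartment, c("nucleus", "cytoplasm", "whole-cell"))
  # pixel counts match the synthetic truth
  expect_equal(tab$n_pixels[tab$compartment == "nucleus"],
               sum(sim$truth$labels == 2L))
  expect_equal(tab$n_pixels[tab$compartment == "cytoplasm"],
               sum(sim$truth$labels == 1L))
  # nuclear bound fraction below cytoplasmic (free nuclear NAD(P)H phantom)
  f_n <- tab$bound_fraction[tab$compartment == "nucleus"]
  f_c <- tab$bound_fraction[tab$compartment == "cytoplasm"]
  expect_lt(f_n, f_c)
  # whole-cell raw intensity is the pixel-weighted compartment mean
  w <- tab$n_pixels[match(c("nucleus", "cytoplasm"), tab$compartment)]
  r <- tab$raw_intensity[match(c("nucleus", "cytoplasm"), tab$compartment)]
  expect_equal(tab$raw_intensity[tab$compartment == "whole-cell"],
               sum(w * r) / sum(w), tolerance = 1e-12)
  # concentration proxy identity where defined
  ok <- is.finite(tab$concentration_proxy)
  expect_equal(tab$concentration_proxy[ok],
               tab$corrected_intensity[ok] / tab$mean_lifetime[ok],
               tolerance = 1e-12)
})

test_that("summaries are permutation-invariant and warn on empty compartments", {
  m <- acquisition_meta(n_bins = 8, period = 10e-9)
  counts <- array(rpois(4 * 4 * 8, 20), dim = c(4, 4, 8))
  cube <- decay_cube(counts, m)
  labels <- matrix(1L, 4, 4)   # no nucleus anywhere
  expect_warning(tab <- summarize_regions(cube, mask_set(labels, "manual")),
                 "empty")
  expect_false("nucleus" %in% tab$compartment)
})
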