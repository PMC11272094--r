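test_that("geometry analytics match the bench values", {
  expect_equal(round(magnification(600, 200), 2), 1.33)
  expect_equal(round(magnification(600, 300), 2), 1.50)
  expect_equal(round(magnification(600, 400), 2), 1.67)
  expect_equal(magnification(600, 0), 1)
  expect_error(magnification(0, 100), "positive")
  g <- geometry(600, 200)
  expect_equal(g$magnification, 4 / 3)
  expect_equal(g$effective_distance_mm, 150)
  expect_equal(g$object_pixel_mm, 0.0135 * 3 / 4)
})

test_that("Fresnel number and validity flag behave as defined", {
  # a = 5 um, lambda = 0.1 nm, d = 1 cm -> NF = 25
  f <- fresnel_number(5e-3, 1e-7, 10)
  expect_equal(f$nf, 25)
  expect_true(f$valid)
  # d = 2.5 mm -> 100
  expect_equal(fresnel_number(5e-3, 1e-7, 2.5)$nf, 100)
  # quadratic in the resolution
  expect_equal(fresnel_number(1e-2, 1e-7, 10)$nf, 4 * 25)
  expect_error(fresnel_number(-1, 1, 1), "positive")
})

test_that("projection approximation gives Beer-Lambert amplitudes", {
  px <- 0.01
  # empty map: unit transmission
  empty <- thickness_map(matrix(0, 16, 16), px)
  f <- project_monochromatic(empty, toy_nylon, 10.3)
  expect_equal(Mod(f), matrix(1, 16, 16), ignore_attr = TRUE)
  # uniform slab: |t|^2 = exp(-mu T0), mu = 4 pi beta / lambda
  slab <- thickness_map(matrix(2, 16, 16), px)
  fs <- project_monochromatic(slab, toy_nylon, 10.3)
  mu <- attenuation_coefficient(2.6e-9, 10.3)
  # regression anchor for the toy nylon attenuation at 10.3 keV
  expect_equal(mu, 0.27143, tolerance = 1e-4)
  expect_equal(Mod(fs[1, 1])^2, exp(-mu * 2), tolerance = 1e-10)
  expect_error(project_monochromatic(slab, toy_nylon, 500), "range")
})

test_that("free-space propagation conserves energy and fixed points", {
  px <- 0.005
  n <- 64
  # uniform field stays uniform at any distance
  u <- matrix(1 + 0i, n, n)
  out <- propagate_fresnel(u, 50, 12, px)
  expect_equal(out, matrix(1, n, n), tolerance = 1e-10)
  # distance zero returns contact intensity
  bump <- gaussian_bump_map(n, px, amplitude_mm = 0.3)
  f <- project_monochromatic(bump, toy_nylon, 12)
  expect_equal(propagate_fresnel(f, 0, 12, px), Mod(f)^2)
  # Parseval: total intensity conserved without cropping
  i1 <- propagate_fresnel(f, 40, 12, px, pad = FALSE)
  expect_equal(sum(i1), sum(Mod(f)^2), tolerance = 1e-9)
  expect_warning(propagate_fresnel(f, 1e9, 12, px), "sampling limit")
})

test_that("polychromatic image is the weighted sum of monochromatic images", {
  geom <- test_geometry()
  bump <- gaussian_bump_map(96, geom$object_pixel_mm)
  # delta spectrum equals the single-energy image
  mono <- spectrum(10.3, 1)
  p1 <- forward_polychromatic(bump, toy_nylon, mono, geom, mode = "tie")
  two <- spectrum(c(9, 12), c(1, 3))
  p9 <- forward_polychromatic(bump, toy_nylon, spectrum(9, 1), geom, "tie")
  p12 <- forward_polychromatic(bump, toy_nylon, spectrum(12, 1), geom, "tie")
  pmix <- forward_polychromatic(bump, toy_nylon, two, geom, "tie")
  expect_equal(pmix$sample, (p9$sample + 3 * p12$sample) / 4,
               tolerance = 1e-12)
  # empty map, no noise: sample == reference exactly
  empty <- thickness_map(matrix(0, 96, 96), geom$object_pixel_mm)
  pe <- forward_polychromatic(empty, toy_nylon, two, geom, "tie")
  expect_identical(pe$sample, pe$reference)
  # uniform slab in TIE mode: pure Beer-Lambert contrast
  slab <- thickness_map(matrix(1.5, 96, 96), geom$object_pixel_mm)
  ps <- forward_polychromatic(slab, toy_nylon, mono, geom, "tie")
  mu <- attenuation_coefficient(2.6e-9, 10.3)
  expect_equal(ps$sample, matrix(exp(-mu * 1.5), 96, 96), tolerance = 1e-9)
})

test_that("TIE and Fresnel modes agree to first order in weak objects", {
  geom <- geometry(600, 200, source_size_mm = 0)
  n <- 128
  err_at <- function(amp) {
    bump <- gaussian_bump_map(n, geom$object_pixel_mm, amplitude_mm = amp,
                              sigma_frac = 0.12)
    sp <- spectrum(10.3, 1)
    tie <- forward_polychromatic(bump, toy_nylon, sp, geom, "tie")
    fre <- forward_polychromatic(bump, toy_nylon, sp, geom, "fresnel")
    max(abs(tie$sample - fre$sample))
  }
  e1 <- err_at(0.2)
  e2 <- err_at(0.02)
  # discrepancy is second order: 10x smaller amplitude -> ~100x smaller error
  expect_lt(e2, e1 / 30)
})

test_that("Poisson noise fluctuates at the photon-statistics level", {
  geom <- test_geometry()
  empty <- thickness_map(matrix(0, 128, 128), geom$object_pixel_mm)
  sp <- spectrum(10.3, 1)
  pair <- forward_polychromatic(empty, toy_nylon, sp, geom, "tie",
                                photons = 1e4, seed = 42)
  rel_sd <- sd(pair$sample) / mean(pair$sample)
  expect_equal(rel_sd, 1 / sqrt(1e4), tolerance = 0.1)
  # seeded: reproducible
  pair2 <- forward_polychromatic(empty, toy_nylon, sp, geom, "tie",
                                 photons = 1e4, seed = 42)
  expect_identical(pair$sample, pair2$sample)
})

test_that("speckle visibility matches closed forms and the design target", {
  # constant image: zero visibility
  expect_equal(speckle_visibility(matrix(5, 120, 120)), 0)
  # two-level image alternating a and b: V = |a - b| / (a + b)
  a <- 2; b <- 1
  chk <- matrix(rep(c(a, b), length.out = 100 * 100), 100, 100)
  expect_equal(speckle_visibility(chk), abs(a - b) / (a + b),
               tolerance = 1e-3)
  expect_error(speckle_visibility(matrix(0, 50, 50),
                                  list(row = 1, col = 1, size = 10)),
               "zero mean")
  expect_error(speckle_visibility(matrix(1, 50, 50),
                                  list(row = 40, col = 40, size = 20)),
               "outside")
  # simulated 3-layer diffuser: V = 0.12 +- 0.02 at the default roughness
  geom <- test_geometry()
  empty <- thickness_map(matrix(0, 256, 256), geom$object_pixel_mm)
  d <- make_diffuser(c(256, 256), geom$object_pixel_mm, seed = 5)
  pair <- forward_polychromatic(empty, toy_nylon,
                                make_synthetic_spectrum(50, 51), geom, "tie",
                                diffuser = d, diffuser_material = toy_sic)
  v <- speckle_visibility(pair$reference)
  expect_gt(v, 0.10)
  expect_lt(v, 0.14)
})

test_that("image pairs round-trip through TIFF + sidecar", {
  geom <- test_geometry()
  bump <- gaussian_bump_map(48, geom$object_pixel_mm)
  pair <- forward_polychromatic(bump, toy_nylon, spectrum(10.3, 1), geom,
                                "tie")
  stem <- file.path(withr::local_tempdir(), "pair")
  write_image_pair(pair, stem, extra = list(seed = 1, mode = "tie"))
  back <- read_image_pair(stem)
  expect_equal(back$sample, pair$sample, tolerance = 1e-6)
  expect_equal(back$geometry$odd_mm, 200)
})
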