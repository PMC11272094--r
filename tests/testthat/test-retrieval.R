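params_at <- function(energy) {
  ip <- interp_material(toy_nylon, energy)
  averaged_params(energy, ip$delta, ip$beta)
}

test_that("the near-field filter has the expected fixed points", {
  geom <- test_geometry()
  p <- params_at(10.3)
  # uniform image: only the zero frequency, denominator 1
  u <- matrix(3, 64, 64)
  expect_equal(paganin_filter(u, p$lambda_mm, p$gamma, geom),
               u, tolerance = 1e-10, ignore_attr = TRUE)
  # z = 0 and s = 0: identity at all frequencies
  g0 <- geometry(600, 0, source_size_mm = 0)
  r <- matrix(runif(64 * 64, 0.5, 1.5), 64, 64)
  expect_equal(paganin_filter(r, p$lambda_mm, p$gamma, g0), r,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the filter divides a pure spatial frequency by its denominator", {
  geom <- geometry(600, 200, source_size_mm = 0)
  p <- params_at(10.3)
  n <- 128
  px <- geom$object_pixel_mm
  # mirror-even mode: cos(pi nu0 (2x+1)/(2n)) survives reflection padding
  j <- 8
  nu0 <- j / (2 * n * px)
  x <- seq_len(n) - 1
  prof <- cos(pi * j * (2 * x + 1) / (2 * n))
  img <- matrix(prof, n, n, byrow = TRUE)
  den <- 1 + pi * p$lambda_mm * (p$gamma * geom$odd_mm / geom$magnification) *
    nu0^2
  out <- paganin_filter(img, p$lambda_mm, p$gamma, geom)
  expect_equal(unclass(out), img / den, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PT inverts Beer-Lambert exactly and the TIE forward exactly", {
  geom <- test_geometry()
  p <- params_at(10.3)
  # pure Beer-Lambert uniform slab: filter inert, T = T0; no low-frequency
  # distortion from any hidden high-pass
  t0 <- 1.7
  ref <- matrix(2, 96, 96)
  pair <- image_pair(ref * exp(-p$mu_mm * t0), ref, geom)
  tmap <- retrieve_pt(pair, p)
  expect_equal(unclass(tmap), matrix(t0, 96, 96), tolerance = 1e-9,
               ignore_attr = TRUE)
  # I = I_R: zero thickness
  pair0 <- image_pair(ref, ref, geom)
  expect_equal(max(abs(retrieve_pt(pair0, p))), 0, tolerance = 1e-12)
  # matched forward-inverse oracle on a smooth bump
  bump <- gaussian_bump_map(128, geom$object_pixel_mm, amplitude_mm = 0.8)
  fpair <- forward_polychromatic(bump, toy_nylon, spectrum(10.3, 1), geom,
                                 "tie")
  rec <- retrieve_pt(fpair, p)
  expect_lt(max(abs(rec - bump)) / max(bump), 1e-6)
})

test_that("PT and AT are scale invariant in the illumination", {
  geom <- test_geometry()
  p <- params_at(10.3)
  bump <- gaussian_bump_map(64, geom$object_pixel_mm, amplitude_mm = 0.5)
  pair <- forward_polychromatic(bump, toy_nylon, spectrum(10.3, 1), geom,
                                "tie")
  scaled <- image_pair(7.3 * pair$sample, 7.3 * pair$reference, geom)
  expect_equal(unclass(retrieve_pt(scaled, p)), unclass(retrieve_pt(pair, p)),
               tolerance = 1e-12)
  expect_equal(unclass(retrieve_at(scaled, p)), unclass(retrieve_at(pair, p)),
               tolerance = 1e-12)
})

test_that("AT linearisation: exact limit behaviour against PT", {
  geom <- test_geometry()
  p <- params_at(10.3)
  ref <- matrix(1, 32, 32)
  at_vs_pt <- function(t0) {
    pair <- image_pair(ref * exp(-p$mu_mm * t0), ref, geom)
    at <- retrieve_at(pair, p)[1, 1]
    pt <- retrieve_pt(pair, p)[1, 1]
    c(at = at, pt = pt, rel = abs(at - pt) / pt)
  }
  # weak absorber mu T = 1e-4: agreement to first order
  weak <- at_vs_pt(1e-4 / p$mu_mm)
  expect_lt(weak[["rel"]], 1e-4)
  # error ratio between amplitude levels ~ mu T / 2 scaling (factor 10)
  weaker <- at_vs_pt(1e-5 / p$mu_mm)
  expect_equal(weak[["rel"]] / weaker[["rel"]], 10, tolerance = 0.01)
  # strong absorber mu T = 1: AT returns (1 - e^-1)/mu, underestimate
  t1 <- 1 / p$mu_mm
  strong <- at_vs_pt(t1)
  expect_equal(strong[["at"]], (1 - exp(-1)) / p$mu_mm, tolerance = 1e-6)
  expect_lt(strong[["at"]], t1)
})

test_that("all operators reduce to Beer-Lambert inversion at s = 0, z -> 0", {
  p <- params_at(10.3)
  g0 <- geometry(600, 1e-9, source_size_mm = 0)
  bump <- gaussian_bump_map(64, g0$object_pixel_mm, amplitude_mm = 0.6)
  ref <- matrix(1, 64, 64)
  pair <- image_pair(ref * exp(-p$mu_mm * unclass(bump)), ref, g0)
  expect_equal(unclass(retrieve_pt(pair, p)), unclass(bump),
               tolerance = 1e-7, ignore_attr = TRUE)
  at <- retrieve_at(pair, p)
  expect_equal(unclass(at), (1 - exp(-p$mu_mm * unclass(bump))) / p$mu_mm,
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("retrieval is translation equivariant away from the edges", {
  geom <- test_geometry()
  p <- params_at(10.3)
  bump <- gaussian_bump_map(128, geom$object_pixel_mm, amplitude_mm = 0.5,
                            sigma_frac = 0.05)
  pair <- forward_polychromatic(bump, toy_nylon, spectrum(10.3, 1), geom,
                                "tie")
  shift <- 7L
  roll <- function(m) m[, c((shift + 1):ncol(m), 1:shift)]
  pair_s <- image_pair(roll(pair$sample), roll(pair$reference), geom)
  rec <- retrieve_pt(pair, p)
  rec_s <- retrieve_pt(pair_s, p)
  interior <- 33:96
  expect_equal(unclass(rec_s)[interior, interior],
               roll(unclass(rec))[interior, interior], tolerance = 1e-6)
})

test_that("ST equals PT for a flat diffuser and tolerates real speckle", {
  geom <- test_geometry()
  p <- params_at(10.3)
  n <- 256
  ph <- fiber_projection(0.71, 1.3, c(n, n), geom$object_pixel_mm)
  # flat diffuser: a uniform absorbing screen cancels in the ratio
  pair <- forward_polychromatic(ph, toy_nylon, spectrum(10.3, 1), geom, "tie")
  flat <- 0.6
  st <- retrieve_st(pair$sample * flat, pair$reference * flat, geom, p)
  pt <- retrieve_pt(pair, p)
  expect_equal(unclass(st), unclass(pt), tolerance = 1e-12)
  # speckled diffuser, one energy: apex recovered within 2% over seeds
  for (s in 1:5) {
    d <- make_diffuser(c(n, n), geom$object_pixel_mm, seed = s)
    sp_pair <- forward_polychromatic(ph, toy_nylon, spectrum(10.3, 1), geom,
                                     "tie", diffuser = d,
                                     diffuser_material = toy_sic)
    st2 <- retrieve_st(sp_pair$sample, sp_pair$reference, geom, p)
    apex <- max(unclass(st2)[n / 2, ])
    expect_lt(abs(apex - 0.71) / 0.71, 0.02)
  }
  # no object: zero-mean speckle residual
  empty <- thickness_map(matrix(0, n, n), geom$object_pixel_mm)
  d <- make_diffuser(c(n, n), geom$object_pixel_mm, seed = 11)
  ep <- forward_polychromatic(empty, toy_nylon, spectrum(10.3, 1), geom,
                              "tie", diffuser = d,
                              diffuser_material = toy_sic)
  st0 <- retrieve_st(ep$sample, ep$reference, geom, p)
  expect_lt(abs(mean(st0)), 1e-6)
})

test_that("two-material retrieval reduces to PT for vacuum material 1", {
  geom <- test_geometry()
  p2 <- params_at(10.3)
  # a near-vacuum material 1: delta, beta orders of magnitude below nylon
  vac <- averaged_params(10.3, 1e-20, 1e-23)
  bump <- gaussian_bump_map(96, geom$object_pixel_mm, amplitude_mm = 0.8)
  pair <- forward_polychromatic(bump, toy_nylon, spectrum(10.3, 1), geom,
                                "tie")
  a <- matrix(2, 96, 96)
  mpt <- retrieve_mpt(pair, a, vac, p2)
  pt <- retrieve_pt(pair, p2)
  expect_equal(unclass(mpt$t2), unclass(pt), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("two-material retrieval inverts the matched forward", {
  geom <- test_geometry()
  n <- 128
  plate <- two_material_plate(n = c(n, n), pixel_mm = geom$object_pixel_mm,
                              total_mm = 10, vol_frac = 0.4, corr_mm = 0.4,
                              seed = 5)
  mats <- list(toy_material("hips"), toy_material("pla"))
  pair <- forward_polychromatic(plate, mats, spectrum(10.3, 1), geom, "tie")
  p1 <- {ip <- interp_material(mats[[1]], 10.3)
         averaged_params(10.3, ip$delta, ip$beta)}
  p2 <- {ip <- interp_material(mats[[2]], 10.3)
         averaged_params(10.3, ip$delta, ip$beta)}
  a <- unclass(plate$t1) + unclass(plate$t2)
  rec <- retrieve_mpt(pair, a, p1, p2)
  expect_lt(max(abs(rec$t2 - plate$t2)) / max(plate$t2), 1e-4)
  # T1 is the complement
  expect_equal(unclass(rec$t1), a - unclass(rec$t2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # degenerate contrast rejected
  expect_error(retrieve_mpt(pair, a, p2, p2), "degenerate")
  # all-material-1 truth: T2 ~ 0
  plate0 <- two_material_plate(n = c(n, n), pixel_mm = geom$object_pixel_mm,
                               total_mm = 10, vol_frac = 0, seed = 5)
  pair0 <- forward_polychromatic(plate0, mats, spectrum(10.3, 1), geom, "tie")
  rec0 <- retrieve_mpt(pair0, a, p1, p2)
  expect_lt(max(rec0$t2), 1e-6)
})

test_that("polychromatic strategies coincide where they must", {
  geom <- test_geometry()
  bump <- gaussian_bump_map(96, geom$object_pixel_mm, amplitude_mm = 0.5)
  mono <- spectrum(10.3, 1)
  pair <- forward_polychromatic(bump, toy_nylon, mono, geom, "tie")
  cfg <- function(avg, n_ta = 16)
    retrieval_config("PT", avg, geom, mono, toy_nylon,
                     n_energy_samples = n_ta)
  rec_ea <- retrieve_polychromatic(pair, cfg("EA"))
  rec_pa <- retrieve_polychromatic(pair, cfg("PA"))
  rec_ta <- retrieve_polychromatic(pair, cfg("TA"))
  expect_equal(unclass(rec_ea), unclass(rec_pa), tolerance = 1e-12)
  expect_equal(unclass(rec_ea), unclass(rec_ta), tolerance = 1e-12)
  # TA with one sample equals EA at the mean energy, any spectrum
  sp <- make_synthetic_spectrum(50, 101)
  pairp <- forward_polychromatic(bump, toy_nylon, sp, geom, "tie")
  cfg_ta1 <- retrieval_config("PT", "TA", geom, sp, toy_nylon,
                              n_energy_samples = 1)
  cfg_ea <- retrieval_config("PT", "EA", geom, sp, toy_nylon)
  expect_equal(unclass(retrieve_polychromatic(pairp, cfg_ta1)),
               unclass(retrieve_polychromatic(pairp, cfg_ea)),
               tolerance = 1e-12)
})

test_that("TA is linear in the per-energy maps and converges in n", {
  geom <- test_geometry()
  bump <- gaussian_bump_map(96, geom$object_pixel_mm, amplitude_mm = 0.5)
  sp <- make_synthetic_spectrum(50, 201)
  pair <- forward_polychromatic(bump, toy_nylon, sp, geom, "tie")
  rec <- function(n_ta)
    unclass(retrieve_polychromatic(
      pair, retrieval_config("PT", "TA", geom, sp, toy_nylon,
                             n_energy_samples = n_ta)))
  r101 <- rec(101)
  r51 <- rec(51)
  r25 <- rec(25)
  # energy-grid refinement converges: halving the step shrinks the change
  d1 <- max(abs(r101 - r51))
  d2 <- max(abs(r51 - r25))
  expect_lt(d1, d2)
  expect_lt(d1, 1e-4)
})
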