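# Shared fixtures. Everything is generated in code; the heavier end-to-end
# polychromatic experiment is computed once per test run and cached.

toy_nylon <- toy_material("nylon")
toy_sic <- toy_material("sic")

# two-line spectrum used across averaging tests
two_line_spectrum <- function(w1 = 1, w2 = 3) spectrum(c(10, 20), c(w1, w2))

# material with delta = c/E^2 and beta = b/E^2 for hand-computable averages
inverse_square_material <- function(c_delta = 1e-4, c_beta = 1e-7) {
  e <- seq(1, 60, length.out = 120)
  material_table(e, c_delta / e^2, c_beta / e^2, name = "invsq")
}

# a smooth, strictly interior Gaussian-bump thickness map
gaussian_bump_map <- function(n = 128, pixel_mm = 0.0135 / (4 / 3),
                              amplitude_mm = 0.5, sigma_frac = 0.08) {
  x <- (seq_len(n) - 0.5) * pixel_mm
  cx <- mean(x)
  sigma <- sigma_frac * n * pixel_mm
  g <- outer(x, x, function(y, x) exp(-((x - cx)^2 + (y - cx)^2) /
                                        (2 * sigma^2)))
  thickness_map(amplitude_mm * g, pixel_mm, material = "toy-nylon")
}

test_geometry <- function(odd_mm = 200, source_size_mm = 0.02)
  geometry(600, odd_mm, source_size_mm = source_size_mm)

# cache for the shared polychromatic twin experiment (acceptance tests)
.twin_cache <- new.env(parent = emptyenv())

twin_experiment <- function() {
  if (is.null(.twin_cache$result)) {
    plan <- experiment_plan(odds_mm = 200, grid_n = 512, n_ta = 101,
                            seed = 101)
    .twin_cache$result <- run_experiment(plan)
  }
  .twin_cache$result
}
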