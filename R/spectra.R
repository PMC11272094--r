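#' X-ray spectrum object
#'
#' A detected X-ray spectrum: a strictly increasing photon-energy grid (keV)
#' with nonnegative relative weights. Weights are treated as a sampled
#' continuous density D(E) (integrated with trapezoidal quadrature) unless the
#' spectrum is a single line.
#'
#' @param energies_kev Strictly increasing photon energies, keV.
#' @param weights Nonnegative relative weights, same length; at least one > 0.
#' @return A tibble of class `xray_spectrum` with columns `energy_kev`, `weight`.
#' @export
#' @examples
#' sp <- spectrum(c(10, 20), c(1, 3))
#' average_over_spectrum(sp$energy_kev, sp) # 17.5
spectrum <- function(energies_kev, weights) {
  energies_kev <- as.numeric(energies_kev)
  weights <- as.numeric(weights)
  if (length(energies_kev) < 1L) stop("spectrum needs at least one energy bin")
  if (length(weights) != length(energies_kev))
    stop("energies and weights differ in length")
  if (any(!is.finite(energies_kev)) || any(!is.finite(weights)))
    stop("non-finite values in spectrum")
  if (any(diff(energies_kev) <= 0)) stop("energies must be strictly increasing")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("invalid spectrum: all weights are zero")
  structure(tibble(energy_kev = energies_kev, weight = weights),
            class = c("xray_spectrum", class(tibble())))
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %d bins, %.3g-%.3g keV, mean %.3g keV\n",
              nrow(x), min(x$energy_kev), max(x$energy_kev),
              average_over_spectrum(x$energy_kev, x)))
  NextMethod()
}

# trapezoid bin widths for an increasing grid; a single bin gets weight 1
trapezoid_widths <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  c(diff(x)[1] / 2, (x[seq(3, length.out = n - 2)] - x[seq_len(n - 2)]) / 2,
    diff(x)[n - 1] / 2)
}

#' Spectrum-weighted average of a per-energy quantity
#'
#' Computes the detected-spectrum average of a quantity Q(E): the ratio of the
#' integrals of Q(E) D(E) and D(E) over the spectrum. The integral is evaluated
#' by trapezoidal quadrature on the stored energy grid (`quadrature =
#' "trapezoid"`, the default); `"discrete"` treats the bins as discrete
#' emission lines and takes a plain weighted mean. A single-bin spectrum is
#' always treated as a line.
#'
#' @param q Numeric vector of the quantity sampled on the spectrum's energy
#'   grid (same length), or a function of energy in keV.
#' @param spectrum An [spectrum()] object.
#' @param quadrature `"trapezoid"` or `"discrete"`.
#' @return A scalar.
#' @export
average_over_spectrum <- function(q, spectrum,
                                  quadrature = c("trapezoid", "discrete")) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (is.function(q)) q <- q(spectrum$energy_kev)
  if (length(q) != nrow(spectrum))
    stop("q and spectrum grid differ in length")
  if (all(spectrum$weight == 0)) stop("invalid spectrum: all weights are zero")
  w <- spectrum$weight
  if (quadrature == "trapezoid") w <- w * trapezoid_widths(spectrum$energy_kev)
  sum(q * w) / sum(w)
}

# Resample a spectrum onto n evenly spaced energy nodes spanning its support,
# depositing each bin's trapezoid mass onto the two neighbouring nodes by
# linear (hat-function) splitting. Conserves total weight and the mean energy
# of every emission line exactly, so downstream quadratures converge at the
# rate of the smooth per-energy integrand rather than of the spiky density.
# If the spectrum has <= n bins it is returned as-is (energies + mass
# weights), which keeps discrete-line spectra exact.
spectral_nodes <- function(spectrum, n) {
  mass <- spectrum$weight * trapezoid_widths(spectrum$energy_kev)
  if (nrow(spectrum) <= n || n < 2L) {
    keep <- mass > 0
    return(list(energies = spectrum$energy_kev[keep],
                weights = mass[keep] / sum(mass)))
  }
  rng <- range(spectrum$energy_kev)
  nodes <- seq(rng[1], rng[2], length.out = n)
  h <- diff(nodes)[1]
  pos <- (spectrum$energy_kev - rng[1]) / h
  j <- pmin(floor(pos), n - 2)
  frac <- pos - j
  w <- numeric(n)
  for (i in seq_along(mass)) {
    w[j[i] + 1] <- w[j[i] + 1] + mass[i] * (1 - frac[i])
    w[j[i] + 2] <- w[j[i] + 2] + mass[i] * frac[i]
  }
  keep <- w > 0
  list(energies = nodes[keep], weights = w[keep] / sum(w))
}

#' Material optical-constant table
#'
#' Tabulates the refractive-index decrement delta and absorption index beta of
#' n = 1 - delta + i beta on a strictly increasing energy grid. Queries between
#' grid points are interpolated log-log (exact for power laws); queries outside
#' the tabulated range are an error.
#'
#' @param energies_kev Strictly increasing energies, keV.
#' @param delta,beta Positive optical constants on that grid.
#' @param name Material label.
#' @return A tibble of class `material_table` with attribute `material`.
#' @export
material_table <- function(energies_kev, delta, beta, name = "material") {
  energies_kev <- as.numeric(energies_kev)
  if (any(diff(energies_kev) <= 0)) stop("energies must be strictly increasing")
  if (length(delta) != length(energies_kev) || length(beta) != length(energies_kev))
    stop("delta/beta and energy grid differ in length")
  if (any(delta <= 0) || any(beta <= 0)) stop("delta and beta must be positive")
  out <- tibble(energy_kev = energies_kev, delta = as.numeric(delta),
                beta = as.numeric(beta))
  attr(out, "material") <- name
  class(out) <- c("material_table", class(tibble()))
  out
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %s, %d rows, %.3g-%.3g keV\n",
              attr(x, "material"), nrow(x), min(x$energy_kev), max(x$energy_kev)))
  NextMethod()
}

#' Interpolate a material table
#'
#' Log-log linear interpolation of delta and beta at arbitrary energies inside
#' the tabulated range.
#'
#' @param material A [material_table()].
#' @param energies_kev Query energies, keV.
#' @return A tibble with columns `energy_kev`, `delta`, `beta`.
#' @export
interp_material <- function(material, energies_kev) {
  stopifnot(inherits(material, "material_table"))
  rng <- range(material$energy_kev)
  if (any(energies_kev < rng[1] | energies_kev > rng[2]))
    stop(sprintf("energy outside tabulated range [%.4g, %.4g] keV",
                 rng[1], rng[2]))
  le <- log(material$energy_kev)
  lq <- log(energies_kev)
  tibble(
    energy_kev = energies_kev,
    delta = exp(approx(le, log(material$delta), lq)$y),
    beta = exp(approx(le, log(material$beta), lq)$y)
  )
}

#' Reduced single-energy optical parameters
#'
#' Bundles the single-energy parameters a monochromatic retrieval consumes:
#' energy, delta, beta, and the derived gamma = delta/beta, wavelength and
#' mu = 4 pi beta / lambda.
#'
#' @param energy_kev Energy, keV.
#' @param delta,beta Optical constants at that energy.
#' @return A list of class `averaged_params` with fields `energy_kev`, `delta`,
#'   `beta`, `gamma`, `lambda_mm`, `mu_mm`.
#' @export
averaged_params <- function(energy_kev, delta, beta) {
  stopifnot(energy_kev > 0, delta > 0, beta > 0)
  lambda <- energy_to_wavelength(energy_kev)
  structure(list(energy_kev = energy_kev, delta = delta, beta = beta,
                 gamma = delta / beta, lambda_mm = lambda,
                 mu_mm = 4 * pi * beta / lambda),
            class = "averaged_params")
}

#' @export
print.averaged_params <- function(x, ...) {
  cat(sprintf(paste0("<averaged_params> E = %.4g keV, delta = %.4g, ",
                     "beta = %.4g, gamma = %.4g, mu = %.4g /mm\n"),
              x$energy_kev, x$delta, x$beta, x$gamma, x$mu_mm))
  invisible(x)
}

#' Mean-energy parameter reduction
#'
#' The conventional polychromatic strategy: compute the spectrum's mean energy
#' and evaluate the material's delta and beta at that single energy.
#'
#' @param spectrum An [spectrum()].
#' @param material A [material_table()] covering the mean energy.
#' @return An [averaged_params()] object.
#' @export
reduce_ea <- function(spectrum, material) {
  e_bar <- average_over_spectrum(spectrum$energy_kev, spectrum)
  ip <- interp_material(material, e_bar)
  averaged_params(e_bar, ip$delta, ip$beta)
}

#' Spectrum-averaged parameter reduction
#'
#' Averages energy, delta and beta each over the spectrum; gamma is the ratio
#' of the averaged delta and beta. For non-degenerate spectra and optical
#' constants decreasing in energy this yields larger delta and beta than
#' [reduce_ea()] (Jensen's inequality).
#'
#' @inheritParams reduce_ea
#' @return An [averaged_params()] object.
#' @export
reduce_pa <- function(spectrum, material) {
  ip <- interp_material(material, spectrum$energy_kev)
  averaged_params(
    average_over_spectrum(spectrum$energy_kev, spectrum),
    average_over_spectrum(ip$delta, spectrum),
    average_over_spectrum(ip$beta, spectrum)
  )
}

#' Beer-Lambert filtering of a spectrum
#'
#' Multiplies each weight by exp(-mu(E) * thickness) for an absorber of the
#' given material, emulating beam hardening by e.g. a diffuser screen. The
#' energy grid is unchanged.
#'
#' @param spectrum An [spectrum()].
#' @param material Absorber [material_table()] covering the spectrum support.
#' @param thickness_mm Absorber thickness, mm (>= 0).
#' @return A filtered [spectrum()].
#' @export
filter_spectrum <- function(spectrum, material, thickness_mm) {
  if (thickness_mm < 0) stop("thickness must be nonnegative")
  ip <- interp_material(material, spectrum$energy_kev)
  mu <- attenuation_coefficient(ip$beta, spectrum$energy_kev)
  spectrum(spectrum$energy_kev, spectrum$weight * exp(-mu * thickness_mm))
}

#' Synthetic 50 kV-class laboratory spectrum
#'
#' Builds a deterministic stand-in for the detected spectrum of a tungsten
#' microfocus source: a Kramers bremsstrahlung continuum, weight proportional
#' to (kvp - E)/E, optionally mixed with tungsten L fluorescence lines and
#' multiplied by an air-path Beer-Lambert filter and a thin-scintillator
#' absorption weight 1 - exp(-c (10/E)^3). With the defaults at `kvp = 50` the
#' detected mean energy is 10.3 keV and rises to 11.4 keV behind a 3-layer SiC
#' sandpaper diffuser, matching a 50 kV microfocus mammography-type bench.
#'
#' `n_bins = 1` returns a monochromatic line at the midpoint of the energy
#' range.
#'
#' @param kvp Tube voltage, kV (continuum endpoint, weight 0 there).
#' @param n_bins Number of energy bins (>= 1).
#' @param e_min Low-energy truncation, keV.
#' @param lines_frac Fraction of detected weight in the characteristic L lines
#'   (0 disables them).
#' @param air_path_mm Source-detector air path for the filtration term, mm.
#' @param scint_depth Scintillator absorption depth c = mu(10 keV) * thickness
#'   (dimensionless); larger means a thicker, harder-responding screen.
#' @param hardening Optional extra filter: a list `list(material =
#'   material_table, thickness_mm = x)` applied via [filter_spectrum()].
#' @return An [spectrum()].
#' @export
#' @examples
#' sp <- make_synthetic_spectrum(50, 1500)
#' average_over_spectrum(sp$energy_kev, sp) # ~10.3 keV
make_synthetic_spectrum <- function(kvp = 50, n_bins = 1500, e_min = 2,
                                    lines_frac = 0.3636, air_path_mm = 800,
                                    scint_depth = 0.5717, hardening = NULL) {
  if (kvp <= 0) stop("kvp must be positive")
  if (n_bins < 1) stop("n_bins must be at least 1")
  if (e_min <= 0 || e_min >= kvp) stop("e_min must lie in (0, kvp)")
  if (n_bins == 1L) {
    sp <- spectrum((e_min + kvp) / 2, 1)
  } else {
    e <- seq(e_min, kvp, length.out = n_bins)
    mu_air <- 6.17e-4 * (10 / e)^3            # 1/mm, air at ~sea level
    att <- exp(-mu_air * air_path_mm) * (1 - exp(-scint_depth * (10 / e)^3))
    tw <- trapezoid_widths(e)
    cont <- (kvp - e) / e * att
    w <- cont / sum(cont * tw)
    if (lines_frac > 0 && kvp > 12) {
      # tungsten L alpha / beta / gamma fluorescence
      ln <- (0.47 * dnorm(e, 8.40, 0.25) + 0.40 * dnorm(e, 9.67, 0.25) +
               0.13 * dnorm(e, 11.29, 0.25)) * att
      w <- (1 - lines_frac) * w + lines_frac * ln / sum(ln * tw)
    }
    sp <- spectrum(e, w)
  }
  if (!is.null(hardening))
    sp <- filter_spectrum(sp, hardening$material, hardening$thickness_mm)
  sp
}

#' Built-in toy power-law materials
#'
#' Small synthetic optical-constant tables for tests and simulations:
#' delta(E) = delta0 (E0/E)^2 (exact for solids far from edges) and
#' beta(E) = beta0 (E0/E)^p_beta with an in-band *effective* exponent. For the
#' light organic materials (nylon, PLA, HIPS) p_beta = 2, which tracks
#' tabulated values over 5-50 keV once Compton absorption is folded in; for
#' SiC, photoelectric absorption dominates throughout the band, so p_beta = 4
#' (mu ~ E^-3). Anchors at E0 = 10.3 keV; the nylon anchor is
#' delta = 2.3e-6, beta = 2.6e-9. These are labelled stand-ins, not tabulated
#' data; supply a measured [material_table()] for quantitative work on real
#' images.
#'
#' @param name One of `"nylon"`, `"sic"`, `"pla"`, `"hips"`.
#' @param energies_kev Tabulation grid, keV.
#' @return A [material_table()].
#' @export
toy_material <- function(name = c("nylon", "sic", "pla", "hips"),
                         energies_kev = exp(seq(log(1), log(60), length.out = 200))) {
  name <- match.arg(name)
  # anchors at E0 = 10.3 keV: delta0, beta0, beta exponent
  anchors <- list(
    nylon = c(delta0 = 2.3e-6, beta0 = 2.6e-9, p_beta = 2),
    sic   = c(delta0 = 6.2e-6, beta0 = 6.7e-8, p_beta = 4),
    pla   = c(delta0 = 2.65e-6, beta0 = 3.8e-9, p_beta = 2),
    hips  = c(delta0 = 2.2e-6, beta0 = 1.9e-9, p_beta = 2)
  )[[name]]
  power_law_material(paste0("toy-", name), e0 = 10.3,
                     delta0 = anchors[["delta0"]], beta0 = anchors[["beta0"]],
                     p_delta = 2, p_beta = anchors[["p_beta"]],
                     energies_kev = energies_kev)
}

#' Power-law material constructor
#'
#' Builds a [material_table()] from power-law scalings anchored at one energy:
#' delta = delta0 (e0/E)^p_delta, beta = beta0 (e0/E)^p_beta.
#'
#' @param name Label.
#' @param e0 Anchor energy, keV.
#' @param delta0,beta0 Values at `e0`.
#' @param p_delta,p_beta Power-law exponents.
#' @param energies_kev Tabulation grid.
#' @return A [material_table()].
#' @export
power_law_material <- function(name, e0, delta0, beta0, p_delta = 2, p_beta = 2,
                               energies_kev = exp(seq(log(1), log(60),
                                                      length.out = 200))) {
  material_table(energies_kev,
                 delta = delta0 * (e0 / energies_kev)^p_delta,
                 beta = beta0 * (e0 / energies_kev)^p_beta,
                 name = name)
}

#' Read / write spectrum CSV
#'
#' CSV with header `energy_keV,weight`, UTF-8, `.` decimal separator.
#'
#' @param path File path.
#' @return [read_spectrum()] returns an [spectrum()]; [write_spectrum()]
#'   returns `path` invisibly.
#' @export
#' @examples
#' f <- system.file("extdata", "spectrum_50kv_detected.csv",
#'                  package = "phasethick")
#' sp <- read_spectrum(f)
read_spectrum <- function(path) {
  d <- read.csv(path)
  if (!all(c("energy_keV", "weight") %in% names(d)))
    stop("spectrum CSV needs columns energy_keV, weight")
  spectrum(d$energy_keV, d$weight)
}

#' @param spectrum An [spectrum()].
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(data.frame(energy_keV = spectrum$energy_kev,
                       weight = spectrum$weight),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write material table CSV
#'
#' CSV with header `energy_keV,delta,beta`.
#'
#' @param path File path.
#' @param name Material label for the returned table.
#' @return [read_material_table()] returns a [material_table()].
#' @export
read_material_table <- function(path, name = basename(path)) {
  d <- read.csv(path)
  if (!all(c("energy_keV", "delta", "beta") %in% names(d)))
    stop("material CSV needs columns energy_keV, delta, beta")
  material_table(d$energy_keV, d$delta, d$beta, name = name)
}

#' @param material A [material_table()].
#' @rdname read_material_table
#' @export
write_material_table <- function(material, path) {
  write.csv(data.frame(energy_keV = material$energy_kev,
                       delta = material$delta, beta = material$beta),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
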