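#' Single-material near-field low-pass filter
#'
#' The Fourier-space deconvolution at the heart of single-shot thickness
#' retrieval: the transform of the flat-corrected image is divided by
#' 1 + pi lambda (gamma z / M - k s^2) |nu|^2 and transformed back. `nu` is
#' spatial frequency in cycles/mm on the object-plane grid; k = 2 pi / lambda;
#' z is the ODD. Denominator values below `eps` are clamped (and counted in
#' the result's `clamped_freqs` attribute), which can occur at high
#' frequencies when the source term k s^2 exceeds gamma z / M.
#'
#' @param ratio Flat-corrected intensity matrix (I / I_R).
#' @param lambda_mm Wavelength, mm.
#' @param gamma delta / beta of the assumed material.
#' @param geometry An [geometry()] (supplies z, M, s and the object pixel).
#' @param eps Denominator floor (> 0).
#' @return Filtered matrix with attribute `clamped_freqs`.
#' @export
paganin_filter <- function(ratio, lambda_mm, gamma, geometry, eps = 1e-6) {
  stopifnot(eps > 0)
  nr <- nrow(ratio); nc <- ncol(ratio)
  pixel <- geometry$object_pixel_mm
  nu2 <- freq_sq_grid(2 * nr, 2 * nc, pixel)
  k <- 2 * pi / lambda_mm
  den <- 1 + pi * lambda_mm *
    (gamma * geometry$odd_mm / geometry$magnification -
       k * geometry$source_size_mm^2) * nu2
  n_clamped <- sum(den < eps)
  out <- filtered_transform(ratio, 1 / pmax(den, eps))
  attr(out, "clamped_freqs") <- n_clamped
  out
}

# shared log step with clamping report
clamped_log <- function(x, floor = 1e-12) {
  n_bad <- sum(x < floor)
  out <- log(pmax(x, floor))
  attr(out, "clamped_pixels") <- n_bad
  out
}

#' Paganin single-material thickness retrieval
#'
#' Recovers projected thickness from one flat-corrected near-field image of a
#' single-material object: T = -(1/mu) log F^-1 \[ F(I/I_R) / (1 + pi lambda
#' (gamma z/M - k s^2) |nu|^2) \]. Nonpositive filtered values are clamped
#' before the logarithm and counted.
#'
#' @param pair An [image_pair()].
#' @param params An [averaged_params()] (single-energy optical parameters).
#' @param eps Denominator floor for the filter.
#' @return A [thickness_map()] on the object-plane grid with attributes
#'   `clamped_freqs` and `clamped_pixels`.
#' @export
retrieve_pt <- function(pair, params, eps = 1e-6) {
  ratio <- pair$sample / pair$reference
  filt <- paganin_filter(ratio, params$lambda_mm, params$gamma,
                         pair$geometry, eps)
  lg <- clamped_log(filt)
  # thickness may legitimately go slightly negative in noise; keep raw values
  structure(-lg / params$mu_mm,
                   pixel_mm = pair$geometry$object_pixel_mm,
                   material = "retrieved",
                   class = c("thickness_map", "matrix", "array"),
                   clamped_freqs = attr(filt, "clamped_freqs"),
                   clamped_pixels = attr(lg, "clamped_pixels"))
}

#' Weak-absorption linearised thickness retrieval
#'
#' The small-thickness/weak-absorption approximation of [retrieve_pt()]:
#' T = (1/mu) F^-1 \[ F(1 - I/I_R) / (1 + pi lambda (gamma z/M - k s^2)
#' |nu|^2) \]. No logarithm is taken, so strong absorbers are systematically
#' underestimated: a uniform slab returns (1 - exp(-mu T0))/mu.
#'
#' @inheritParams retrieve_pt
#' @return A [thickness_map()].
#' @export
retrieve_at <- function(pair, params, eps = 1e-6) {
  ratio <- pair$sample / pair$reference
  filt <- paganin_filter(1 - ratio, params$lambda_mm, params$gamma,
                         pair$geometry, eps)
  structure(filt / params$mu_mm,
            pixel_mm = pair$geometry$object_pixel_mm, material = "retrieved",
            class = c("thickness_map", "matrix", "array"),
            clamped_freqs = attr(filt, "clamped_freqs"))
}

#' Speckle-referenced thickness retrieval
#'
#' Single-shot speckle-based retrieval: the identical operator to
#' [retrieve_pt()] applied to the ratio of the sample image (sample +
#' diffuser) and the reference image (diffuser alone). The caller is
#' responsible for supplying optical parameters reduced on the
#' diffuser-hardened spectrum (see [filter_spectrum()]).
#'
#' @param sample Intensity matrix with sample and diffuser.
#' @param reference Intensity matrix with the diffuser only.
#' @param geometry An [geometry()].
#' @inheritParams retrieve_pt
#' @return A [thickness_map()].
#' @export
retrieve_st <- function(sample, reference, geometry, params, eps = 1e-6) {
  retrieve_pt(image_pair(sample, reference, geometry), params, eps)
}

#' Two-material thickness retrieval
#'
#' Multi-material extension of the Paganin operator for a sample made of two
#' materials with known total projected thickness A = T1 + T2:
#' T2 = -(1/Dmu) log F^-1 \[ F( I_S / (I_R exp(-mu1 A)) ) / (1 + pi lambda
#' (Dgamma z/M - k s^2) |nu|^2) \] with Dmu = mu2 - mu1 and
#' Dgamma = (delta2 - delta1)/(beta2 - beta1). Returns T2 and T1 = A - T2,
#' both clipped to \[0, A\] with a clipped-pixel count.
#'
#' @param pair An [image_pair()].
#' @param total_map Total-thickness raster A (matrix or [thickness_map()]).
#' @param params1,params2 [averaged_params()] for materials 1 and 2 at a
#'   common energy.
#' @param eps Denominator floor.
#' @return A list of class `two_material_map` with `t1`, `t2`, `total_mm`
#'   (the mean of A), plus attribute `clipped_pixels`.
#' @export
retrieve_mpt <- function(pair, total_map, params1, params2, eps = 1e-6) {
  if (!all(dim(total_map) == dim(pair$sample)))
    stop("total-thickness map does not match the image grid")
  if (abs(params1$energy_kev - params2$energy_kev) > 1e-9)
    stop("material parameters must be reduced at a common energy")
  dbeta <- params2$beta - params1$beta
  if (abs(dbeta) < .Machine$double.eps)
    stop("degenerate contrast: beta2 == beta1")
  dmu <- params2$mu_mm - params1$mu_mm
  dgamma <- (params2$delta - params1$delta) / dbeta
  a <- unclass(total_map)
  ratio <- pair$sample / (pair$reference * exp(-params1$mu_mm * a))
  filt <- paganin_filter(ratio, params2$lambda_mm, dgamma, pair$geometry, eps)
  lg <- clamped_log(filt)
  t2 <- -lg / dmu
  n_clip <- sum(t2 < 0 | t2 > a)
  t2 <- pmin(pmax(t2, 0), a)
  pixel <- pair$geometry$object_pixel_mm
  structure(list(t1 = thickness_map(a - t2, pixel, material = "material-1"),
                 t2 = thickness_map(t2, pixel, material = "material-2"),
                 total_mm = mean(a), pixel_mm = pixel,
                 materials = c("material-1", "material-2")),
            class = "two_material_map", clipped_pixels = n_clip,
            clamped_pixels = attr(lg, "clamped_pixels"))
}

#' Retrieval configuration
#'
#' Bundles everything one polychromatic retrieval needs: the technique (PT,
#' AT, ST or MPT), the spectrum-handling strategy (EA: mean-energy
#' parameters; PA: spectrum-averaged parameters; TA: per-energy retrieval and
#' thickness averaging), the number of TA energy samples (evenly spaced over
#' the spectrum support; 1500 reproduces the reference analysis, smaller
#' values converge quickly), geometry, spectrum and material(s).
#'
#' @param technique `"PT"`, `"AT"`, `"ST"` or `"MPT"`.
#' @param averaging `"EA"`, `"PA"` or `"TA"`.
#' @param geometry An [geometry()].
#' @param spectrum An [spectrum()]. For ST pass the diffuser-hardened
#'   spectrum.
#' @param material A [material_table()] (PT/AT/ST) or list of two (MPT).
#' @param n_energy_samples TA sample count (>= 1).
#' @param total_map Total-thickness raster, required for MPT.
#' @param eps Denominator floor.
#' @return A list of class `retrieval_config`.
#' @export
retrieval_config <- function(technique = c("PT", "AT", "ST", "MPT"),
                             averaging = c("TA", "EA", "PA"),
                             geometry, spectrum, material,
                             n_energy_samples = 1500, total_map = NULL,
                             eps = 1e-6) {
  technique <- match.arg(technique)
  averaging <- match.arg(averaging)
  if (n_energy_samples < 1) stop("n_energy_samples must be at least 1")
  if (eps <= 0) stop("eps must be positive")
  if (technique == "MPT") {
    if (!is.list(material) || length(material) != 2)
      stop("MPT needs a list of two material tables")
    if (is.null(total_map)) stop("MPT needs the total-thickness map")
  }
  structure(list(technique = technique, averaging = averaging,
                 geometry = geometry, spectrum = spectrum, material = material,
                 n_energy_samples = n_energy_samples, total_map = total_map,
                 eps = eps),
            class = "retrieval_config")
}

# single retrieval at fixed single-energy parameters
retrieve_mono <- function(pair, config, params, params2 = NULL) {
  switch(config$technique,
    PT = retrieve_pt(pair, params, config$eps),
    AT = retrieve_at(pair, params, config$eps),
    ST = retrieve_pt(pair, params, config$eps),
    MPT = retrieve_mpt(pair, config$total_map, params, params2, config$eps)
  )
}

reduce_at_energy <- function(material, energy_kev) {
  ip <- interp_material(material, energy_kev)
  averaged_params(energy_kev, ip$delta, ip$beta)
}

#' Polychromatic thickness retrieval
#'
#' Applies the configured technique with the configured spectrum strategy.
#' EA/PA perform one retrieval with [reduce_ea()] / [reduce_pa()] parameters.
#' TA performs `n_energy_samples` retrievals at energies evenly spaced over
#' the spectrum support and averages the thickness maps pixelwise with the
#' interpolated spectral weights (a single TA sample falls back to the mean
#' energy, i.e. EA). For a monochromatic spectrum all three strategies
#' coincide.
#'
#' @param pair An [image_pair()]. For ST this is the (sample+diffuser,
#'   diffuser-only) pair.
#' @param config A [retrieval_config()].
#' @return A [thickness_map()] (or `two_material_map` for MPT).
#' @export
retrieve_polychromatic <- function(pair, config) {
  stopifnot(inherits(config, "retrieval_config"))
  sp <- config$spectrum
  two_mat <- config$technique == "MPT"
  reduce1 <- function(fn) if (two_mat)
    list(fn(sp, config$material[[1]]), fn(sp, config$material[[2]])) else
      list(fn(sp, config$material), NULL)
  if (config$averaging == "EA") {
    p <- reduce1(reduce_ea)
    return(retrieve_mono(pair, config, p[[1]], p[[2]]))
  }
  if (config$averaging == "PA") {
    p <- reduce1(reduce_pa)
    return(retrieve_mono(pair, config, p[[1]], p[[2]]))
  }
  # TA
  n <- config$n_energy_samples
  rng <- range(sp$energy_kev)
  if (n == 1L || diff(rng) == 0) {
    p <- reduce1(reduce_ea)
    return(retrieve_mono(pair, config, p[[1]], p[[2]]))
  }
  nodes <- spectral_nodes(sp, n)
  energies <- nodes$energies
  tw <- nodes$weights
  acc <- NULL
  for (i in seq_along(energies)) {
    if (two_mat) {
      p1 <- reduce_at_energy(config$material[[1]], energies[i])
      p2 <- reduce_at_energy(config$material[[2]], energies[i])
      r <- retrieve_mono(pair, config, p1, p2)
      acc <- if (is.null(acc)) tw[i] * unclass(r$t2) else
        acc + tw[i] * unclass(r$t2)
    } else {
      p <- reduce_at_energy(config$material, energies[i])
      r <- retrieve_mono(pair, config, p)
      acc <- if (is.null(acc)) tw[i] * unclass(r) else acc + tw[i] * unclass(r)
    }
  }
  pixel <- config$geometry$object_pixel_mm
  if (two_mat) {
    a <- unclass(config$total_map)
    t2 <- pmin(pmax(acc, 0), a)
    structure(list(t1 = thickness_map(a - t2, pixel, "material-1"),
                   t2 = thickness_map(t2, pixel, "material-2"),
                   total_mm = mean(a), pixel_mm = pixel,
                   materials = c("material-1", "material-2")),
              class = "two_material_map")
  } else {
    structure(acc, pixel_mm = pixel, material = "retrieved",
              class = c("thickness_map", "matrix", "array"))
  }
}
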