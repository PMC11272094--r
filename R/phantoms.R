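#' Projected-thickness map
#'
#' A 2D raster of projected thickness in mm on an object-plane grid. Matrices
#' are indexed `[row, col]` = `[y, x]`; `pixel_mm` is the object-plane
#' sampling. Two-material maps carry a second raster (see
#' [two_material_plate()]).
#'
#' @param values Numeric matrix, thickness in mm, all >= 0.
#' @param pixel_mm Object-plane pixel size, mm.
#' @param material Material label.
#' @return A `thickness_map` object (matrix with attributes).
#' @export
thickness_map <- function(values, pixel_mm, material = "material") {
  stopifnot(is.matrix(values), pixel_mm > 0)
  if (any(values < -1e-12)) stop("thickness values must be nonnegative")
  structure(values, pixel_mm = pixel_mm, material = material,
            class = c("thickness_map", "matrix", "array"))
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s, %d x %d px @ %.4g mm, range [%.4g, %.4g] mm\n",
              attr(x, "material"), nrow(x), ncol(x), attr(x, "pixel_mm"),
              min(x), max(x)))
  invisible(x)
}

# x coordinates (mm) of pixel centres along columns
map_x <- function(n, pixel_mm) (seq_len(n) - 0.5) * pixel_mm

#' Projected thickness of a cylindrical fiber
#'
#' A solid cylinder of diameter d with its axis along y projects to the
#' semicircular chord profile T(x) = d sqrt(1 - 4((x - x0)/d)^2) inside
#' |x - x0| <= d/2 and 0 outside, constant along the fiber axis.
#'
#' @param diameter_mm Fiber diameter d, mm (> 0).
#' @param center_x_mm Fiber centre x0, mm from the left edge of the grid.
#' @param n Raster size, `c(ny, nx)` pixels.
#' @param pixel_mm Object-plane pixel, mm.
#' @return A [thickness_map()].
#' @export
fiber_projection <- function(diameter_mm, center_x_mm, n = c(512, 512),
                             pixel_mm = 0.0135 / (4 / 3)) {
  if (diameter_mm <= 0) stop("diameter must be positive")
  x <- map_x(n[2], pixel_mm)
  if (center_x_mm - diameter_mm / 2 < 0 ||
      center_x_mm + diameter_mm / 2 > n[2] * pixel_mm)
    stop("fiber does not fit in the grid")
  u <- (x - center_x_mm) / diameter_mm
  prof <- ifelse(abs(u) <= 0.5, diameter_mm * sqrt(pmax(0, 1 - 4 * u^2)), 0)
  thickness_map(matrix(prof, nrow = n[1], ncol = n[2], byrow = TRUE),
                pixel_mm, material = "fiber")
}

#' Three-fiber test phantom
#'
#' Superposition of three non-overlapping cylindrical fibers with nominal
#' diameters 1.02, 0.81 and 0.71 mm (configurable), axes along y. The nominal
#' diameter ratios are d2/d1 = 0.79 and d3/d1 = 0.70.
#'
#' @param n Raster size `c(ny, nx)`.
#' @param pixel_mm Object-plane pixel, mm.
#' @param diameters_mm Three fiber diameters, mm.
#' @param centers_frac Fiber centres as fractions of the grid width.
#' @return A [thickness_map()] with attributes `diameters_mm`, `centers_mm`.
#' @export
three_fiber_phantom <- function(n = c(512, 512), pixel_mm = 0.0135 / (4 / 3),
                                diameters_mm = c(1.02, 0.81, 0.71),
                                centers_frac = c(0.25, 0.52, 0.78)) {
  stopifnot(length(diameters_mm) == 3, length(centers_frac) == 3)
  width <- n[2] * pixel_mm
  centers <- centers_frac * width
  edges <- cbind(centers - diameters_mm / 2, centers + diameters_mm / 2)
  ord <- order(centers)
  if (any(edges[ord, 1][-1] < edges[ord, 2][-3]))
    stop("fibers overlap; adjust centers or diameters")
  maps <- purrr::map2(diameters_mm, centers,
                      ~ fiber_projection(.x, .y, n, pixel_mm))
  out <- thickness_map(Reduce(`+`, maps), pixel_mm, material = "fiber")
  attr(out, "diameters_mm") <- diameters_mm
  attr(out, "centers_mm") <- centers
  out
}

#' Two-material plate phantom
#'
#' A plate of constant total projected thickness A split pointwise between two
#' materials: T1 + T2 = A exactly at every pixel. The material-2 fraction is a
#' smooth, blob-like random field: a Gaussian random field smoothed to the
#' requested correlation length is squashed through a logistic so the spatial
#' mean of T2/A approximates `vol_frac`. Deterministic for a fixed seed.
#'
#' @param n Raster size `c(ny, nx)`.
#' @param pixel_mm Object-plane pixel, mm.
#' @param total_mm Total plate thickness A, mm (> 0).
#' @param vol_frac Target material-2 volume fraction in (0, 1); 0 gives
#'   T2 == 0.
#' @param corr_mm Blob correlation length, mm.
#' @param softness Logistic squashing width in field standard deviations;
#'   smaller gives sharper blob boundaries.
#' @param seed Integer seed.
#' @param materials Length-2 character vector of labels (material 1, 2).
#' @return A list of class `two_material_map` with [thickness_map()]s `t1`,
#'   `t2` and fields `total_mm`, `pixel_mm`, `materials`.
#' @export
two_material_plate <- function(n = c(512, 512), pixel_mm = 0.0135 / (4 / 3),
                               total_mm = 10, vol_frac = 0.4, corr_mm = 0.5,
                               softness = 0.4, seed = 1,
                               materials = c("toy-hips", "toy-pla")) {
  if (total_mm <= 0) stop("total thickness must be positive")
  if (vol_frac < 0 || vol_frac >= 1) stop("volume fraction must be in [0, 1)")
  g <- with_local_seed(seed, {
    noise <- matrix(rnorm(prod(n)), n[1], n[2])
    smooth_random_field(noise, corr_mm / 1.665, pixel_mm)
  })
  g <- (g - mean(g)) / sd(g)
  frac2 <- if (vol_frac == 0) matrix(0, n[1], n[2]) else
    stats::plogis((g - stats::qnorm(1 - vol_frac)) / softness)
  t2 <- thickness_map(total_mm * frac2, pixel_mm, material = materials[2])
  t1 <- thickness_map(total_mm - total_mm * frac2, pixel_mm,
                      material = materials[1])
  structure(list(t1 = t1, t2 = t2, total_mm = total_mm, pixel_mm = pixel_mm,
                 materials = materials),
            class = "two_material_map")
}

#' @export
print.two_material_map <- function(x, ...) {
  cat(sprintf(paste0("<two_material_map> %s + %s, %d x %d px, A = %g mm, ",
                     "mean T2/A = %.3f\n"),
              x$materials[1], x$materials[2], nrow(x$t2), ncol(x$t2),
              x$total_mm, mean(x$t2) / x$total_mm))
  invisible(x)
}

# Gaussian-smooth a white-noise matrix to correlation scale sigma (mm)
smooth_random_field <- function(noise, sigma_mm, pixel_mm) {
  # periodic smoothing is fine here: the field is statistical, not an image
  nu2 <- freq_sq_grid(nrow(noise), ncol(noise), pixel_mm)
  Re(ifft2(fft2(noise) * exp(-2 * pi^2 * sigma_mm^2 * nu2)))
}

#' Sandpaper diffuser screen
#'
#' A random projected-thickness screen emulating stacked sheets of SiC
#' sandpaper: each layer is a clipped Gaussian random field smoothed to a
#' correlation length of about one particle size, linearly rescaled to a mean
#' thickness of one particle size; layers are independent and add. The
#' default roughness is calibrated so a 3-layer screen produces ~12% speckle
#' visibility in the simulated near field (see [speckle_visibility()]).
#'
#' @param n Raster size `c(ny, nx)`.
#' @param pixel_mm Object-plane pixel, mm.
#' @param particle_mm Mean grit particle size, mm (P1000 sandpaper: ~0.018).
#' @param n_layers Number of stacked sheets (>= 1).
#' @param roughness Relative thickness fluctuation per layer (std/mean before
#'   clipping).
#' @param seed Integer seed.
#' @return A list of class `diffuser_screen` with the thickness raster
#'   (`thickness`, a [thickness_map()]), `material`, `n_layers`, `particle_mm`.
#' @export
make_diffuser <- function(n = c(512, 512), pixel_mm = 0.0135 / (4 / 3),
                          particle_mm = 0.018, n_layers = 3, roughness = 0.55,
                          seed = 1) {
  if (particle_mm <= 0) stop("particle size must be positive")
  if (n_layers < 1) stop("need at least one layer")
  total <- with_local_seed(seed, {
    layers <- purrr::map(seq_len(n_layers), function(i) {
      g <- smooth_random_field(matrix(rnorm(prod(n)), n[1], n[2]),
                               particle_mm / 1.665, pixel_mm)
      g <- (g - mean(g)) / sd(g)
      layer <- pmax(1 + roughness * g, 0)  # pmax keeps the matrix shape
      layer * (particle_mm / mean(layer))
    })
    Reduce(`+`, layers)
  })
  structure(list(thickness = thickness_map(total, pixel_mm,
                                           material = "toy-sic"),
                 material = "toy-sic", n_layers = n_layers,
                 particle_mm = particle_mm),
            class = "diffuser_screen")
}

#' @export
print.diffuser_screen <- function(x, ...) {
  cat(sprintf("<diffuser_screen> %s, %d layers of %.3g mm grit, mean %.3g mm\n",
              x$material, x$n_layers, x$particle_mm, mean(x$thickness)))
  invisible(x)
}
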