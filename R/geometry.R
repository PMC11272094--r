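#' Cone-beam acquisition geometry
#'
#' Source-object distance (SOD), object-detector distance (ODD), source size
#' and detector pixel, all in mm. The geometric magnification
#' M = (SOD + ODD)/SOD is derived, as are the effective parallel-beam
#' propagation distance ODD/M and the object-plane pixel (detector pixel / M)
#' used by both the simulator and the retrieval filters.
#'
#' @param sod_mm Source-object distance, mm (> 0).
#' @param odd_mm Object-detector distance, mm (>= 0).
#' @param source_size_mm Source size s, mm (>= 0).
#' @param detector_pixel_mm Detector pixel pitch, mm.
#' @return A list of class `xpci_geometry`.
#' @export
#' @examples
#' g <- geometry(600, 200)
#' g$magnification # 1.33
geometry <- function(sod_mm, odd_mm, source_size_mm = 0.02,
                     detector_pixel_mm = 0.0135) {
  if (sod_mm <= 0) stop("sod must be positive")
  if (odd_mm < 0) stop("odd must be nonnegative")
  if (source_size_mm < 0) stop("source size must be nonnegative")
  if (detector_pixel_mm <= 0) stop("detector pixel must be positive")
  m <- magnification(sod_mm, odd_mm)
  structure(list(sod_mm = sod_mm, odd_mm = odd_mm,
                 source_size_mm = source_size_mm,
                 detector_pixel_mm = detector_pixel_mm,
                 magnification = m,
                 effective_distance_mm = odd_mm / m,
                 object_pixel_mm = detector_pixel_mm / m),
            class = "xpci_geometry")
}

#' @export
print.xpci_geometry <- function(x, ...) {
  cat(sprintf(paste0("<xpci_geometry> SOD %g mm, ODD %g mm, M = %.3f, ",
                     "s = %g mm, pixel %g mm (object %g mm)\n"),
              x$sod_mm, x$odd_mm, x$magnification, x$source_size_mm,
              x$detector_pixel_mm, x$object_pixel_mm))
  invisible(x)
}

#' Geometric magnification
#'
#' M = (SOD + ODD) / SOD for a point-projection cone beam.
#'
#' @param sod_mm Source-object distance, mm (> 0).
#' @param odd_mm Object-detector distance, mm.
#' @return Dimensionless magnification.
#' @export
#' @examples
#' round(magnification(600, 200), 2) # 1.33
magnification <- function(sod_mm, odd_mm) {
  if (any(sod_mm <= 0)) stop("sod must be positive")
  (sod_mm + odd_mm) / sod_mm
}

#' Fresnel number of the projection approximation
#'
#' NF = a^2 / (lambda d) for resolution limit a, wavelength lambda and sample
#' thickness d (all in the same length unit). The projection approximation
#' (sample as a single thin phase/amplitude screen) is conventionally taken as
#' valid for NF > 10.
#'
#' @param resolution_mm System resolution limit a, mm.
#' @param wavelength_mm Wavelength, mm.
#' @param thickness_mm Sample thickness d, mm.
#' @return A list with `nf` and logical `valid` (NF > 10).
#' @export
#' @examples
#' fresnel_number(5e-4, 1e-7, 10)$nf # 25
fresnel_number <- function(resolution_mm, wavelength_mm, thickness_mm) {
  if (any(c(resolution_mm, wavelength_mm, thickness_mm) <= 0))
    stop("all Fresnel-number inputs must be positive")
  nf <- resolution_mm^2 / (wavelength_mm * thickness_mm)
  list(nf = nf, valid = nf > 10)
}
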