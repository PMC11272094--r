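#' Write / read a thickness map as TIFF + JSON sidecar
#'
#' The raster is stored as a 32-bit float TIFF scaled to \[0, 1\]; the sidecar
#' JSON (`<path>.json`) records the scale factor, pixel size, units and
#' material label, so the pair round-trips to single precision.
#'
#' @param map A [thickness_map()].
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar (provenance).
#' @return `path`, invisibly.
#' @export
write_thickness_tiff <- function(map, path, extra = NULL) {
  m <- unclass(map)
  scale <- max(m, 1e-300)
  tiff::writeTIFF(pmin(pmax(m / scale, 0), 1), path, bits.per.sample = 32L)
  meta <- c(list(scale = scale, pixel_mm = attr(map, "pixel_mm"),
                 units = "mm", material = attr(map, "material")),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thickness_tiff
#' @export
read_thickness_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  thickness_map(m, meta$pixel_mm, material = meta$material %||% "material")
}

#' Write / read an image pair as two TIFFs + JSON sidecar
#'
#' Writes `<stem>_sample.tif`, `<stem>_reference.tif` (32-bit float, scaled)
#' and `<stem>.json` holding the scales, geometry and any provenance passed
#' in `extra` (e.g. seed, mode, spectrum hash).
#'
#' @param pair An [image_pair()].
#' @param stem Path stem (no extension).
#' @param extra Optional named list of provenance fields.
#' @return `stem`, invisibly.
#' @export
write_image_pair <- function(pair, stem, extra = NULL) {
  ssc <- max(pair$sample, 1e-300)
  rsc <- max(pair$reference, 1e-300)
  tiff::writeTIFF(pmin(pmax(pair$sample / ssc, 0), 1),
                  paste0(stem, "_sample.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(pmin(pmax(pair$reference / rsc, 0), 1),
                  paste0(stem, "_reference.tif"), bits.per.sample = 32L)
  g <- pair$geometry
  meta <- c(list(sample_scale = ssc, reference_scale = rsc,
                 sod_mm = g$sod_mm, odd_mm = g$odd_mm,
                 source_size_mm = g$source_size_mm,
                 detector_pixel_mm = g$detector_pixel_mm), extra)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  g <- geometry(meta$sod_mm, meta$odd_mm, meta$source_size_mm,
                meta$detector_pixel_mm)
  image_pair(tiff::readTIFF(paste0(stem, "_sample.tif")) * meta$sample_scale,
             tiff::readTIFF(paste0(stem, "_reference.tif")) *
               meta$reference_scale,
             g)
}
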