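#' Read and write attenuation images
#'
#' Images persist as 32-bit float TIFF holding attenuation in 1/cm, plus a
#' YAML sidecar (`<file>.yaml`) with the pixel size (mm) and the water
#' attenuation used for HU conversion.
#'
#' @param img an [AttenuationImage-class].
#' @param path TIFF file path.
#' @param muWater recorded in the sidecar for provenance.
#' @return `writeAttenuationImage` returns `path` invisibly;
#'   `readAttenuationImage` returns the [AttenuationImage-class].
#' @export
writeAttenuationImage <- function(img, path, muWater = 0.2) {
  stopifnot(is(img, "AttenuationImage"))
  sc <- .tiffScale(img@values)
  tiff::writeTIFF((img@values - sc$offset) / sc$scale, path,
                  bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(pixel_size_mm = img@pixelSize,
                        mu_water_per_cm = muWater,
                        unit = "1/cm",
                        offset = sc$offset, scale = sc$scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

# the float TIFF writer stores [0, 1]; keep an affine map in the sidecar
.tiffScale <- function(vals) {
  offset <- min(vals)
  scale <- max(vals) - offset
  if (scale <= 0) scale <- 1
  list(offset = offset, scale = scale)
}

#' @rdname writeAttenuationImage
#' @export
readAttenuationImage <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  vals <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  attenuationImage(vals * meta$scale + meta$offset, meta$pixel_size_mm)
}

#' Read and write sinograms
#'
#' Sinograms persist as 32-bit float TIFF (views x detector) plus a YAML
#' sidecar holding the full fan-beam geometry (lengths mm, angles degrees).
#'
#' @param sino a [Sinogram-class].
#' @param path TIFF file path.
#' @return `writeSinogram` returns `path` invisibly; `readSinogram` the
#'   [Sinogram-class].
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  g <- geometry(sino)
  sc <- .tiffScale(sino@values)
  tiff::writeTIFF((sino@values - sc$offset) / sc$scale, path,
                  bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(
    source_to_iso_mm = g@sourceToIso, iso_to_detector_mm = g@isoToDetector,
    detector_pitch_mm = g@detectorPitch, n_detector = g@nDetector,
    n_views = g@nViews, angular_range_deg = g@angularRange,
    initial_angle_deg = g@initialAngle, detector_offset_mm = g@detectorOffset,
    iso_offset_mm = g@isoOffset, offset = sc$offset, scale = sc$scale),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  m <- yaml::read_yaml(paste0(path, ".yaml"))
  vals <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  g <- fanBeamGeometry(m$source_to_iso_mm, m$iso_to_detector_mm,
                       m$detector_pitch_mm, m$n_detector, m$n_views,
                       m$angular_range_deg, m$initial_angle_deg,
                       m$detector_offset_mm)
  g@isoOffset <- m$iso_offset_mm
  new("Sinogram", values = vals * m$scale + m$offset, geometry = g)
}

#' Windowed 16-bit PNG preview
#'
#' Exports an image with a declared display window: values at or below
#' `window[1]` map to black, at or above `window[2]` to white.
#'
#' @param img an [AttenuationImage-class] (or matrix).
#' @param path PNG file path.
#' @param window display window in the image units, default the data range.
#' @return `path`, invisibly.
#' @export
writePreviewPNG <- function(img, path, window = NULL) {
  vals <- .asMatrix(img)
  if (is.null(window)) window <- range(vals)
  if (diff(window) <= 0) window <- window + c(0, 1)
  scaled <- (vals - window[1]) / diff(window)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  png::writePNG(scaled, path, dpi = 300)
  invisible(path)
}

# read a geometry block from a config list
.geometryFromConfig <- function(cfg) {
  fanBeamGeometry(cfg$source_to_iso_mm, cfg$iso_to_detector_mm,
                  cfg$detector_pitch_mm, cfg$n_detector, cfg$n_views,
                  angularRange = cfg$angular_range_deg %||% 360,
                  initialAngle = cfg$initial_angle_deg %||% 0,
                  detectorOffset = cfg$detector_offset_mm %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
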