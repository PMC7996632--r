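#' @name interiorCT-accessors
#' @title Accessors for interiorCT objects
#' @description Slot accessors for the core classes: raw array values,
#'   pixel size, sinogram geometry and detector layout.
#' @param object an interiorCT object.
#' @return the corresponding slot value.
NULL

#' @rdname interiorCT-accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("nViews", function(object) standardGeneric("nViews"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("nDetector", function(object) standardGeneric("nDetector"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("detectorPitch", function(object) standardGeneric("detectorPitch"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("sourceToDetector",
           function(object) standardGeneric("sourceToDetector"))

#' Geometric magnification factors
#'
#' @param geom a [FanBeamGeometry-class].
#' @return named numeric vector with the detector magnification `M = c/a`
#'   and the focal-spot magnification `Mprime = c/b`.
#' @export
setGeneric("magnifications", function(geom) standardGeneric("magnifications"))

#' Apply misalignment parameters to a geometry
#'
#' @param geom a [FanBeamGeometry-class].
#' @param mis a [MisalignmentParams-class].
#' @return the perturbed (assumed) [FanBeamGeometry-class].
#' @export
setGeneric("applyMisalignment",
           function(geom, mis) standardGeneric("applyMisalignment"))

#' @rdname interiorCT-accessors
#' @export
setGeneric("effectivePixel", function(object) standardGeneric("effectivePixel"))

## ---- methods -------------------------------------------------------------

#' @rdname interiorCT-accessors
setMethod("values", "AttenuationImage", function(object) object@values)

#' @rdname interiorCT-accessors
setMethod("values", "Sinogram", function(object) object@values)

#' @rdname interiorCT-accessors
setMethod("pixelSize", "AttenuationImage", function(object) object@pixelSize)

#' @rdname interiorCT-accessors
setMethod("geometry", "Sinogram", function(object) object@geometry)

#' @rdname interiorCT-accessors
setMethod("nViews", "FanBeamGeometry", function(object) object@nViews)

#' @rdname interiorCT-accessors
setMethod("nViews", "Sinogram", function(object) object@geometry@nViews)

#' @rdname interiorCT-accessors
setMethod("nDetector", "FanBeamGeometry", function(object) object@nDetector)

#' @rdname interiorCT-accessors
setMethod("nDetector", "Sinogram", function(object) object@geometry@nDetector)

#' @rdname interiorCT-accessors
setMethod("detectorPitch", "FanBeamGeometry",
          function(object) object@detectorPitch)

#' @rdname interiorCT-accessors
setMethod("detectorPitch", "Sinogram",
          function(object) object@geometry@detectorPitch)

#' @rdname interiorCT-accessors
setMethod("sourceToDetector", "FanBeamGeometry",
          function(object) object@sourceToIso + object@isoToDetector)

#' @rdname interiorCT-accessors
setMethod("effectivePixel", "SourceDetectorSpec",
          function(object) object@binning * object@nativePixel)

setMethod("show", "FanBeamGeometry", function(object) {
  m <- magnifications(object)
  cat(sprintf(
    "FanBeamGeometry: a=%.6g mm, b=%.6g mm (c=%.6g mm, M=%.3f)\n",
    object@sourceToIso, object@isoToDetector, sourceToDetector(object),
    m[["M"]]))
  cat(sprintf("  detector: %d x %.6g mm (offset %.6g mm)\n",
              object@nDetector, object@detectorPitch, object@detectorOffset))
  cat(sprintf("  views: %d over %.6g deg from %.6g deg\n",
              object@nViews, object@angularRange, object@initialAngle))
  if (object@isoOffset != 0)
    cat(sprintf("  assumed rotation center offset: %.6g mm\n",
                object@isoOffset))
})

setMethod("show", "AttenuationImage", function(object) {
  n <- nrow(object@values)
  cat(sprintf(
    "AttenuationImage: %d x %d px @ %.6g mm (%.4g mm field), range [%.4g, %.4g] /cm\n",
    n, n, object@pixelSize, n * object@pixelSize,
    min(object@values), max(object@values)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d views x %d bins, range [%.4g, %.4g]\n",
              nViews(object), nDetector(object),
              min(object@values), max(object@values)))
  show(object@geometry)
})

setMethod("show", "MisalignmentParams", function(object) {
  cat(sprintf(
    "MisalignmentParams: isocenter %.4g mm, angle %.4g deg, magnification %+.2f%%\n",
    object@isocenterOffset, object@angleOffset,
    100 * object@magnificationError))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport (mask radius %.4g mm)\n", object@maskRadius))
  cat(sprintf("  SSIM %.4f  PSNR %.2f dB  MSE %.4g  RMSRE %.4f\n",
              object@ssim, object@psnr, object@mse, object@rmsre))
  if (is.finite(object@rmsreCorrected))
    cat(sprintf("  corrected: SSIM %.4f  PSNR %.2f dB  MSE %.4g  RMSRE %.4f\n",
                object@ssimCorrected, object@psnrCorrected,
                object@mseCorrected, object@rmsreCorrected))
})

#' @describeIn QualityReport-class one-row data.frame with the Table-style
#'   column layout (uncorrected metrics, then `Crt.` columns).
#' @param x a [QualityReport-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @export
as.data.frame.QualityReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(ssim = x@ssim, psnr = x@psnr, mse = x@mse, rmsre = x@rmsre,
             ssim_crt = x@ssimCorrected, psnr_crt = x@psnrCorrected,
             mse_crt = x@mseCorrected, rmsre_crt = x@rmsreCorrected,
             mask_radius = x@maskRadius, row.names = row.names, ...)
}
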