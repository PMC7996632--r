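#' Fan-beam scan geometry
#'
#' Describes one circular 2D fan-beam scan with a flat (equispaced) detector.
#' Distances are in mm, angles in degrees.  The rotation center (isocenter)
#' is the origin of the reconstruction frame; at view angle \eqn{\beta} the
#' source sits at \eqn{a(\cos\beta, \sin\beta)} and the detector line passes
#' through \eqn{-b(\cos\beta, \sin\beta)} perpendicular to the source ray,
#' with detector coordinate u increasing along \eqn{(-\sin\beta, \cos\beta)}.
#' Rotation is counter-clockwise.
#'
#' @slot sourceToIso source to rotation-center distance a (mm).
#' @slot isoToDetector rotation-center to detector distance b (mm).
#' @slot detectorPitch detector element pitch at the detector plane (mm).
#' @slot nDetector number of detector elements.
#' @slot nViews number of projection views.
#' @slot angularRange angular span of the scan in degrees, in (0, 360].
#' @slot initialAngle view angle of the first projection (degrees).
#' @slot detectorOffset lateral shift of the detector center from the
#'   central ray (mm).
#' @slot isoOffset shift of the assumed rotation center along the fixed
#'   laboratory x axis (mm); nonzero only for deliberately misaligned
#'   geometries (see [applyMisalignment()]).
#'
#' @seealso [fanBeamGeometry()], [magnifications()], [applyMisalignment()]
#' @export
setClass("FanBeamGeometry",
  representation(
    sourceToIso = "numeric",
    isoToDetector = "numeric",
    detectorPitch = "numeric",
    nDetector = "integer",
    nViews = "integer",
    angularRange = "numeric",
    initialAngle = "numeric",
    detectorOffset = "numeric",
    isoOffset = "numeric"
  ),
  prototype(
    angularRange = 360, initialAngle = 0, detectorOffset = 0, isoOffset = 0
  )
)

setValidity("FanBeamGeometry", function(object) {
  msg <- character()
  if (length(object@sourceToIso) != 1 || !is.finite(object@sourceToIso) ||
      object@sourceToIso <= 0)
    msg <- c(msg, "sourceToIso must be a single positive number")
  if (length(object@isoToDetector) != 1 || !is.finite(object@isoToDetector) ||
      object@isoToDetector <= 0)
    msg <- c(msg, "isoToDetector must be a single positive number")
  if (length(object@detectorPitch) != 1 || object@detectorPitch <= 0)
    msg <- c(msg, "detectorPitch must be positive")
  if (object@nDetector < 1L) msg <- c(msg, "nDetector must be >= 1")
  if (object@nViews < 1L) msg <- c(msg, "nViews must be >= 1")
  if (!(object@angularRange > 0 && object@angularRange <= 360))
    msg <- c(msg, "angularRange must lie in (0, 360]")
  if (length(msg)) msg else TRUE
})

#' Geometric misalignment parameters
#'
#' Perturbation of the *assumed* geometry used when the background sinogram
#' is estimated: an isocenter offset along the fixed horizontal axis, an
#' offset added to the assumed initial view angle, and a relative error of
#' the assumed magnification realized as a scale factor on the detector
#' coordinate.  All three default to zero (the aligned case).
#'
#' @slot isocenterOffset rotation-center shift along x (mm).
#' @slot angleOffset initial view-angle error (degrees).
#' @slot magnificationError dimensionless fraction (> -1); e.g. -0.2 means
#'   the assumed magnification is 20\% too small.
#'
#' @seealso [misalignmentParams()], [applyMisalignment()]
#' @export
setClass("MisalignmentParams",
  representation(
    isocenterOffset = "numeric",
    angleOffset = "numeric",
    magnificationError = "numeric"
  ),
  prototype(isocenterOffset = 0, angleOffset = 0, magnificationError = 0)
)

setValidity("MisalignmentParams", function(object) {
  if (object@magnificationError <= -1)
    return("magnificationError must be > -1")
  TRUE
})

#' Source and detector element specification
#'
#' Focal-spot size and detector pixel of the imaging chain, used by the
#' system spatial-resolution model.  Sizes in micrometres.
#'
#' @slot focalSpot focal spot size x (um), >= 0.
#' @slot nativePixel native detector pixel d0 (um).
#' @slot binning integer binning factor; the effective pixel is
#'   d = binning * d0.
#'
#' @seealso [sourceDetectorSpec()], [systemResolution()]
#' @export
setClass("SourceDetectorSpec",
  representation(focalSpot = "numeric", nativePixel = "numeric",
                 binning = "integer"),
  prototype(focalSpot = 50, nativePixel = 55, binning = 2L)
)

setValidity("SourceDetectorSpec", function(object) {
  msg <- character()
  if (object@focalSpot < 0) msg <- c(msg, "focalSpot must be >= 0")
  if (object@nativePixel <= 0) msg <- c(msg, "nativePixel must be > 0")
  if (object@binning < 1L) msg <- c(msg, "binning must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Attenuation image
#'
#' A square pixel grid of linear attenuation values (1/cm) whose center
#' coincides with the isocenter.  Row 1 is the top of the image: pixel
#' (i, j) sits at x = (j - (n+1)/2) * pixelSize,
#' y = ((n+1)/2 - i) * pixelSize.  Phantoms are nonnegative with air at 0;
#' reconstructions may carry small negative values.
#'
#' @slot values numeric matrix of attenuation values (1/cm).
#' @slot pixelSize pixel edge length (mm).
#'
#' @seealso [makeHeadPhantom()], [fanFBP()]
#' @export
setClass("AttenuationImage",
  representation(values = "matrix", pixelSize = "numeric")
)

setValidity("AttenuationImage", function(object) {
  msg <- character()
  if (nrow(object@values) != ncol(object@values))
    msg <- c(msg, "attenuation grid must be square")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "attenuation values must be finite")
  if (length(msg)) msg else TRUE
})

#' Sinogram
#'
#' Views-by-detector array of dimensionless line integrals together with the
#' fan-beam geometry that produced (or labels) it.  The `metadata` list
#' carries optional annotations such as the extrapolation mask attached by
#' [upsampleSinogram()].
#'
#' @slot values numeric matrix, nViews x nDetector.
#' @slot geometry a [FanBeamGeometry-class] whose dimensions match `values`.
#' @slot metadata free-form list of annotations.
#'
#' @seealso [forwardProject()], [truncateSinogram()]
#' @export
setClass("Sinogram",
  representation(values = "matrix", geometry = "FanBeamGeometry",
                 metadata = "list"),
  prototype(metadata = list())
)

setValidity("Sinogram", function(object) {
  g <- object@geometry
  msg <- character()
  if (nrow(object@values) != g@nViews)
    msg <- c(msg, "nrow(values) must equal geometry nViews")
  if (ncol(object@values) != g@nDetector)
    msg <- c(msg, "ncol(values) must equal geometry nDetector")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "sinogram values must be finite")
  if (length(msg)) msg else TRUE
})

#' Circular region of interest
#'
#' @slot center (x, y) of the ROI center in the isocenter frame (mm).
#' @slot radius ROI radius (mm), > 0.
#' @export
setClass("CircularROI",
  representation(center = "numeric", radius = "numeric"),
  prototype(center = c(0, 0))
)

setValidity("CircularROI", function(object) {
  msg <- character()
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite length-2 vector")
  if (length(object@radius) != 1 || object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Image-quality report
#'
#' SSIM, PSNR (dB), MSE (1/cm^2) and RMSRE (fraction) of a reconstruction
#' against a reference over a circular evaluation mask, with the same
#' metrics for the bias-corrected reconstruction.
#'
#' @slot ssim,psnr,mse,rmsre metrics of the uncorrected reconstruction.
#' @slot ssimCorrected,psnrCorrected,mseCorrected,rmsreCorrected metrics of
#'   the bias-corrected reconstruction (NA when no correction was applied).
#' @slot maskRadius evaluation-mask radius (mm).
#'
#' @seealso [qualityReport()]
#' @export
setClass("QualityReport",
  representation(
    ssim = "numeric", psnr = "numeric", mse = "numeric", rmsre = "numeric",
    ssimCorrected = "numeric", psnrCorrected = "numeric",
    mseCorrected = "numeric", rmsreCorrected = "numeric",
    maskRadius = "numeric"
  ),
  prototype(ssimCorrected = NA_real_, psnrCorrected = NA_real_,
            mseCorrected = NA_real_, rmsreCorrected = NA_real_)
)

setValidity("QualityReport", function(object) {
  msg <- character()
  if (is.finite(object@mse) && object@mse < 0) msg <- c(msg, "mse must be >= 0")
  if (is.finite(object@rmsre) && object@rmsre < 0)
    msg <- c(msg, "rmsre must be >= 0")
  if (is.finite(object@ssim) && object@ssim > 1 + 1e-12)
    msg <- c(msg, "ssim must be <= 1")
  if (length(msg)) msg else TRUE
})
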