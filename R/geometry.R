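#' Construct a fan-beam scan geometry
#'
#' @param sourceToIso source to rotation-center distance a (mm).
#' @param isoToDetector rotation-center to detector distance b (mm).
#' @param detectorPitch detector element pitch at the detector plane (mm).
#' @param nDetector number of detector elements.
#' @param nViews number of views, equally spaced over `angularRange`.
#' @param angularRange angular span in degrees (default full scan, 360).
#' @param initialAngle view angle of the first projection (degrees).
#' @param detectorOffset lateral detector shift from the central ray (mm).
#' @return a validated [FanBeamGeometry-class].
#' @examples
#' g <- fanBeamGeometry(200, 200, detectorPitch = 0.11, nDetector = 1275,
#'                      nViews = 1440)
#' magnifications(g)
#' @export
fanBeamGeometry <- function(sourceToIso, isoToDetector, detectorPitch,
                            nDetector, nViews, angularRange = 360,
                            initialAngle = 0, detectorOffset = 0) {
  if (sourceToIso <= 0 || isoToDetector <= 0)
    stop("invalid geometry: source and detector distances must be positive")
  new("FanBeamGeometry",
      sourceToIso = as.numeric(sourceToIso),
      isoToDetector = as.numeric(isoToDetector),
      detectorPitch = as.numeric(detectorPitch),
      nDetector = as.integer(nDetector), nViews = as.integer(nViews),
      angularRange = as.numeric(angularRange),
      initialAngle = as.numeric(initialAngle),
      detectorOffset = as.numeric(detectorOffset))
}

#' Construct misalignment parameters
#'
#' @param isocenterOffset rotation-center shift along the laboratory x axis
#'   (mm).
#' @param angleOffset error added to the assumed initial view angle
#'   (degrees).
#' @param magnificationError relative magnification error (fraction, > -1).
#' @return a [MisalignmentParams-class]; all defaults zero (aligned).
#' @export
misalignmentParams <- function(isocenterOffset = 0, angleOffset = 0,
                               magnificationError = 0) {
  if (magnificationError <= -1)
    stop("magnificationError must be > -1")
  new("MisalignmentParams",
      isocenterOffset = as.numeric(isocenterOffset),
      angleOffset = as.numeric(angleOffset),
      magnificationError = as.numeric(magnificationError))
}

#' Construct a source/detector element specification
#'
#' Defaults describe a 50 um focal spot with a 55 um detector pixel in 2x2
#' binning mode (effective pixel 110 um).
#'
#' @param focalSpot focal spot size x (um).
#' @param nativePixel native detector pixel d0 (um).
#' @param binning integer binning factor.
#' @return a [SourceDetectorSpec-class].
#' @export
sourceDetectorSpec <- function(focalSpot = 50, nativePixel = 55,
                               binning = 2L) {
  if (focalSpot < 0 || nativePixel < 0)
    stop("sizes must be nonnegative")
  new("SourceDetectorSpec", focalSpot = as.numeric(focalSpot),
      nativePixel = as.numeric(nativePixel), binning = as.integer(binning))
}

#' @describeIn magnifications detector magnification M = c/a and focal-spot
#'   magnification M' = c/b of a fan-beam geometry; both exceed 1.
setMethod("magnifications", "FanBeamGeometry", function(geom) {
  a <- geom@sourceToIso
  b <- geom@isoToDetector
  if (a <= 0 || b <= 0) stop("invalid geometry: nonpositive distance")
  cdist <- a + b
  c(M = cdist / a, Mprime = cdist / b)
})

#' System spatial resolution
#'
#' Approximates the resolution of the imaging chain as the quadrature sum of
#' the detector aperture referred to the object plane (d / M) and the
#' focal-spot penumbra at the object plane (x / M'):
#' \deqn{r = \sqrt{(x/M')^2 + (d/M)^2}.}
#' Since \eqn{M' = c/b} and \eqn{M - 1 = b/a}, the focal-spot term equals the
#' usual penumbra expression \eqn{x (M-1)/M}.
#'
#' @param spec a [SourceDetectorSpec-class] (sizes in um).
#' @param M detector magnification c/a.
#' @param Mprime focal-spot magnification c/b.
#' @return resolution r in um.
#' @examples
#' systemResolution(sourceDetectorSpec(focalSpot = 0), M = 2, Mprime = 2)
#' @export
systemResolution <- function(spec, M, Mprime) {
  stopifnot(is(spec, "SourceDetectorSpec"))
  if (M <= 0 || Mprime <= 0) stop("magnifications must be positive")
  x <- spec@focalSpot
  d <- effectivePixel(spec)
  if (x < 0 || d < 0) stop("sizes must be nonnegative")
  sqrt((x / Mprime)^2 + (d / M)^2)
}

#' Imaging field of view
#'
#' Diameter of the field of view at the isocenter given the physical sensor
#' width and the detector magnification: diameter = width / M.
#'
#' @param sensorWidth physical sensor width at the detector plane (mm).
#' @param M detector magnification (> 0).
#' @return field-of-view diameter (mm).
#' @examples
#' fieldOfView(70.4, M = 8 / 3)   # ~26 mm
#' fieldOfView(70.4, M = 1.6)     # 44 mm
#' @export
fieldOfView <- function(sensorWidth, M) {
  if (M <= 0) stop("magnification must be positive")
  if (sensorWidth < 0) stop("sensorWidth must be nonnegative")
  sensorWidth / M
}

#' @describeIn applyMisalignment returns the assumed geometry used for
#'   background reprojection: rotation center shifted by `isocenterOffset`
#'   along x, initial angle incremented by `angleOffset`, and the
#'   detector-coordinate scale (pitch and detector offset) divided by
#'   `1 + magnificationError` (an overestimated magnification maps detector
#'   bins to smaller object-plane coordinates).  All-zero parameters return
#'   the input unchanged.
setMethod("applyMisalignment", signature("FanBeamGeometry",
                                         "MisalignmentParams"),
  function(geom, mis) {
    if (mis@magnificationError <= -1)
      stop("magnificationError must be > -1")
    # assumed magnification M * (1 + m): detector coordinates referred to
    # the object plane scale as 1 / (1 + m), so the effectively accurate
    # region scales with (1 + m)
    s <- 1 / (1 + mis@magnificationError)
    new("FanBeamGeometry",
        sourceToIso = geom@sourceToIso,
        isoToDetector = geom@isoToDetector,
        detectorPitch = geom@detectorPitch * s,
        nDetector = geom@nDetector, nViews = geom@nViews,
        angularRange = geom@angularRange,
        initialAngle = geom@initialAngle + mis@angleOffset,
        detectorOffset = geom@detectorOffset * s,
        isoOffset = geom@isoOffset + mis@isocenterOffset)
  })

## internal helpers shared by the projector and FBP -------------------------

# view angles in radians
.viewAngles <- function(geom) {
  beta0 <- geom@initialAngle * pi / 180
  span <- geom@angularRange * pi / 180
  beta0 + span * (seq_len(geom@nViews) - 1) / geom@nViews
}

# detector bin coordinates u_i (mm at the detector plane), measured from the
# central ray
.detectorCoords <- function(geom) {
  (seq_len(geom@nDetector) - (geom@nDetector + 1) / 2) * geom@detectorPitch +
    geom@detectorOffset
}
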