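#' Circular ROI constructor and pixel mask
#'
#' @param center (x, y) center in the isocenter frame (mm).
#' @param radius radius (mm).
#' @return `circularROI` returns a [CircularROI-class]; `roiMask` a logical
#'   matrix marking pixels whose centers lie inside the circle.
#' @export
circularROI <- function(center = c(0, 0), radius) {
  new("CircularROI", center = as.numeric(center), radius = as.numeric(radius))
}

#' @rdname circularROI
#' @param img an [AttenuationImage-class] defining the pixel grid.
#' @param roi a [CircularROI-class].
#' @export
roiMask <- function(img, roi) {
  stopifnot(is(img, "AttenuationImage"), is(roi, "CircularROI"))
  n <- nrow(img@values)
  p <- img@pixelSize
  xs <- (seq_len(n) - (n + 1) / 2) * p
  ys <- ((n + 1) / 2 - seq_len(n)) * p
  outer(ys, xs, function(y, x)
    (x - roi@center[1])^2 + (y - roi@center[2])^2 <= roi@radius^2)
}

#' Zero out the ROI to form the background image
#'
#' Sets to zero every pixel whose center lies inside the ROI circle of the
#' aligned global reconstruction; all other pixels are unchanged.  The
#' result is the background image whose reprojection estimates the
#' out-of-ROI contribution to the local sinogram.
#'
#' @param img the aligned global reconstruction ([AttenuationImage-class]).
#' @param roi a [CircularROI-class] fully inside the image.
#' @return the background [AttenuationImage-class].
#' @export
buildBackground <- function(img, roi) {
  stopifnot(is(img, "AttenuationImage"), is(roi, "CircularROI"))
  half <- nrow(img@values) * img@pixelSize / 2
  if (any(abs(roi@center) + roi@radius > half))
    stop("ROI extends outside the image")
  vals <- img@values
  vals[roiMask(img, roi)] <- 0
  attenuationImage(vals, img@pixelSize)
}

# low-resolution proxy of a local geometry: coarser detector pitch over the
# local window plus a margin, and a subsampled view set
.lrProxyGeometry <- function(gLocal, lrPitch, viewStride, marginFactor) {
  if (gLocal@nViews %% viewStride != 0)
    stop("viewStride must divide the number of local views")
  width <- gLocal@nDetector * gLocal@detectorPitch * marginFactor
  nd <- ceiling(width / lrPitch)
  if (nd %% 2 == 0) nd <- nd + 1
  g <- gLocal
  g@detectorPitch <- as.numeric(lrPitch)
  g@nDetector <- as.integer(nd)
  g@nViews <- as.integer(gLocal@nViews / viewStride)
  g
}

#' Estimate the background sinogram by reprojection
#'
#' Digitally reprojects the background image (global reconstruction with the
#' ROI zeroed) following the local scan geometry, at a reduced
#' (low-resolution) detector/view sampling, under the *assumed* geometry
#' obtained by applying the misalignment parameters.  The returned sinogram
#' is labeled with the nominal (unperturbed) low-resolution geometry: a
#' misalignment therefore shifts/scales the estimate relative to its nominal
#' coordinates, exactly as a registration error would in practice.
#'
#' @param vBg background image from [buildBackground()].
#' @param gLocal the (truncated) local scan [FanBeamGeometry-class].
#' @param mis a [MisalignmentParams-class].
#' @param lrPitch detector pitch of the reprojection (mm); defaults to the
#'   local pitch (i.e. direct high-resolution reprojection).
#' @param viewStride take every `viewStride`-th local view (must divide the
#'   local view count).
#' @param marginFactor detector coverage as a multiple of the local window
#'   width; the margin accommodates misalignment during interpolation.
#' @param step ray-marching step (mm), defaulting to half the background
#'   pixel.
#' @return a [Sinogram-class] on the nominal low-resolution geometry.
#' @export
estimateBackgroundSinogram <- function(vBg, gLocal,
                                       mis = misalignmentParams(),
                                       lrPitch = gLocal@detectorPitch,
                                       viewStride = 1L, marginFactor = 1.3,
                                       step = NULL) {
  stopifnot(is(vBg, "AttenuationImage"), is(gLocal, "FanBeamGeometry"),
            is(mis, "MisalignmentParams"))
  gLr <- .lrProxyGeometry(gLocal, lrPitch, viewStride, marginFactor)
  gAssumed <- applyMisalignment(gLr, mis)
  sino <- forwardProject(vBg, gAssumed, step = step)
  new("Sinogram", values = sino@values, geometry = gLr,
      metadata = list(misalignment = mis))
}

#' Interpolate a low-resolution sinogram to high resolution
#'
#' Separable interpolation of a coarsely sampled sinogram onto a finer
#' detector/view sampling: natural cubic splines along the detector axis and
#' linear interpolation along the view axis (with periodic wrap for a full
#' scan).  The interpolation is exact at coincident sample points.  Target
#' detector positions beyond the source extent are filled with the edge
#' value and flagged in `metadata(sino)$extrapolated` (per-column logical).
#'
#' @param pLr the low-resolution [Sinogram-class].
#' @param target a [FanBeamGeometry-class] whose view set equals or refines
#'   the LR view set and whose detector pitch is at most the LR pitch.
#' @return the interpolated [Sinogram-class] on `target`.
#' @export
upsampleSinogram <- function(pLr, target) {
  stopifnot(is(pLr, "Sinogram"), is(target, "FanBeamGeometry"))
  gLr <- geometry(pLr)
  if (target@detectorPitch > gLr@detectorPitch + 1e-12)
    stop("target detector pitch must not exceed the LR pitch")
  if (target@nViews %% gLr@nViews != 0 ||
      abs(target@initialAngle - gLr@initialAngle) > 1e-9 ||
      abs(target@angularRange - gLr@angularRange) > 1e-9)
    stop("target view set must equal or refine the LR view set")
  uLr <- .detectorCoords(gLr)
  uHr <- .detectorCoords(target)
  outside <- uHr < min(uLr) | uHr > max(uLr)
  uEval <- pmin(pmax(uHr, min(uLr)), max(uLr))
  nvLr <- gLr@nViews
  nvHr <- target@nViews
  # detector axis: cubic per LR view
  detInterp <- t(apply(pLr@values, 1, function(row)
    stats::splinefun(uLr, row, method = "natural")(uEval)))
  if (nvHr == nvLr) {
    hr <- detInterp
  } else {
    # view axis: linear between LR views, wrapping around the full scan
    ratio <- nvHr / nvLr
    ext <- rbind(detInterp, detInterp[1, ])
    lrIdx <- c(seq(1, nvHr, by = ratio), nvHr + 1)
    hr <- apply(ext, 2, function(colv)
      stats::approx(lrIdx, colv, xout = seq_len(nvHr))$y)
  }
  new("Sinogram", values = hr, geometry = target,
      metadata = c(pLr@metadata, list(extrapolated = outside)))
}

#' Subtract the background estimate from the local sinogram
#'
#' Elementwise difference `pLocal - pBgHr`, the compensation step that
#' leaves the pure ROI sinogram.  Small negative values from estimation
#' error are allowed (no clamping).  The background estimate must already be
#' truncated to exactly the shape and geometry of the local sinogram.
#'
#' @param pLocal the truncated local [Sinogram-class].
#' @param pBgHr the truncated high-resolution background estimate.
#' @return the compensated [Sinogram-class].
#' @export
compensate <- function(pLocal, pBgHr) {
  stopifnot(is(pLocal, "Sinogram"), is(pBgHr, "Sinogram"))
  g1 <- geometry(pLocal)
  g2 <- geometry(pBgHr)
  if (g1@nViews != g2@nViews || g1@nDetector != g2@nDetector ||
      abs(g1@detectorPitch - g2@detectorPitch) > 1e-9 ||
      abs(g1@detectorOffset - g2@detectorOffset) > 1e-6 ||
      abs(g1@sourceToIso - g2@sourceToIso) > 1e-9)
    stop("sinogram shape/geometry mismatch")
  new("Sinogram", values = pLocal@values - pBgHr@values, geometry = g1,
      metadata = pBgHr@metadata)
}

#' Reconstruct the VOI from the compensated sinogram
#'
#' Fan-beam FBP of the pure ROI sinogram.  Values inside the ROI approximate
#' the true attenuation; outside the ROI the background has been subtracted,
#' so values are near zero and are not quantitative (they are reported but
#' flagged via the `roiOnly` metadata note).
#'
#' @inheritParams fanFBP
#' @param pVoi the compensated [Sinogram-class] from [compensate()].
#' @return an [AttenuationImage-class] of the ROI content only.
#' @export
reconstructVOI <- function(pVoi, gridSize, pixelSize,
                           filter = c("hann", "ram-lak")) {
  fanFBP(pVoi, gridSize, pixelSize, filter)
}

#' Additive bias correction against a known region
#'
#' Subtracts from every pixel the difference between the mean over a
#' reference region and its known target value (e.g. air at 0 1/cm), so the
#' corrected image satisfies `mean(values[ref]) == target` exactly.  Pixel
#' differences are untouched: output minus input is spatially constant.
#'
#' @param img an [AttenuationImage-class].
#' @param refMask logical matrix of the image shape, or a
#'   [CircularROI-class] defining the reference region.
#' @param target the known attenuation of the region (1/cm).
#' @return the corrected [AttenuationImage-class].
#' @export
biasCorrect <- function(img, refMask, target = 0) {
  stopifnot(is(img, "AttenuationImage"))
  if (is(refMask, "CircularROI")) refMask <- roiMask(img, refMask)
  if (!any(refMask)) stop("empty reference mask")
  shift <- mean(img@values[refMask]) - target
  attenuationImage(img@values - shift, img@pixelSize)
}

#' Pipeline options
#'
#' Collects the tunable parameters of the compensation pipeline.
#'
#' @param reconGridSize,reconPixelSize VOI reconstruction grid (pixels, mm).
#' @param globalGridSize,globalPixelSize global reconstruction grid.
#' @param lrPitch background reprojection pitch (mm); `NULL` means the
#'   global scan pitch.
#' @param viewStride background reprojection uses every `viewStride`-th
#'   local view; `NULL` picks the stride matching the global view count.
#' @param marginFactor background detector coverage relative to the local
#'   window.
#' @param filter FBP apodization, `"hann"` or `"ram-lak"`.
#' @param biasRef air-reference region for [biasCorrect()]: a list with
#'   `center`, `radius` (mm) and `target` (1/cm).
#' @param evalRadius quality-metric mask radius (mm).
#' @param evalCenter quality-metric mask center (mm).
#' @param noiseI0 photons per bin for Poisson noise on the measured
#'   sinograms, or `NULL` for the noiseless forward model.
#' @param seed noise seed.
#' @param oversample per-phantom-component detector oversampling for the
#'   measured sinograms (recycled over components).
#' @return a named list of options.
#' @export
pipelineOptions <- function(reconGridSize = 512, reconPixelSize = 0.09,
                            globalGridSize = 424, globalPixelSize = 0.498,
                            lrPitch = NULL, viewStride = NULL,
                            marginFactor = 1.3,
                            filter = "hann",
                            biasRef = list(center = c(7, -5), radius = 2.5,
                                           target = 0),
                            evalRadius = 21, evalCenter = c(0, 0),
                            noiseI0 = NULL, seed = 1L, oversample = 1L) {
  list(reconGridSize = reconGridSize, reconPixelSize = reconPixelSize,
       globalGridSize = globalGridSize, globalPixelSize = globalPixelSize,
       lrPitch = lrPitch, viewStride = viewStride,
       marginFactor = marginFactor, filter = filter, biasRef = biasRef,
       evalRadius = evalRadius, evalCenter = evalCenter,
       noiseI0 = noiseI0, seed = seed, oversample = oversample)
}

# widen a truncated local geometry so its detector covers the whole object
.widenGeometry <- function(gLocal, halfExtent) {
  needed <- 2 * halfExtent * sourceToDetector(gLocal) / gLocal@sourceToIso
  extra <- ceiling((needed - gLocal@nDetector * gLocal@detectorPitch) /
                   (2 * gLocal@detectorPitch))
  extra <- max(extra, 0)
  g <- gLocal
  g@nDetector <- as.integer(gLocal@nDetector + 2 * extra)
  g
}

#' Precompute the measured data of a compensation run
#'
#' Simulates the scans that do not depend on the misalignment under study:
#' the low-resolution global sinogram and its reconstruction, the
#' (untruncated) high-resolution sinogram with its truncation to the local
#' window, and the high-resolution reference reconstruction.  The phantom
#' may be a list of [AttenuationImage-class] components at different pixel
#' sizes (e.g. a coarse full head plus a fine bar-pattern insert); their
#' sinograms are summed, which is exact by linearity of projection.
#'
#' @param phantom an [AttenuationImage-class] or list of them.
#' @param gGlobal global scan [FanBeamGeometry-class].
#' @param gLocal truncated local scan [FanBeamGeometry-class].
#' @param options see [pipelineOptions()].
#' @return a list with `pGlobal`, `vGlobal`, `pFull`, `pLocal`, `reference`
#'   and the geometries, reusable across [compensationPipeline()] calls.
#' @export
pipelineContext <- function(phantom, gGlobal, gLocal,
                            options = pipelineOptions()) {
  if (is(phantom, "AttenuationImage")) phantom <- list(phantom)
  ov <- rep_len(options$oversample, length(phantom))
  halfExtent <- max(vapply(phantom, function(ph)
    nrow(ph@values) * ph@pixelSize / 2, 0))
  gWide <- .widenGeometry(gLocal, halfExtent)
  sumProject <- function(geom) {
    out <- NULL
    for (i in seq_along(phantom)) {
      s <- forwardProject(phantom[[i]], geom, oversample = ov[i])
      out <- if (is.null(out)) s@values else out + s@values
    }
    new("Sinogram", values = out, geometry = geom)
  }
  pGlobal <- sumProject(gGlobal)
  pFull <- sumProject(gWide)
  if (!is.null(options$noiseI0)) {
    pGlobal <- addPoissonNoise(pGlobal, options$noiseI0, options$seed)
    pFull <- addPoissonNoise(pFull, options$noiseI0, options$seed + 1L)
  }
  pLocal <- truncateSinogram(pFull,
                             gLocal@nDetector * gLocal@detectorPitch)
  vGlobal <- fanFBP(pGlobal, options$globalGridSize, options$globalPixelSize,
                    options$filter)
  reference <- fanFBP(pFull, options$reconGridSize, options$reconPixelSize,
                      options$filter)
  list(pGlobal = pGlobal, vGlobal = vGlobal, pFull = pFull, pLocal = pLocal,
       reference = reference, gGlobal = gGlobal, gLocal = gLocal,
       gWide = gWide, options = options)
}

#' Background-compensated interior reconstruction pipeline
#'
#' Orchestrates the full method: global low-resolution scan and FBP,
#' ROI zeroing, background reprojection under the assumed (possibly
#' misaligned) geometry, interpolation to the local sampling, truncation,
#' sinogram compensation, VOI reconstruction, and additive bias correction
#' against the air reference, with an image-quality report against the
#' high-resolution untruncated reference reconstruction.
#'
#' @inheritParams pipelineContext
#' @param roi the compensation [CircularROI-class] (must lie inside the
#'   local scan window).
#' @param mis a [MisalignmentParams-class] injected into the background
#'   estimation chain.
#' @param context optional precomputed [pipelineContext()]; when supplied,
#'   `phantom`, `gGlobal` and `gLocal` may be `NULL`.
#' @return a list with elements `voi`, `voiCorrected`
#'   ([AttenuationImage-class]), `report` ([QualityReport-class]),
#'   `reference`, and the intermediate sinograms.
#' @examples
#' \donttest{
#' ph <- makeHeadPhantom(420, 0.5, seed = 1)
#' gG <- fanBeamGeometry(200, 200, 1.024, nDetector = 400, nViews = 360)
#' gL <- fanBeamGeometry(200, 200, 0.44, nDetector = 319, nViews = 360)
#' run <- compensationPipeline(ph, gG, gL, circularROI(c(0, 0), 23),
#'                             options = pipelineOptions(reconGridSize = 256,
#'                                                       reconPixelSize = 0.18))
#' run$report
#' }
#' @export
compensationPipeline <- function(phantom, gGlobal, gLocal, roi,
                                 mis = misalignmentParams(),
                                 options = pipelineOptions(),
                                 context = NULL) {
  optionsGiven <- !missing(options)
  if (is.null(context))
    context <- pipelineContext(phantom, gGlobal, gLocal, options)
  if (!optionsGiven) options <- context$options
  gLocal <- context$gLocal
  window <- gLocal@nDetector * gLocal@detectorPitch
  if (roi@radius * sourceToDetector(gLocal) / gLocal@sourceToIso >
      window / 2 + 1e-9)
    stop("local scan window does not cover the ROI")
  lrPitch <- if (is.null(options$lrPitch)) context$gGlobal@detectorPitch
             else options$lrPitch
  viewStride <- options$viewStride
  if (is.null(viewStride)) {
    viewStride <- max(1L, gLocal@nViews %/% context$gGlobal@nViews)
    while (gLocal@nViews %% viewStride != 0) viewStride <- viewStride - 1L
  }
  vBg <- buildBackground(context$vGlobal, roi)
  pBgLr <- estimateBackgroundSinogram(vBg, gLocal, mis, lrPitch = lrPitch,
                                      viewStride = viewStride,
                                      marginFactor = options$marginFactor)
  # interpolate onto a widened copy of the local sampling, then truncate to
  # exactly the local window
  gLrExtent <- geometry(pBgLr)@nDetector * geometry(pBgLr)@detectorPitch
  extra <- floor((gLrExtent - window) / (2 * gLocal@detectorPitch))
  gBgTarget <- gLocal
  gBgTarget@nDetector <- as.integer(gLocal@nDetector + 2 * max(extra, 0))
  pBgHr <- upsampleSinogram(pBgLr, gBgTarget)
  pBgHrT <- truncateSinogram(pBgHr, window)
  pVoi <- compensate(context$pLocal, pBgHrT)
  voi <- reconstructVOI(pVoi, options$reconGridSize, options$reconPixelSize,
                        options$filter)
  ref <- options$biasRef
  voiCrt <- biasCorrect(voi, circularROI(ref$center, ref$radius), ref$target)
  report <- qualityReport(voi, context$reference,
                          maskRadius = options$evalRadius,
                          center = options$evalCenter, corrected = voiCrt)
  list(voi = voi, voiCorrected = voiCrt, report = report,
       reference = context$reference, pVoi = pVoi, pBackgroundLR = pBgLr,
       pBackgroundHR = pBgHrT, vBackground = vBg, context = context,
       misalignment = mis)
}
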