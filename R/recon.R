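# Ramp filtering of a fan-beam sinogram on the flat detector rescaled to
# the isocenter plane.  Works in cm so that dimensionless line integrals
# filter to 1/cm.  Returns the filtered rows (nViews x nDetector).
.rampFilter <- function(vals, geom, window = c("hann", "ram-lak")) {
  window <- match.arg(window)
  a <- geom@sourceToIso
  cdist <- sourceToDetector(geom)
  uIso <- .detectorCoords(geom) * a / cdist     # mm at the isocenter plane
  du <- geom@detectorPitch * a / cdist / 10     # cm
  nd <- geom@nDetector
  # cosine pre-weighting
  w <- a / sqrt(a^2 + uIso^2)
  vals <- sweep(vals, 2, w, `*`)
  # band-limited ramp kernel (wrap-around layout), zero-padded FFT
  nfft <- 2^ceiling(log2(max(2 * nd, 64)))
  h <- numeric(nfft)
  h[1] <- 1 / (4 * du^2)
  lag <- seq_len(nfft / 2)
  odd <- lag[lag %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd * du)^2
  h[nfft + 1 - odd] <- -1 / (pi * odd * du)^2
  H <- Re(stats::fft(h))
  if (window == "hann") {
    k <- c(0:(nfft / 2), (nfft / 2 - 1):1)
    H <- H * (0.5 + 0.5 * cos(2 * pi * k / nfft))
  }
  pad <- matrix(0, nrow(vals), nfft)
  pad[, seq_len(nd)] <- vals
  ft <- t(stats::mvfft(t(pad)))
  ft <- sweep(ft, 2, H, `*`)
  filt <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / nfft
  filt[, seq_len(nd), drop = FALSE] * du
}

#' Fan-beam filtered backprojection
#'
#' Standard flat-detector full-scan fan-beam FBP: cosine pre-weighting of
#' each detector row, ramp filtering (band-limited Ram-Lak kernel via a
#' zero-padded FFT of length at least twice the detector count, with a Hann
#' apodization window by default), and distance-weighted backprojection.
#' The output grid is centered on the assumed rotation center of the
#' sinogram geometry and holds attenuation in 1/cm.  The operation is
#' linear in the sinogram.
#'
#' @param sino a [Sinogram-class] with a full 360-degree angular range.
#' @param gridSize reconstruction grid side (pixels).
#' @param pixelSize reconstruction pixel (mm).
#' @param filter `"hann"` (default) or `"ram-lak"`.
#' @param fovMask when `TRUE` (default), pixels outside the scan field of
#'   view -- which no complete set of rays traverses and which FBP cannot
#'   reconstruct -- are set to zero instead of carrying arbitrary values.
#' @return an [AttenuationImage-class].
#' @examples
#' g <- fanBeamGeometry(200, 200, 0.5, nDetector = 181, nViews = 180)
#' disk <- diskPhantom(128, 0.25, radius = 10, mu = 0.2)
#' rec <- fanFBP(forwardProject(disk, g), 64, 0.5)
#' @export
fanFBP <- function(sino, gridSize, pixelSize, filter = c("hann", "ram-lak"),
                   fovMask = TRUE) {
  stopifnot(is(sino, "Sinogram"))
  g <- geometry(sino)
  if (g@angularRange < 360 - 1e-9)
    stop("unsupported scan: fanFBP requires a full 360-degree angular range")
  q <- .rampFilter(sino@values, g, match.arg(filter))
  a <- g@sourceToIso
  uIso <- .detectorCoords(g) * a / sourceToDetector(g)
  dbeta <- 2 * pi / g@nViews
  img <- cpp_backproject(q, .viewAngles(g), uIso, a, g@isoOffset,
                         as.integer(gridSize), pixelSize) * (dbeta / 2)
  if (fovMask) {
    # pixels seen by the detector in every view: radius of the largest
    # centered circle inside the fan coverage
    uEdge <- min(abs(range(uIso)))
    rFov <- a * uEdge / sqrt(a^2 + uEdge^2)
    n <- as.integer(gridSize)
    xs <- (seq_len(n) - (n + 1) / 2) * pixelSize
    ys <- ((n + 1) / 2 - seq_len(n)) * pixelSize
    outside <- outer(ys, xs, function(y, x) x^2 + y^2) > rFov^2
    img[outside] <- 0
  }
  attenuationImage(img, pixelSize)
}

#' Direct interior FBP of a truncated sinogram
#'
#' Applies [fanFBP()] after symmetric constant (edge-value) extrapolation of
#' each truncated detector row over one filter-support width (the detector
#' count).  This is the naive interior reconstruction: inside the scanned
#' window structures are visible but attenuation values show the
#' characteristic cupping/offset of truncated-data FBP.  The operation
#' exists to demonstrate that failure mode; the background-compensated
#' pipeline is the accurate alternative.
#'
#' @inheritParams fanFBP
#' @param sino a laterally truncated [Sinogram-class].
#' @return an [AttenuationImage-class].
#' @export
directInteriorFBP <- function(sino, gridSize, pixelSize,
                              filter = c("hann", "ram-lak")) {
  stopifnot(is(sino, "Sinogram"))
  g <- geometry(sino)
  nd <- g@nDetector
  pad <- nd
  vals <- sino@values
  left <- matrix(vals[, 1], nrow(vals), pad)
  right <- matrix(vals[, nd], nrow(vals), pad)
  gExt <- g
  gExt@nDetector <- as.integer(nd + 2 * pad)
  # padding is symmetric so the window center is unchanged
  ext <- new("Sinogram", values = cbind(left, vals, right), geometry = gExt)
  fanFBP(ext, gridSize, pixelSize, filter)
}
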