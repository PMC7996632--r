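#' Fan-beam forward projection
#'
#' Computes the sinogram of an attenuation image under a fan-beam geometry
#' by ray-driven marching with bilinear interpolation at a step of half the
#' image pixel (or finer).  Each entry is the line integral of mu along the
#' source-to-detector-bin ray; with mu in 1/cm and lengths in mm the
#' integrals are dimensionless (mu * path / 10).  The operator is exactly
#' linear in the image, and lateral truncation is allowed: the detector need
#' not cover the image.
#'
#' @param img an [AttenuationImage-class] centered on the isocenter.
#' @param geom a [FanBeamGeometry-class]; its `isoOffset`, `initialAngle`,
#'   `detectorPitch` and `detectorOffset` define the (possibly misaligned)
#'   scanning frame.
#' @param step ray-marching step (mm); defaults to `pixelSize(img) / 2` and
#'   is clamped to at most that value.
#' @param oversample number of sub-rays averaged across each detector bin
#'   aperture (1 = bin-center ray only).  Values > 1 model the detector
#'   aperture integration and avoid aliasing of structures near the detector
#'   sampling limit.
#' @return a [Sinogram-class] of dimension nViews x nDetector.
#' @examples
#' disk <- diskPhantom(128, 0.25, radius = 10, mu = 0.2)
#' g <- fanBeamGeometry(200, 200, 0.5, nDetector = 181, nViews = 90)
#' sino <- forwardProject(disk, g)
#' @export
forwardProject <- function(img, geom, step = NULL, oversample = 1L) {
  stopifnot(is(img, "AttenuationImage"), is(geom, "FanBeamGeometry"))
  if (length(img@values) == 0) stop("empty image")
  px <- img@pixelSize
  if (is.null(step)) step <- px / 2
  step <- min(step, px / 2)
  vals <- cpp_forward_project(img@values, px, geom@sourceToIso,
                              geom@isoToDetector, .viewAngles(geom),
                              .detectorCoords(geom), geom@isoOffset,
                              step, as.integer(oversample))
  new("Sinogram", values = vals, geometry = geom)
}

#' Uniform disk phantom
#'
#' Convenience phantom for analytic validation: a uniform disk of radius R
#' and attenuation mu has line integrals 2 mu sqrt(R^2 - s^2) / 10 at signed
#' ray distance s from its center.
#'
#' @param gridSize grid side (pixels).
#' @param pixelSize pixel size (mm).
#' @param radius disk radius (mm).
#' @param mu disk attenuation (1/cm).
#' @param center disk center (mm).
#' @param supersample sub-pixel sampling factor for partial-volume edge
#'   rendering (1 = binary membership at pixel centers).
#' @return an [AttenuationImage-class].
#' @export
diskPhantom <- function(gridSize, pixelSize, radius = 10, mu = 0.2,
                        center = c(0, 0), supersample = 4L) {
  n <- as.integer(gridSize)
  ss <- max(1L, as.integer(supersample))
  off <- ((seq_len(ss) - (ss + 1) / 2) / ss) * pixelSize
  xs <- (seq_len(n) - (n + 1) / 2) * pixelSize
  ys <- ((n + 1) / 2 - seq_len(n)) * pixelSize
  cover <- matrix(0, n, n)
  for (ox in off) for (oy in off) {
    X <- matrix(xs + ox, n, n, byrow = TRUE)
    Y <- matrix(ys + oy, n, n)
    cover <- cover +
      ((X - center[1])^2 + (Y - center[2])^2 <= radius^2)
  }
  attenuationImage(mu * cover / ss^2, pixelSize)
}

#' Laterally truncate a sinogram
#'
#' Retains the central contiguous detector bins spanning `keepWidth` (mm at
#' the detector plane), symmetric about the central ray and honoring the
#' detector offset: bins with |u_i| <= keepWidth / 2 are kept.  The returned
#' geometry carries the reduced detector count and the detector offset of
#' the kept window.
#'
#' @param sino a [Sinogram-class].
#' @param keepWidth width to keep (mm at the detector plane), > 0 and at
#'   most the detector extent.
#' @return the truncated [Sinogram-class].
#' @export
truncateSinogram <- function(sino, keepWidth) {
  stopifnot(is(sino, "Sinogram"))
  if (keepWidth <= 0) stop("keepWidth must be positive")
  g <- geometry(sino)
  if (keepWidth > g@nDetector * g@detectorPitch + 1e-9)
    stop("keepWidth exceeds the detector extent")
  u <- .detectorCoords(g)
  keep <- which(abs(u) <= keepWidth / 2 + 1e-9)
  if (!length(keep)) stop("no detector bins inside the kept window")
  keep <- seq(min(keep), max(keep))
  gNew <- g
  gNew@nDetector <- length(keep)
  # preserve the absolute coordinates of the kept bins
  gNew@detectorOffset <- mean(u[range(keep)])
  new("Sinogram", values = sino@values[, keep, drop = FALSE],
      geometry = gNew, metadata = sino@metadata)
}

#' Add Poisson counting noise
#'
#' Simulates photon-counting statistics: for each line integral p the
#' transmitted count is drawn as Poisson(I0 * exp(-p)) and converted back to
#' a noisy line integral -log(count / I0); zero counts are clamped to 0.5
#' photons.  Reproducible for a fixed seed.
#'
#' @param sino a [Sinogram-class].
#' @param I0 unattenuated photons per detector bin, > 0.
#' @param seed integer seed.
#' @return a noisy [Sinogram-class].
#' @export
addPoissonNoise <- function(sino, I0, seed = 1L) {
  stopifnot(is(sino, "Sinogram"))
  if (I0 <= 0) stop("I0 must be positive")
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(sino@values), I0 * exp(-sino@values))
  counts[counts == 0] <- 0.5
  vals <- matrix(-log(counts / I0), nrow(sino@values), ncol(sino@values))
  new("Sinogram", values = vals, geometry = geometry(sino),
      metadata = sino@metadata)
}

#' Focal-spot penumbra blur
#'
#' Convolves each view along the detector axis with a rectangular kernel of
#' width x * (b / a) at the detector plane: the geometric penumbra of a
#' focal spot of size x.  The kernel integrates to one; a zero focal spot is
#' the identity.
#'
#' @param sino a [Sinogram-class].
#' @param spec a [SourceDetectorSpec-class] (focal spot in um).
#' @return the blurred [Sinogram-class].
#' @export
focalSpotBlur <- function(sino, spec) {
  stopifnot(is(sino, "Sinogram"), is(spec, "SourceDetectorSpec"))
  g <- geometry(sino)
  width <- spec@focalSpot / 1000 * g@isoToDetector / g@sourceToIso  # mm
  if (width <= 0) return(sino)
  kern <- .boxKernel(width / g@detectorPitch)
  vals <- t(apply(sino@values, 1, .convSame, kern = kern))
  new("Sinogram", values = vals, geometry = g, metadata = sino@metadata)
}

# discrete box kernel of (possibly fractional) width w bins, unit sum,
# centered; built from the overlap of each bin with the box
.boxKernel <- function(w) {
  if (w <= 0) return(1)
  half <- ceiling((w - 1) / 2 + 1e-9)
  idx <- seq(-half, half)
  lo <- pmax(idx - 0.5, -w / 2)
  hi <- pmin(idx + 0.5, w / 2)
  k <- pmax(hi - lo, 0)
  k / sum(k)
}

# same-length 1D convolution with edge zero padding
.convSame <- function(x, kern) {
  if (length(kern) == 1) return(x * kern)
  half <- (length(kern) - 1) / 2
  full <- stats::convolve(x, rev(kern), type = "open")
  full[(half + 1):(half + length(x))]
}
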