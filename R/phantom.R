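#' Construct an attenuation image
#'
#' @param values square numeric matrix of linear attenuation (1/cm); a
#'   single number is recycled into a `gridSize` x `gridSize` grid.
#' @param pixelSize pixel edge length (mm).
#' @param gridSize grid side when `values` is scalar.
#' @return an [AttenuationImage-class] centered on the isocenter.
#' @export
attenuationImage <- function(values, pixelSize, gridSize = NULL) {
  if (length(values) == 1 && !is.null(gridSize))
    values <- matrix(as.numeric(values), gridSize, gridSize)
  new("AttenuationImage", values = values, pixelSize = as.numeric(pixelSize))
}

#' Convert Hounsfield units to linear attenuation
#'
#' Standard CT convention: mu = muWater * (1 + hu/1000), clamped below at 0
#' so that air (-1000 HU) maps exactly to zero attenuation.
#'
#' @param hu Hounsfield units (vectorized).
#' @param muWater attenuation of water (1/cm), > 0.
#' @return attenuation in 1/cm.
#' @examples
#' huToMu(c(-1000, 0, 600), muWater = 0.2)
#' @export
huToMu <- function(hu, muWater = 0.2) {
  if (muWater <= 0) stop("muWater must be positive")
  pmax(muWater * (1 + hu / 1000), 0)
}

# fixed anatomy of the synthetic head (mm, isocenter frame); the dense
# temporal-bone-like disk sits at the isocenter so that a scan of the region
# of interest rotates about it
.headAnatomy <- list(
  center = c(-22, 6),        # head (skull) center
  outer = c(80, 62),         # outer skull ellipse semi-axes
  inner = c(73, 55),         # inner skull ellipse semi-axes
  sinus = list(center = c(36, 6), semi = c(8, 12)),          # frontal sinus
  disk = list(center = c(0, 0), radius = 30),                # dense region
  cochlea = list(center = c(-3, 4), semi = c(4, 2.5)),
  airCells = list(list(center = c(7, -5), radius = 3.5),
                  list(center = c(-6, 8), radius = 2)),
  # mastoid-like air cells in the dense bone just outside the ROI
  mastoid = local({
    ang <- seq(0, 330, by = 30) * pi / 180
    lapply(seq_along(ang), function(k)
      list(center = 26 * c(cos(ang[k]), sin(ang[k])),
           radius = 1.0 + 0.4 * (k %% 3)))
  }),
  huSoft = 40, huBone = 1500, huAir = -1000,
  textureBlobs = 18, textureAmpHU = 25,
  edgeSigma = 0.35   # mm; band-limits tissue boundaries (see makeHeadPhantom)
)

.inEllipse <- function(X, Y, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 <= 1
}

.inDisk <- function(X, Y, center, radius) {
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2
}

#' Synthetic head phantom
#'
#' Generates a 2D attenuation phantom emulating an axial head slice: a
#' cortical-bone skull ring around an elliptical soft-tissue interior with a
#' frontal air sinus, and a dense temporal-bone-like disk at the isocenter
#' containing a soft-tissue (cochlea-like) inclusion and two air cells.  A
#' seeded smooth random texture (Gaussian blobs, +/- 25 HU) is added to the
#' soft tissue so repeated renderings are bitwise reproducible per seed and
#' consistent across pixel sizes.  Air maps to exactly 0 1/cm.
#'
#' @param gridSize grid side in pixels (>= 64).
#' @param pixelSize pixel edge length (mm); the grid must contain the whole
#'   head (about 204 mm across).
#' @param seed integer seed for the soft-tissue texture.
#' @param muWater water attenuation (1/cm) for the HU conversion.
#' @return an [AttenuationImage-class].
#' @examples
#' ph <- makeHeadPhantom(256, pixelSize = 0.85, seed = 1)
#' @export
makeHeadPhantom <- function(gridSize, pixelSize, seed = 1L, muWater = 0.2) {
  an <- .headAnatomy
  if (gridSize < 64) stop("gridSize must be at least 64")
  halfNeeded <- max(abs(an$center[1]) + an$outer[1],
                    abs(an$center[2]) + an$outer[2])
  if (gridSize * pixelSize / 2 < halfNeeded)
    stop(sprintf("grid too small to contain the head: need >= %.0f mm extent",
                 2 * halfNeeded))
  n <- as.integer(gridSize)
  xs <- (seq_len(n) - (n + 1) / 2) * pixelSize
  ys <- ((n + 1) / 2 - seq_len(n)) * pixelSize

  # tissue-class HU at exact coordinates (painting order defines overlaps)
  classHU <- function(X, Y) {
    hu <- matrix(an$huAir, nrow(X), ncol(X))
    hu[.inEllipse(X, Y, an$center, an$outer)] <- an$huBone
    hu[.inEllipse(X, Y, an$center, an$inner)] <- an$huSoft
    hu[.inEllipse(X, Y, an$sinus$center, an$sinus$semi)] <- an$huAir
    hu[.inDisk(X, Y, an$disk$center, an$disk$radius)] <- an$huBone
    hu[.inEllipse(X, Y, an$cochlea$center, an$cochlea$semi)] <- an$huSoft
    for (ac in an$airCells)
      hu[.inDisk(X, Y, ac$center, ac$radius)] <- an$huAir
    for (mc in an$mastoid)
      hu[.inDisk(X, Y, mc$center, mc$radius)] <- an$huAir
    hu
  }
  # partial-volume rendering: average the class map over a 3x3 subgrid per
  # pixel so tissue boundaries are band-limited rather than jagged
  ss <- 3L
  off <- ((seq_len(ss) - (ss + 1) / 2) / ss) * pixelSize
  hu <- matrix(0, n, n)
  for (ox in off) for (oy in off) {
    X <- matrix(xs + ox, n, n, byrow = TRUE)
    Y <- matrix(ys + oy, n, n)
    hu <- hu + classHU(X, Y)
  }
  hu <- hu / ss^2

  # seeded smooth texture on soft tissue (evaluated at pixel centers; the
  # blobs are band-limited already)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  soft <- abs(hu - an$huSoft) < 1e-9
  if (any(soft)) {
    blobs <- .textureBlobs(seed, an)
    tex <- matrix(0, n, n)
    for (bl in blobs) {
      d2 <- (X - bl$cx)^2 + (Y - bl$cy)^2
      tex <- tex + bl$amp * exp(-d2 / (2 * bl$sigma^2))
    }
    hu[soft] <- hu[soft] + tex[soft]
  }

  # band-limit tissue boundaries with a fixed physical Gaussian so the
  # rendered object has the same edge profile at every pixel size and no
  # structure beyond what a standard CT scan can represent; fine detail is
  # carried by the separately rendered bar-pattern insert
  mu <- huToMu(hu, muWater)
  sigmaPx <- an$edgeSigma / pixelSize
  if (sigmaPx > 0.25)
    mu <- .gaussFilter(mu, sigma = sigmaPx, radius = ceiling(3 * sigmaPx))

  attenuationImage(mu, pixelSize)
}

# texture blob parameters drawn once per seed, independent of the grid, so a
# phantom rendered at different pixel sizes samples the same object
.textureBlobs <- function(seed, an) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  k <- an$textureBlobs
  lapply(seq_len(k), function(i) {
    list(cx = an$center[1] + stats::runif(1, -1, 1) * an$inner[1] * 0.8,
         cy = an$center[2] + stats::runif(1, -1, 1) * an$inner[2] * 0.8,
         sigma = stats::runif(1, 5, 15),
         amp = stats::runif(1, -1, 1) * an$textureAmpHU)
  })
}

# fraction of [t - p/2, t + p/2] covered by the "bar" phase of a square wave
# that starts with a bar at t0 (bars and gaps both of width w, nBars bars)
.barCoverage <- function(t, p, t0, w, nBars) {
  lo <- t - p / 2
  hi <- t + p / 2
  # cumulative bar measure in [t0, s]
  cum <- function(s) {
    s <- pmin(pmax(s - t0, 0), (2 * nBars - 1) * w)
    period <- 2 * w
    full <- floor(s / period)
    rem <- s - full * period
    full * w + pmin(rem, w)
  }
  (cum(hi) - cum(lo)) / p
}

#' Embed resolution bar patterns
#'
#' Adds bar-pattern groups to an attenuation image: for each requested bar
#' width one group of horizontal bars (modulated along y) and one group of
#' vertical bars (modulated along x), each with `nBars` bars separated by
#' gaps of the same width.  Bars raise the local attenuation by
#' `muWater * amplitude / 1000` (the attenuation difference corresponding to
#' `amplitude` HU); pixels outside the pattern footprints are untouched.
#' Partial-volume coverage is applied along the modulation axis.
#'
#' @param img an [AttenuationImage-class].
#' @param anchor (x, y) of the lower-left corner of the pattern block (mm).
#' @param barWidths bar widths in um; defaults include the 50 and 75 um
#'   patterns.
#' @param amplitude pattern amplitude in HU.
#' @param muWater water attenuation (1/cm) used for the HU conversion.
#' @param nBars number of bars per group (>= 3).
#' @param barLength bar length (mm).
#' @return the image with the patterns added.
#' @export
embedBarPatterns <- function(img, anchor, barWidths = c(50, 75),
                             amplitude = 600, muWater = 0.2, nBars = 4L,
                             barLength = 1.6) {
  stopifnot(is(img, "AttenuationImage"), nBars >= 3)
  p <- img@pixelSize
  wmm <- sort(barWidths) / 1000
  if (any(wmm < p))
    stop("bar width narrower than one phantom pixel")
  inc <- muWater * amplitude / 1000
  if (inc == 0) return(img)
  n <- nrow(img@values)
  xs <- (seq_len(n) - (n + 1) / 2) * p
  ys <- ((n + 1) / 2 - seq_len(n)) * p
  vals <- img@values
  rowGap <- 0.5
  y0 <- anchor[2]
  for (k in seq_along(wmm)) {
    w <- wmm[k]
    span <- (2 * nBars - 1) * w
    # horizontal bars: stripes along x, modulated along y
    hx0 <- anchor[1]
    covY <- .barCoverage(ys, p, y0, w, nBars)
    covX <- pmin(pmax((pmin(xs + p / 2, hx0 + barLength) -
                       pmax(xs - p / 2, hx0)) / p, 0), 1)
    vals <- vals + inc * outer(covY, covX)
    # vertical bars: stripes along y, modulated along x
    vx0 <- anchor[1] + barLength + rowGap
    covX2 <- .barCoverage(xs, p, vx0, w, nBars)
    covY2 <- pmin(pmax((pmin(ys + p / 2, y0 + barLength) -
                        pmax(ys - p / 2, y0)) / p, 0), 1)
    vals <- vals + inc * outer(covY2, covX2)
    y0 <- y0 + max(span, barLength) + rowGap
  }
  attenuationImage(vals, p)
}

#' Footprint centers of the embedded bar patterns
#'
#' Returns, for each bar width and orientation, the (x, y) midlines of each
#' bar and of each gap, as used when measuring bar-pattern modulation.
#' Layout mirrors [embedBarPatterns()] exactly.
#'
#' @inheritParams embedBarPatterns
#' @return a list per width with elements `horizontal` and `vertical`, each
#'   holding `barCenters`, `gapCenters` (positions along the modulation
#'   axis, mm), the fixed `cross` extent along the bar, and the bar width.
#' @export
barPatternLayout <- function(anchor, barWidths = c(50, 75), nBars = 4L,
                             barLength = 1.6) {
  wmm <- sort(barWidths) / 1000
  rowGap <- 0.5
  y0 <- anchor[2]
  out <- list()
  for (k in seq_along(wmm)) {
    w <- wmm[k]
    span <- (2 * nBars - 1) * w
    barC <- y0 + (seq_len(nBars) - 1) * 2 * w + w / 2
    gapC <- y0 + (seq_len(nBars - 1) - 1) * 2 * w + 1.5 * w
    vx0 <- anchor[1] + barLength + rowGap
    out[[as.character(barWidths[k])]] <- list(
      width_um = sort(barWidths)[k],
      horizontal = list(barCenters = barC, gapCenters = gapC,
                        cross = c(anchor[1], anchor[1] + barLength),
                        axis = "y"),
      vertical = list(
        barCenters = vx0 + (seq_len(nBars) - 1) * 2 * w + w / 2,
        gapCenters = vx0 + (seq_len(nBars - 1) - 1) * 2 * w + 1.5 * w,
        cross = c(y0, y0 + barLength), axis = "x"))
    y0 <- y0 + max(span, barLength) + rowGap
  }
  out
}
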