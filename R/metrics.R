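.asMatrix <- function(x) {
  if (is(x, "AttenuationImage")) x@values else as.matrix(x)
}

.asMask <- function(mask, ref) {
  if (is.null(mask)) return(matrix(TRUE, nrow(ref), ncol(ref)))
  if (is(mask, "CircularROI"))
    stop("pass a logical matrix (use roiMask()) or NULL")
  mask
}

#' Mean squared error over a mask
#'
#' @param rec,gt reconstruction and ground truth ([AttenuationImage-class]
#'   or matrices of equal shape).
#' @param mask logical matrix selecting the evaluated pixels, or `NULL` for
#'   all pixels.
#' @return mean of squared differences (1/cm^2 for attenuation images).
#' @export
imageMSE <- function(rec, gt, mask = NULL) {
  r <- .asMatrix(rec); g <- .asMatrix(gt)
  stopifnot(all(dim(r) == dim(g)))
  m <- .asMask(mask, r)
  if (!any(m)) stop("empty mask")
  mean((r[m] - g[m])^2)
}

#' Root mean-squared relative error
#'
#' `sqrt(mean(((rec - gt) / gt)^2))` over the mask pixels whose ground-truth
#' value exceeds `eps`; the default `eps` of 0.01 1/cm excludes air, where
#' relative error is undefined.
#'
#' @inheritParams imageMSE
#' @param eps ground-truth threshold (same units as the images), > 0.
#' @return RMSRE as a dimensionless fraction.
#' @export
imageRMSRE <- function(rec, gt, mask = NULL, eps = 0.01) {
  r <- .asMatrix(rec); g <- .asMatrix(gt)
  stopifnot(all(dim(r) == dim(g)), eps > 0)
  m <- .asMask(mask, r) & (g > eps)
  if (!any(m)) stop("no pixel passes the eps filter")
  sqrt(mean(((r[m] - g[m]) / g[m])^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / mse)` with the peak taken as the maximum of the ground
#' truth over the mask.  A zero MSE returns `Inf`.
#'
#' @inheritParams imageMSE
#' @return PSNR in dB.
#' @export
imagePSNR <- function(rec, gt, mask = NULL) {
  g <- .asMatrix(gt)
  m <- .asMask(mask, g)
  mse <- imageMSE(rec, gt, mask)
  if (mse == 0) return(Inf)
  peak <- max(g[m])
  10 * log10(peak^2 / mse)
}

# separable Gaussian filtering with replicate (edge) padding
.gaussFilter <- function(x, sigma = 1.5, radius = 5) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  idx <- function(len) pmin(pmax(seq(1 - radius, len + radius), 1), len)
  xp <- x[idx(n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(k))
    out <- out + k[t] * xp[t:(t + n - 1), , drop = FALSE]
  xp <- out[, idx(m), drop = FALSE]
  out2 <- matrix(0, n, m)
  for (t in seq_along(k))
    out2 <- out2 + k[t] * xp[, t:(t + m - 1), drop = FALSE]
  out2
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian weighting window (sigma 1.5) and
#' the conventional constants K1 = 0.01, K2 = 0.03, using the ground-truth
#' dynamic range over the mask as the data range.  Local statistics use
#' Gaussian-weighted (population) moments with replicate edge padding; a
#' border of half the window width is excluded, and the map is averaged over
#' the remaining mask pixels.  With no mask this matches the standard
#' reference implementation of the Wang et al. index.
#'
#' @inheritParams imageMSE
#' @param K1,K2 stabilization constants.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param winSize window size (odd, default 11).
#' @return mean SSIM over the mask (<= 1).
#' @export
imageSSIM <- function(rec, gt, mask = NULL, K1 = 0.01, K2 = 0.03,
                      sigma = 1.5, winSize = 11) {
  r <- .asMatrix(rec); g <- .asMatrix(gt)
  stopifnot(all(dim(r) == dim(g)), winSize %% 2 == 1)
  radius <- (winSize - 1) / 2
  if (min(dim(r)) < winSize) stop("mask/image smaller than the SSIM window")
  m <- .asMask(mask, r)
  L <- diff(range(g[m]))
  if (L <= 0) L <- max(abs(g[m]), 1e-12)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mur <- .gaussFilter(r, sigma, radius)
  mug <- .gaussFilter(g, sigma, radius)
  srr <- .gaussFilter(r * r, sigma, radius) - mur^2
  sgg <- .gaussFilter(g * g, sigma, radius) - mug^2
  srg <- .gaussFilter(r * g, sigma, radius) - mur * mug
  ssimMap <- ((2 * mur * mug + C1) * (2 * srg + C2)) /
    ((mur^2 + mug^2 + C1) * (srr + sgg + C2))
  interior <- matrix(FALSE, nrow(r), ncol(r))
  interior[(radius + 1):(nrow(r) - radius),
           (radius + 1):(ncol(r) - radius)] <- TRUE
  sel <- m & interior
  if (!any(sel)) stop("mask smaller than the SSIM window")
  mean(ssimMap[sel])
}

#' Error profiles through the ROI center
#'
#' One-dimensional slices of the error map `rec - gt` and the relative error
#' `(rec - gt) / gt` along the horizontal and vertical midlines of the ROI.
#'
#' @inheritParams imageMSE
#' @param roi a [CircularROI-class] inside both images.
#' @param eps relative errors are `NA` where `gt <= eps`.
#' @return a data.frame with columns `axis` ("horizontal"/"vertical"),
#'   `position` (mm along the axis, relative to the ROI center), `error`
#'   and `relative`.
#' @export
errorProfiles <- function(rec, gt, roi, eps = 0.01) {
  stopifnot(is(rec, "AttenuationImage"), is(gt, "AttenuationImage"),
            is(roi, "CircularROI"))
  r <- rec@values; g <- gt@values
  stopifnot(all(dim(r) == dim(g)))
  n <- nrow(r); p <- rec@pixelSize
  ctr <- (n + 1) / 2
  ic <- round(ctr - roi@center[2] / p)   # row of the ROI center
  jc <- round(ctr + roi@center[1] / p)   # column of the ROI center
  halfPx <- floor(roi@radius / p)
  jj <- (jc - halfPx):(jc + halfPx)
  ii <- (ic - halfPx):(ic + halfPx)
  jj <- jj[jj >= 1 & jj <= n]
  ii <- ii[ii >= 1 & ii <= n]
  err <- r - g
  rel <- ifelse(g > eps, err / g, NA_real_)
  rbind(
    data.frame(axis = "horizontal", position = (jj - jc) * p,
               error = err[ic, jj], relative = rel[ic, jj]),
    data.frame(axis = "vertical", position = (ic - ii) * p,
               error = err[ii, jc], relative = rel[ii, jc]))
}

#' Image-quality report of a reconstruction
#'
#' Computes SSIM, PSNR, MSE and RMSRE of a reconstruction (and optionally a
#' bias-corrected variant) against a reference over a circular evaluation
#' mask.
#'
#' @param rec reconstruction ([AttenuationImage-class]).
#' @param gt reference of the same grid.
#' @param maskRadius evaluation-mask radius (mm).
#' @param center mask center (mm).
#' @param corrected optional bias-corrected reconstruction.
#' @param eps RMSRE air-exclusion threshold (1/cm).
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(rec, gt, maskRadius, center = c(0, 0),
                          corrected = NULL, eps = 0.01) {
  mask <- roiMask(gt, circularROI(center, maskRadius))
  rep <- new("QualityReport",
             ssim = imageSSIM(rec, gt, mask),
             psnr = imagePSNR(rec, gt, mask),
             mse = imageMSE(rec, gt, mask),
             rmsre = imageRMSRE(rec, gt, mask, eps),
             maskRadius = as.numeric(maskRadius))
  if (!is.null(corrected)) {
    rep@ssimCorrected <- imageSSIM(corrected, gt, mask)
    rep@psnrCorrected <- imagePSNR(corrected, gt, mask)
    rep@mseCorrected <- imageMSE(corrected, gt, mask)
    rep@rmsreCorrected <- imageRMSRE(corrected, gt, mask, eps)
  }
  rep
}
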