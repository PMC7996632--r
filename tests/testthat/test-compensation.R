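test_that("background construction zeroes exactly the ROI pixels", {
  ph <- makeHeadPhantom(424, 0.498, seed = 1)
  roi <- circularROI(c(0, 0), 23)
  bg <- buildBackground(ph, roi)
  m <- roiMask(ph, roi)
  expect_true(all(values(bg)[m] == 0))
  expect_identical(values(bg)[!m], values(ph)[!m])
  expect_equal(sum(values(bg)), sum(values(ph)) - sum(values(ph)[m]))
  # center pixel belongs to the ROI; far pixels are untouched
  n <- 424
  expect_identical(values(bg)[n / 2, n / 2], 0)
  expect_error(buildBackground(ph, circularROI(c(100, 0), 23)),
               "outside the image")
})

test_that("background reprojection vanishes for empty backgrounds", {
  gL <- fanBeamGeometry(200, 200, 0.44, 319, 120)
  zero <- attenuationImage(0, 0.5, gridSize = 420)
  s <- estimateBackgroundSinogram(zero, gL)
  expect_true(all(values(s) == 0))
  # object entirely inside the ROI leaves no background
  disk <- diskPhantom(420, 0.5, radius = 10, mu = 0.2)
  bg <- buildBackground(disk, circularROI(c(0, 0), 23))
  s2 <- estimateBackgroundSinogram(bg, gL)
  expect_true(all(values(s2) == 0))
})

test_that("sinogram interpolation reproduces constants and ramps", {
  gLr <- fanBeamGeometry(200, 200, 1.024, 179, 120)
  gHr <- fanBeamGeometry(200, 200, 0.11, 1275, 240)
  cst <- new("Sinogram", values = matrix(2.5, 120, 179), geometry = gLr)
  up <- upsampleSinogram(cst, gHr)
  expect_lt(max(abs(values(up) - 2.5)), 1e-9)
  u <- interiorCT:::.detectorCoords(gLr)
  ramp <- new("Sinogram",
              values = matrix(0.03 * u + 1, 120, 179, byrow = TRUE),
              geometry = gLr)
  upr <- upsampleSinogram(ramp, gHr)
  uh <- interiorCT:::.detectorCoords(gHr)
  expect_lt(max(abs(sweep(values(upr), 2, 0.03 * uh + 1, `-`))), 1e-9)
  expect_false(any(up@metadata$extrapolated))
})

test_that("interpolation is exact at coincident views and flags overreach", {
  gLr <- fanBeamGeometry(200, 200, 0.5, 21, 6)
  gHr <- fanBeamGeometry(200, 200, 0.5, 21, 12)
  vals <- matrix(rnorm(6 * 21), 6, 21)
  lr <- new("Sinogram", values = vals, geometry = gLr)
  up <- upsampleSinogram(lr, gHr)
  expect_equal(values(up)[seq(1, 12, 2), ], vals, tolerance = 1e-12)
  # a wider target detector is edge-filled and flagged
  gWide <- fanBeamGeometry(200, 200, 0.5, 41, 6)
  upw <- upsampleSinogram(lr, gWide)
  expect_true(any(upw@metadata$extrapolated))
  expect_equal(values(upw)[, 1], values(upw)[, 2])
})

test_that("compensation subtracts the background estimate exactly", {
  g <- fanBeamGeometry(200, 200, 0.44, 319, 60)
  a <- new("Sinogram", values = matrix(runif(60 * 319), 60, 319),
           geometry = g)
  b <- new("Sinogram", values = matrix(runif(60 * 319), 60, 319),
           geometry = g)
  expect_equal(values(compensate(a, b)), values(a) - values(b))
  expect_true(all(values(compensate(a, a)) == 0))
  zg <- new("Sinogram", values = matrix(0, 60, 319), geometry = g)
  expect_identical(values(compensate(a, zg)), values(a))
  g2 <- fanBeamGeometry(200, 200, 0.44, 317, 60)
  b2 <- new("Sinogram", values = matrix(0, 60, 317), geometry = g2)
  expect_error(compensate(a, b2), "mismatch")
})

test_that("compensated recon equals the ROI-only recon given exact data", {
  # noiseless data, background reprojected at full resolution directly
  ph <- makeHeadPhantom(420, 0.5, seed = 4)
  gL <- fanBeamGeometry(200, 200, 0.44, 319, 180)
  roi <- circularROI(c(0, 0), 23)
  gWide <- interiorCT:::.widenGeometry(gL, 105)
  pFull <- forwardProject(ph, gWide)
  pLocal <- truncateSinogram(pFull, 319 * 0.44)
  pBg <- forwardProject(buildBackground(ph, roi), gL)
  voi <- reconstructVOI(compensate(pLocal, pBg), 192, 0.24)
  roiOnly <- attenuationImage(values(ph) * roiMask(ph, roi), 0.5)
  ref <- fanFBP(forwardProject(roiOnly, gWide), 192, 0.24)
  m <- roiMask(voi, roi)
  relerr <- max(abs(values(voi)[m] - values(ref)[m])) / max(values(ref)[m])
  expect_lt(relerr, 1e-6)
})

test_that("bias correction shifts by a constant to meet the target", {
  ph <- makeHeadPhantom(424, 0.498, seed = 1)
  ref <- circularROI(c(60, 40), 5)
  corrected <- biasCorrect(ph, ref, target = 0.21)
  m <- roiMask(ph, ref)
  expect_equal(mean(values(corrected)[m]), 0.21, tolerance = 1e-12)
  # pixel differences are untouched: output - input is spatially constant
  d <- values(corrected) - values(ph)
  expect_lt(diff(range(d)), 1e-12)
  # an image already satisfying the target is unchanged
  again <- biasCorrect(corrected, ref, target = 0.21)
  expect_equal(values(again), values(corrected), tolerance = 1e-14)
  # an additive offset is removed exactly
  shifted <- attenuationImage(values(ph) + 0.05, 0.498)
  back <- biasCorrect(shifted, ref, target = mean(values(ph)[m]))
  expect_equal(values(back), values(ph), tolerance = 1e-12)
  expect_error(biasCorrect(ph, matrix(FALSE, 424, 424)), "empty")
})

test_that("aligned pipeline reconstructs the ROI accurately", {
  run <- smallRun()
  expect_lt(run$report@rmsre, 0.02)
  expect_gt(run$report@ssim, 0.98)
  # bias correction against the air cell helps or is neutral
  expect_lt(run$report@rmsreCorrected, run$report@rmsre + 0.002)
})

test_that("LR background bridging changes the result only marginally", {
  ctx <- smallContext()
  opts <- smallOptions()
  # direct high-resolution reprojection instead of the LR-then-interpolate
  optsHr <- opts
  optsHr$lrPitch <- 0.22
  optsHr$viewStride <- 1L
  runHr <- compensationPipeline(NULL, NULL, NULL, smallROI(),
                                misalignmentParams(), options = optsHr,
                                context = ctx)
  runLr <- smallRun()
  expect_lt(abs(runHr$report@rmsre - runLr$report@rmsre), 0.01)
})

test_that("misalignment degrades the reconstruction", {
  aligned <- smallRun()$report@rmsre
  off <- smallRun(misalignmentParams(isocenterOffset = 1.992))$report@rmsre
  expect_gt(off, aligned)
})

test_that("the pipeline rejects a window that misses the ROI", {
  ctx <- smallContext()
  expect_error(
    compensationPipeline(NULL, NULL, NULL, circularROI(c(0, 0), 40),
                         misalignmentParams(), options = smallOptions(),
                         context = ctx),
    "does not cover")
})
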