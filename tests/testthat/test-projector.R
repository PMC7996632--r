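test_that("forward projection matches the analytic disk transform", {
  disk <- diskPhantom(512, 0.1, radius = 10, mu = 0.2)
  g <- fanBeamGeometry(200, 200, 0.2, nDetector = 301, nViews = 4)
  sino <- forwardProject(disk, g)
  for (view in c(1, 2, 3)) {
    s <- rayDistances(g, view)
    expected <- diskLineIntegral(s)
    inside <- abs(s) < 9  # |s| < 0.9 R
    err <- abs(values(sino)[view, inside] - expected[inside]) /
      expected[inside]
    expect_lt(max(err), 0.005)
  }
  # central ray of the first view: chord through the center
  expect_equal(values(sino)[1, 151], 0.4, tolerance = 1e-3)
})

test_that("projection is linear and zero on the empty image", {
  g <- fanBeamGeometry(180, 220, 0.5, nDetector = 101, nViews = 12)
  a <- diskPhantom(128, 0.3, radius = 8, mu = 0.15, center = c(3, -2))
  b <- diskPhantom(128, 0.3, radius = 12, mu = 0.05)
  ab <- attenuationImage(2.5 * values(a) + values(b), 0.3)
  lhs <- values(forwardProject(ab, g))
  rhs <- 2.5 * values(forwardProject(a, g)) + values(forwardProject(b, g))
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
  z <- forwardProject(attenuationImage(0, 0.3, gridSize = 128), g)
  expect_true(all(values(z) == 0))
})

test_that("ROI/background sinograms add to the full sinogram exactly", {
  ph <- makeHeadPhantom(424, 0.498, seed = 2)
  roi <- circularROI(c(0, 0), 23)
  m <- roiMask(ph, roi)
  roiImg <- attenuationImage(values(ph) * m, 0.498)
  bgImg <- buildBackground(ph, roi)
  g <- fanBeamGeometry(200, 200, 1.024, 400, 8)
  pFull <- values(forwardProject(ph, g))
  pSum <- values(forwardProject(roiImg, g)) + values(forwardProject(bgImg, g))
  expect_lt(max(abs(pFull - pSum)) / max(pFull), 1e-10)
})

test_that("truncation keeps the central window and its coordinates", {
  g <- fanBeamGeometry(200, 200, 1, nDetector = 8, nViews = 2)
  sino <- new("Sinogram", values = matrix(rep(1:8, each = 2), 2, 8),
              geometry = g)
  tr <- truncateSinogram(sino, 4)
  expect_equal(nDetector(tr), 4)
  expect_equal(values(tr)[1, ], c(3, 4, 5, 6))  # 0-based bins 2..5
  expect_equal(geometry(tr)@detectorOffset, 0)
  # full width is the identity
  full <- truncateSinogram(sino, 8)
  expect_identical(values(full), values(sino))
  expect_error(truncateSinogram(sino, 0), "positive")
  expect_error(truncateSinogram(sino, 10), "exceeds")
})

test_that("truncation preserves values of objects inside the window", {
  disk <- diskPhantom(256, 0.2, radius = 6, mu = 0.2)
  g <- fanBeamGeometry(200, 200, 0.4, nDetector = 201, nViews = 10)
  sino <- forwardProject(disk, g)
  tr <- truncateSinogram(sino, 40)  # 20 mm at iso > disk diameter
  keep <- (201 - nDetector(tr)) / 2
  expect_identical(values(tr),
                   values(sino)[, (keep + 1):(201 - keep), drop = FALSE])
  # all signal lives inside the kept window
  expect_equal(sum(values(sino)), sum(values(tr)), tolerance = 1e-12)
})

test_that("Poisson noise is reproducible, unbiased at zero, right variance", {
  g <- fanBeamGeometry(200, 200, 0.5, nDetector = 500, nViews = 200)
  zero <- new("Sinogram", values = matrix(0, 200, 500), geometry = g)
  n1 <- addPoissonNoise(zero, 1e6, seed = 11)
  n2 <- addPoissonNoise(zero, 1e6, seed = 11)
  expect_identical(values(n1), values(n2))
  expect_lt(abs(mean(values(n1))), 3e-3)
  one <- new("Sinogram", values = matrix(1, 200, 500), geometry = g)
  np <- addPoissonNoise(one, 1e5, seed = 3)
  v <- stats::var(as.vector(values(np)))
  expect_lt(abs(v - exp(1) / 1e5) / (exp(1) / 1e5), 0.1)
  expect_error(addPoissonNoise(zero, 0), "positive")
})

test_that("focal-spot blur is a normalized penumbra-wide rectangle", {
  g <- fanBeamGeometry(200, 200, 1 / 3, nDetector = 31, nViews = 1)
  delta <- matrix(0, 1, 31); delta[1, 16] <- 1
  sino <- new("Sinogram", values = delta, geometry = g)
  # zero focal spot: identity
  same <- focalSpotBlur(sino, sourceDetectorSpec(focalSpot = 0))
  expect_identical(values(same), values(sino))
  # penumbra x * b / a = 1 mm = 3 detector pitches
  bl <- focalSpotBlur(sino, sourceDetectorSpec(focalSpot = 1000))
  row <- values(bl)[1, ]
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_equal(sum(row > 1e-9), 3)
  expect_equal(row[16], 1 / 3, tolerance = 1e-12)
})
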