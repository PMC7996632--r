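test_that("FBP recovers a uniform disk quantitatively", {
  disk <- diskPhantom(512, 0.1, radius = 10, mu = 0.2)
  g <- fanBeamGeometry(200, 200, 0.2, nDetector = 301, nViews = 360)
  sino <- forwardProject(disk, g)
  rec <- fanFBP(sino, 256, 0.11)
  ctr <- values(rec)[128:129, 128:129]
  expect_lt(max(abs(ctr - 0.2)) / 0.2, 0.01)
  m <- roiMask(rec, circularROI(c(0, 0), 8))
  gt <- diskPhantom(256, 0.11, radius = 10, mu = 0.2)
  expect_lt(imageRMSRE(rec, gt, m), 0.02)
})

test_that("FBP is linear and zero on the zero sinogram", {
  g <- fanBeamGeometry(200, 200, 0.4, nDetector = 151, nViews = 90)
  disk <- diskPhantom(256, 0.2, radius = 12, mu = 0.3, center = c(4, 1))
  sino <- forwardProject(disk, g)
  r1 <- values(fanFBP(sino, 96, 0.25))
  s2 <- new("Sinogram", values = 3 * values(sino), geometry = g)
  r2 <- values(fanFBP(s2, 96, 0.25))
  expect_lt(max(abs(r2 - 3 * r1)) / max(abs(r1)), 1e-10)
  z <- new("Sinogram", values = matrix(0, 90, 151), geometry = g)
  expect_true(all(values(fanFBP(z, 96, 0.25)) == 0))
})

test_that("FBP rejects partial angular ranges", {
  g <- fanBeamGeometry(200, 200, 0.4, 151, 90, angularRange = 180)
  z <- new("Sinogram", values = matrix(0, 90, 151), geometry = g)
  expect_error(fanFBP(z, 64, 0.25), "unsupported scan")
})

test_that("untruncated scan of the head reconstructs within 2% in-object", {
  ctx <- smallContext()
  rec <- fanFBP(ctx$pGlobal, 424, 0.498)
  gt <- makeHeadPhantom(424, 0.498, seed = 1)
  # in-object mask away from material boundaries (2-pixel edge band)
  v <- values(gt)
  n <- nrow(v)
  edge <- matrix(FALSE, n, n)
  step <- abs(diff(range(v))) * 0.1
  for (di in -2:2) for (dj in -2:2) {
    sh <- v[pmin(pmax(seq_len(n) + di, 1), n),
            pmin(pmax(seq_len(n) + dj, 1), n)]
    edge <- edge | abs(sh - v) > step
  }
  m <- v > 0.01 & !edge
  expect_gt(sum(m), 10000)
  expect_lt(imageRMSRE(rec, gt, m), 0.02)
})

test_that("an initial-angle offset rotates the reconstruction", {
  disk <- diskPhantom(512, 0.1, radius = 6, mu = 0.2, center = c(5, 2))
  g <- fanBeamGeometry(200, 200, 0.2, nDetector = 301, nViews = 180)
  sino <- forwardProject(disk, g)
  f <- values(fanFBP(sino, 128, 0.2))
  gRot <- g; gRot@initialAngle <- 90
  sinoRot <- new("Sinogram", values = values(sino), geometry = gRot)
  fRot <- values(fanFBP(sinoRot, 128, 0.2))
  # believing the scan started 90 deg later rotates the image CCW by 90:
  # f'(i, j) = f(j, n + 1 - i)
  n <- 128
  expected <- t(f)[n:1, ]
  expect_lt(max(abs(fRot - expected)) / max(abs(f)), 1e-10)
})

test_that("direct interior FBP equals plain FBP on untruncated data", {
  disk <- diskPhantom(256, 0.2, radius = 8, mu = 0.2)
  g <- fanBeamGeometry(200, 200, 0.4, nDetector = 151, nViews = 90)
  sino <- forwardProject(disk, g)  # disk well inside, edge bins ~0
  a <- values(fanFBP(sino, 64, 0.2))
  b <- values(directInteriorFBP(sino, 64, 0.2))
  expect_lt(max(abs(a - b)) / max(a), 1e-9)
  z <- new("Sinogram", values = matrix(0, 90, 151), geometry = g)
  expect_true(all(values(directInteriorFBP(z, 64, 0.2)) == 0))
})

test_that("direct interior FBP of a truncated scan shows strong bias", {
  ctx <- smallContext()
  rec <- directInteriorFBP(ctx$pLocal, 384, 0.12)
  rep <- qualityReport(rec, ctx$reference, 21)
  comp <- smallRun()$report
  expect_gt(rep@rmsre, 5 * comp@rmsre)
})
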