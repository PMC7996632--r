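test_that("configuration merging overrides defaults recursively", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, local_scan = list(n_views = 96)), f)
  cfg <- readStudyConfig(f)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$local_scan$n_views, 96)
  # untouched keys keep their defaults
  expect_equal(cfg$local_scan$detector_pitch_mm, 0.11)
  expect_equal(cfg$roi$radius_mm, 23)
})

test_that("study geometries implement the scan protocol", {
  g <- studyGeometries()
  expect_equal(unname(magnifications(g$gGlobal)[["M"]]), 2)
  expect_equal(detectorPitch(g$gGlobal), 1.024)
  expect_equal(detectorPitch(g$gLocal), 0.11)
  # local window: 35.05 mm radius at the isocenter, magnification 2
  width <- nDetector(g$gLocal) * detectorPitch(g$gLocal)
  expect_gte(width, 2 * 35.05 * 2)
  expect_lt(width, 2 * 35.05 * 2 + 2 * 0.11)
})

test_that("sweep tables have the layout and sizes of the study design", {
  cfg <- tinyStudyConfig()
  ctxKey <- cached("tinySweepIso", function() sweepIsocenter(cfg))
  iso <- ctxKey
  expect_equal(nrow(iso$tidy), 10)
  expect_equal(iso$tidy$position_error_mm, 0.498 * (0:9))
  expect_equal(rownames(iso$table),
               c("SSIM", "PSNR", "MSE x 1e-4", "RMSRE", "SSIM (Crt.)",
                 "PSNR (Crt.)", "MSE x 1e-4 (Crt.)", "RMSRE (Crt.)"))
  expect_equal(ncol(iso$table), 10)
  ang <- cached("tinySweepAng", function() sweepAngle(cfg, context = iso$context))
  expect_equal(nrow(ang$tidy), 9)
  expect_equal(range(ang$tidy$angle_error_deg), c(-4.392, 4.392))
  mag <- cached("tinySweepMag", function()
    sweepMagnification(cfg, context = iso$context))
  expect_equal(nrow(mag$tidy), 9)
  expect_equal(range(mag$tidy$magnification_error), c(-0.2, 0.2))
  expect_true(all(mag$tidy$mask_radius == 16.8))
})

test_that("study runs are reproducible and write their artifacts", {
  cfg <- tinyStudyConfig()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a1 <- runAccuracyExperiment(cfg, outputDir = d1)
  a2 <- runAccuracyExperiment(cfg, outputDir = d2)
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
  expect_identical(a1$barContrast, a2$barContrast)
  expect_true(file.exists(file.path(d1, "config.yaml")))
  expect_true(file.exists(file.path(d1, "run.log")))
  expect_true(file.exists(file.path(d1, "images", "compensated.tiff")))
  expect_true(file.exists(file.path(d1, "previews", "compensated.png")))
  # the experiment produces both failure-mode and compensated metrics
  expect_setequal(a1$metrics$method, c("compensated", "direct_fbp"))
})

test_that("bar contrast measurement reads the embedded layout", {
  # a synthetic reconstruction equal to the phantom resolves bars fully
  img <- attenuationImage(0.3, 0.025, gridSize = 520)
  withBars <- embedBarPatterns(img, c(-4, -4.5), c(50, 75), 600)
  bc <- measureBarContrast(withBars, c(-4, -4.5), c(50, 75))
  expect_equal(bc$width_um, c(50, 75))
  expect_gt(min(bc$contrast), 0.85)
  # blur the image: the finer pattern must lose more contrast
  k <- exp(-(-6:6)^2 / (2 * 2^2)); k <- k / sum(k)
  sm <- values(withBars)
  sm <- apply(sm, 2, function(x) stats::filter(x, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(x) stats::filter(x, k, circular = TRUE)))
  bcs <- measureBarContrast(attenuationImage(sm, 0.025), c(-4, -4.5),
                            c(50, 75))
  expect_lt(bcs$contrast[1], bcs$contrast[2])
  expect_lt(bcs$contrast[2], bc$contrast[2])
})

test_that("effective radius detects where accuracy is lost", {
  n <- 256
  ref <- attenuationImage(matrix(0.3, n, n), 0.2)
  v <- values(ref)
  xs <- (seq_len(n) - (n + 1) / 2) * 0.2
  D <- sqrt(outer(xs^2, xs^2, `+`))
  # 10% shift outside radius 17
  rec <- attenuationImage(ifelse(t(D) > 17, 0.33, 0.3), 0.2)
  eff <- measureEffectiveRadius(rec, ref, maxRadius = 23, dr = 0.5,
                                threshold = 0.05)
  expect_equal(eff, 17, tolerance = 0.6)
  full <- measureEffectiveRadius(ref, ref, maxRadius = 23, dr = 0.5)
  expect_equal(full, 23, tolerance = 0.5)
})
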