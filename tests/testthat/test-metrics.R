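test_that("MSE follows hand-computed values", {
  g <- matrix(0.2, 5, 5)
  expect_equal(imageMSE(g, g), 0)
  expect_equal(imageMSE(g + 0.001, g), 1e-6)
  mask <- matrix(FALSE, 5, 5)
  mask[1, 1:3] <- TRUE
  r <- g
  r[1, 1:3] <- g[1, 1:3] + c(0.001, -0.002, 0.003)
  expect_equal(imageMSE(r, g, mask), mean(c(1e-6, 4e-6, 9e-6)))
  expect_equal(imageMSE(r, g, mask), 4.667e-6, tolerance = 1e-4)
  expect_error(imageMSE(g, g, matrix(FALSE, 5, 5)), "empty mask")
})

test_that("RMSRE is the air-excluded relative error norm", {
  g <- matrix(0.2, 8, 8)
  expect_equal(imageRMSRE(1.01 * g, g), 0.01)
  expect_equal(imageRMSRE(g, g), 0)
  # uniform ground truth ties RMSRE to sqrt(MSE)/gt
  r <- g + matrix(rnorm(64, sd = 5e-4), 8, 8)
  expect_equal(imageRMSRE(r, g), sqrt(imageMSE(r, g)) / 0.2,
               tolerance = 1e-12)
  # the Table-style pairing: mse 4.54e-6 over gt 0.2 gives 1.065%
  expect_equal(sqrt(4.54e-6) / 0.2, 0.010654, tolerance = 1e-4)
  # air pixels are excluded by the eps filter
  g2 <- g; g2[1, ] <- 0
  r2 <- g2; r2[1, ] <- 10  # air pixels wildly off must not matter
  expect_equal(imageRMSRE(r2, g2), 0)
  expect_error(imageRMSRE(g * 0 + 1, g * 0), "eps filter")
})

test_that("PSNR uses the masked ground-truth peak", {
  g <- matrix(0.32, 6, 6)
  r <- g + 0.32   # mse = peak^2
  expect_equal(imagePSNR(r, g), 0)
  expect_equal(imagePSNR(g, g), Inf)
  # peak 0.32, mse 4.54e-6: 43.53 dB
  r2 <- g + sqrt(4.54e-6)
  expect_equal(imagePSNR(r2, g), 10 * log10(0.32^2 / 4.54e-6))
  expect_equal(imagePSNR(r2, g), 43.53, tolerance = 1e-3)
})

test_that("SSIM matches the reference implementation", {
  i <- matrix(1:64, 64, 64); j <- t(i)
  g <- sin(0.31 * i) * cos(0.17 * j)
  r <- g + 0.05 * sin(0.53 * i + 0.29 * j) + 0.02 * cos(0.11 * i * j)
  # frozen oracle: scikit-image structural_similarity, gaussian_weights,
  # sigma 1.5, win 11, population covariance, data_range = range(g)
  expect_equal(imageSSIM(r, g), 0.9471421365997399, tolerance = 1e-6)
  g2 <- sin(0.9 * i) * sin(0.9 * j)
  expect_equal(imageSSIM(0.5 * g2 + 0.1, g2), 0.04817205764320743,
               tolerance = 1e-6)
  expect_equal(imageSSIM(g, g), 1.0)
  # inverting the structure around a constant local mean scores very low
  gc <- 0.5 + 0.3 * sin(0.9 * i) * sin(0.9 * j)
  inv <- 2 * mean(gc) - gc
  expect_lt(imageSSIM(inv, gc), 0)
  expect_error(imageSSIM(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("all metrics are invariant to a joint 90-degree rotation", {
  set.seed(42)
  n <- 64
  g <- matrix(0.2, n, n) + 0.1 * outer(sin(seq_len(n) / 5),
                                       cos(seq_len(n) / 7))
  r <- g + matrix(rnorm(n^2, sd = 0.01), n, n)
  rot <- function(m) t(m)[n:1, ]
  mask <- roiMask(attenuationImage(g, 1), circularROI(c(0, 0), 20))
  expect_equal(imageMSE(r, g, mask), imageMSE(rot(r), rot(g), rot(mask)))
  expect_equal(imageRMSRE(r, g, mask), imageRMSRE(rot(r), rot(g), rot(mask)))
  expect_equal(imagePSNR(r, g, mask), imagePSNR(rot(r), rot(g), rot(mask)))
  expect_equal(imageSSIM(r, g, mask), imageSSIM(rot(r), rot(g), rot(mask)),
               tolerance = 1e-9)
})

test_that("error profiles slice the midlines of the ROI", {
  img <- attenuationImage(matrix(0.2, 128, 128), 0.5)
  roi <- circularROI(c(0, 0), 10)
  p0 <- errorProfiles(img, img, roi)
  expect_true(all(p0$error == 0))
  shifted <- attenuationImage(values(img) + 0.01, 0.5)
  p1 <- errorProfiles(shifted, img, roi)
  expect_true(all(abs(p1$error - 0.01) < 1e-12))
  expect_true(all(abs(p1$relative - 0.05) < 1e-12))
  # one sample per pixel across the ROI diameter
  h <- p1[p1$axis == "horizontal", ]
  expect_equal(nrow(h), 2 * floor(10 / 0.5) + 1)
  expect_equal(range(h$position), c(-10, 10))
})

test_that("the quality report bundles the four metrics and corrections", {
  g <- attenuationImage(matrix(0.2, 64, 64) +
                          0.05 * outer(sin(1:64 / 4), cos(1:64 / 6)), 1)
  r <- attenuationImage(values(g) + 0.01, 1)
  rep <- qualityReport(r, g, maskRadius = 20, corrected = g)
  expect_s4_class(rep, "QualityReport")
  expect_equal(rep@mse, 1e-4, tolerance = 1e-10)
  expect_equal(rep@mseCorrected, 0)
  expect_equal(rep@maskRadius, 20)
  df <- as.data.frame(rep)
  expect_named(df, c("ssim", "psnr", "mse", "rmsre", "ssim_crt", "psnr_crt",
                     "mse_crt", "rmsre_crt", "mask_radius"))
})
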