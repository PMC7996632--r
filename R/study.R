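#' Default study configuration
#'
#' Desk-scale defaults of the virtual scanning study: a symmetric fan-beam
#' chain (a = b = 200 mm, magnification 2), a global scan at 1.024 mm
#' detector pitch, a high-resolution local scan at 0.11 mm pitch covering a
#' window of radius 35.05 mm around the isocenter, a compensation ROI of
#' radius 23 mm, quality metrics at radius 21 mm (16.8 mm for the
#' magnification sweep), and 50/75 um bar patterns of 600 HU amplitude
#' embedded in the dense region.  Misalignment sweeps run at reduced
#' sampling (720 views, 0.06 mm reconstruction pixels).
#'
#' @return a nested named list; see the fields themselves for units.
#' @export
defaultStudyConfig <- function() {
  list(
    seed = 1L,
    mu_water = 0.2,
    geometry = list(source_to_iso_mm = 200, iso_to_detector_mm = 200),
    global_scan = list(detector_pitch_mm = 1.024, n_detector = 824L,
                       n_views = 1440L),
    local_scan = list(detector_pitch_mm = 0.11, window_radius_mm = 35.05,
                      n_views = 1440L),
    roi = list(center = c(0, 0), radius_mm = 23),
    phantom = list(base_grid = 1680L, base_pixel_mm = 0.125,
                   insert_grid = 520L, insert_pixel_mm = 0.025,
                   bar_anchor = c(-4, -4.5), bar_widths_um = c(50, 75),
                   bar_amplitude_hu = 600, insert_oversample = 3L),
    global_recon = list(grid = 424L, pixel_mm = 0.498),
    accuracy = list(recon_grid = 2048L, recon_pixel_mm = 0.025,
                    eval_radius_mm = 21),
    sweeps = list(n_views = 720L, recon_grid = 768L, recon_pixel_mm = 0.06,
                  eval_radius_mm = 21, eval_radius_mag_mm = 16.8,
                  isocenter_step_mm = 0.498, isocenter_n = 10L,
                  angle_step_deg = 1.098, angle_half_n = 4L,
                  magnification_step = 0.05, magnification_half_n = 4L),
    bias_ref = list(center = c(7, -5), radius_mm = 2.5, target = 0),
    background = list(margin_factor = 1.3)
  )
}

#' Read a study configuration file
#'
#' Loads a YAML configuration and merges it over [defaultStudyConfig()]:
#' keys present in the file override the defaults, recursively.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return the resolved configuration list.
#' @export
readStudyConfig <- function(path = NULL) {
  cfg <- defaultStudyConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  .mergeConfig(cfg, user)
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Scan geometries of a study configuration
#'
#' @param config a study configuration list.
#' @return list with the global geometry `gGlobal`, the truncated local
#'   geometry `gLocal`, and the reduced-view local geometry `gLocalSweep`.
#' @export
studyGeometries <- function(config = defaultStudyConfig()) {
  a <- config$geometry$source_to_iso_mm
  b <- config$geometry$iso_to_detector_mm
  M <- (a + b) / a
  gGlobal <- fanBeamGeometry(a, b, config$global_scan$detector_pitch_mm,
                             config$global_scan$n_detector,
                             config$global_scan$n_views)
  windowDet <- 2 * config$local_scan$window_radius_mm * M
  ndLocal <- ceiling(windowDet / config$local_scan$detector_pitch_mm)
  if (ndLocal %% 2 == 0) ndLocal <- ndLocal + 1
  gLocal <- fanBeamGeometry(a, b, config$local_scan$detector_pitch_mm,
                            ndLocal, config$local_scan$n_views)
  gLocalSweep <- gLocal
  gLocalSweep@nViews <- as.integer(config$sweeps$n_views)
  list(gGlobal = gGlobal, gLocal = gLocal, gLocalSweep = gLocalSweep)
}

#' Build the study phantom components
#'
#' The full head is rendered at the base pixel size; the bar patterns are
#' rendered separately on a fine insert grid so the 50 um bars keep genuine
#' sub-pixel structure relative to the head render.  Projections of the two
#' components add exactly by linearity.
#'
#' @param config a study configuration list.
#' @return list of two [AttenuationImage-class] components `base` and
#'   `insert`, plus the insert oversampling factor.
#' @export
studyPhantom <- function(config = defaultStudyConfig()) {
  ph <- config$phantom
  base <- makeHeadPhantom(ph$base_grid, ph$base_pixel_mm,
                          seed = config$seed, muWater = config$mu_water)
  insert0 <- attenuationImage(0, ph$insert_pixel_mm,
                              gridSize = ph$insert_grid)
  insert <- embedBarPatterns(insert0, ph$bar_anchor, ph$bar_widths_um,
                             ph$bar_amplitude_hu, muWater = config$mu_water)
  list(base = base, insert = insert,
       oversample = c(1L, as.integer(ph$insert_oversample)))
}

# subsample the view dimension of a sinogram (uniform stride)
.thinViews <- function(sino, stride) {
  g <- geometry(sino)
  if (g@nViews %% stride != 0) stop("stride must divide the view count")
  g@nViews <- as.integer(g@nViews / stride)
  new("Sinogram", values = sino@values[seq(1, nrow(sino@values), by = stride),
                                       , drop = FALSE],
      geometry = g, metadata = sino@metadata)
}

.accuracyOptions <- function(config) {
  pipelineOptions(
    reconGridSize = config$accuracy$recon_grid,
    reconPixelSize = config$accuracy$recon_pixel_mm,
    globalGridSize = config$global_recon$grid,
    globalPixelSize = config$global_recon$pixel_mm,
    marginFactor = config$background$margin_factor,
    biasRef = list(center = config$bias_ref$center,
                   radius = config$bias_ref$radius_mm,
                   target = config$bias_ref$target),
    evalRadius = config$accuracy$eval_radius_mm,
    evalCenter = config$roi$center,
    oversample = studyPhantomOversample(config))
}

studyPhantomOversample <- function(config)
  c(1L, as.integer(config$phantom$insert_oversample))

.sweepOptions <- function(config, evalRadius) {
  opts <- .accuracyOptions(config)
  opts$reconGridSize <- config$sweeps$recon_grid
  opts$reconPixelSize <- config$sweeps$recon_pixel_mm
  opts$evalRadius <- evalRadius
  opts
}

#' Accuracy and resolution experiment
#'
#' Runs the full virtual experiment: global low-resolution scan, truncated
#' high-resolution local scan, direct interior FBP (the failure mode),
#' background-compensated reconstruction, the untruncated high-resolution
#' reference, bar-pattern modulation measurements, and midline error
#' profiles.
#'
#' @param config a study configuration list.
#' @param outputDir optional run directory for CSV/TIFF/PNG artifacts.
#' @param context optional precomputed [pipelineContext()].
#' @return a list: `run` (the [compensationPipeline()] result), `direct`
#'   and `directReport` (naive interior FBP and its metrics), `barContrast`
#'   (data.frame of modulation per bar width), `profiles` (midline error
#'   profiles), `metrics` (data.frame combining both reconstructions) and
#'   `context`.
#' @export
runAccuracyExperiment <- function(config = defaultStudyConfig(),
                                  outputDir = NULL, context = NULL) {
  geoms <- studyGeometries(config)
  opts <- .accuracyOptions(config)
  if (is.null(context)) {
    ph <- studyPhantom(config)
    context <- pipelineContext(list(ph$base, ph$insert), geoms$gGlobal,
                               geoms$gLocal, opts)
  }
  roi <- circularROI(config$roi$center, config$roi$radius_mm)
  run <- compensationPipeline(NULL, NULL, NULL, roi, misalignmentParams(),
                              options = opts, context = context)
  direct <- directInteriorFBP(context$pLocal, opts$reconGridSize,
                              opts$reconPixelSize, opts$filter)
  directReport <- qualityReport(direct, context$reference,
                                maskRadius = opts$evalRadius,
                                center = opts$evalCenter)
  amplitudeMu <- config$mu_water * config$phantom$bar_amplitude_hu / 1000
  barContrast <- measureBarContrast(run$voi, config$phantom$bar_anchor,
                                    config$phantom$bar_widths_um,
                                    amplitudeMu = amplitudeMu)
  profiles <- errorProfiles(run$voi, context$reference, roi)
  metrics <- rbind(
    cbind(method = "compensated", as.data.frame(run$report)),
    cbind(method = "direct_fbp", as.data.frame(directReport)))
  out <- list(run = run, direct = direct, directReport = directReport,
              barContrast = barContrast, profiles = profiles,
              metrics = metrics, context = context, config = config)
  if (!is.null(outputDir)) .writeAccuracyOutputs(out, outputDir)
  out
}

#' Measure bar-pattern modulation
#'
#' Samples a reconstruction at the known bar and gap midlines of the
#' embedded patterns (see [barPatternLayout()]) and reports the modulation
#' contrast `(mean(bars) - mean(gaps)) / amplitude` per bar width, averaged
#' over the horizontal and vertical groups.  Fully resolved bars give a
#' contrast near 1, unresolved bars near 0.
#'
#' @param img reconstructed [AttenuationImage-class].
#' @param anchor,barWidths,nBars,barLength pattern layout, as passed to
#'   [embedBarPatterns()].
#' @param amplitudeMu pattern amplitude in attenuation units (1/cm).
#' @return data.frame with `width_um` and `contrast`.
#' @export
measureBarContrast <- function(img, anchor, barWidths = c(50, 75),
                               nBars = 4L, barLength = 1.6,
                               amplitudeMu = 0.12) {
  stopifnot(is(img, "AttenuationImage"))
  p <- img@pixelSize
  n <- nrow(img@values)
  ctr <- (n + 1) / 2
  layout <- barPatternLayout(anchor, barWidths, nBars, barLength)
  sampleLines <- function(grp) {
    cross <- grp$cross + c(0.25, -0.25)   # trim bar ends
    lineMean <- function(pos) {
      if (grp$axis == "y") {
        i <- round(ctr - pos / p)
        j <- seq(ceiling(ctr + cross[1] / p), floor(ctr + cross[2] / p))
        mean(img@values[i, j])
      } else {
        j <- round(ctr + pos / p)
        i <- seq(ceiling(ctr - cross[2] / p), floor(ctr - cross[1] / p))
        mean(img@values[i, j])
      }
    }
    mean(vapply(grp$barCenters, lineMean, 0)) -
      mean(vapply(grp$gapCenters, lineMean, 0))
  }
  do.call(rbind, lapply(layout, function(l) {
    data.frame(width_um = l$width_um,
               contrast = mean(c(sampleLines(l$horizontal),
                                 sampleLines(l$vertical))) / amplitudeMu)
  }))
}

#' Effective radius of accurate reconstruction
#'
#' Walks outward from the evaluation center in annuli and returns the
#' largest radius up to which every annulus has a median absolute relative
#' error at or below `threshold`.  Used to quantify how a magnification
#' error shrinks or grows the effectively reconstructed region.
#'
#' @param rec,ref reconstruction and reference ([AttenuationImage-class]).
#' @param center evaluation center (mm).
#' @param maxRadius largest radius probed (mm).
#' @param dr annulus width (mm).
#' @param threshold tolerated median absolute relative error.
#' @param eps air-exclusion threshold on the reference (1/cm).
#' @return the effective radius in mm.
#' @export
measureEffectiveRadius <- function(rec, ref, center = c(0, 0),
                                   maxRadius = 23, dr = 0.7,
                                   threshold = 0.05, eps = 0.01) {
  r <- .asMatrix(rec); g <- .asMatrix(ref)
  n <- nrow(r); p <- rec@pixelSize
  xs <- (seq_len(n) - (n + 1) / 2) * p
  ys <- ((n + 1) / 2 - seq_len(n)) * p
  D <- sqrt(outer(ys - center[2], xs - center[1],
                  function(y, x) x^2 + y^2))
  rel <- abs(r - g) / ifelse(g > eps, g, NA_real_)
  edges <- seq(0, maxRadius, by = dr)
  eff <- 0
  for (k in seq_len(length(edges) - 1)) {
    sel <- D >= edges[k] & D < edges[k + 1] & !is.na(rel)
    if (!any(sel)) next
    if (stats::median(rel[sel]) > threshold) break
    eff <- edges[k + 1]
  }
  eff
}

.sweepTable <- function(reports, param, values) {
  tidy <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(stats::setNames(data.frame(values[i]), param),
          as.data.frame(reports[[i]]))))
  wide <- rbind(
    SSIM = vapply(reports, function(r) r@ssim, 0),
    PSNR = vapply(reports, function(r) r@psnr, 0),
    `MSE x 1e-4` = vapply(reports, function(r) r@mse * 1e4, 0),
    RMSRE = vapply(reports, function(r) r@rmsre, 0),
    `SSIM (Crt.)` = vapply(reports, function(r) r@ssimCorrected, 0),
    `PSNR (Crt.)` = vapply(reports, function(r) r@psnrCorrected, 0),
    `MSE x 1e-4 (Crt.)` = vapply(reports, function(r) r@mseCorrected * 1e4, 0),
    `RMSRE (Crt.)` = vapply(reports, function(r) r@rmsreCorrected, 0))
  colnames(wide) <- format(values)
  list(tidy = tidy, table = wide,
       reference = format(values[which.min(abs(values))]))
}

# reduced-sampling context shared by the sweeps: thins the view set of a
# precomputed accuracy context, or builds one from scratch
.sweepContext <- function(config, context = NULL) {
  geoms <- studyGeometries(config)
  opts <- .sweepOptions(config, config$sweeps$eval_radius_mm)
  if (!is.null(context)) {
    stride <- geometry(context$pFull)@nViews %/% geoms$gLocalSweep@nViews
    pFull <- .thinViews(context$pFull, stride)
    pLocal <- truncateSinogram(
      pFull, geoms$gLocalSweep@nDetector * geoms$gLocalSweep@detectorPitch)
    reference <- fanFBP(pFull, opts$reconGridSize, opts$reconPixelSize,
                        opts$filter)
    list(pGlobal = context$pGlobal, vGlobal = context$vGlobal,
         pFull = pFull, pLocal = pLocal, reference = reference,
         gGlobal = context$gGlobal, gLocal = geoms$gLocalSweep,
         gWide = geometry(pFull), options = opts)
  } else {
    ph <- studyPhantom(config)
    pipelineContext(list(ph$base, ph$insert), geoms$gGlobal,
                    geoms$gLocalSweep, opts)
  }
}

.runSweep <- function(config, misList, evalRadius, param, values,
                      context = NULL, outputDir = NULL, label = param) {
  ctx <- .sweepContext(config, context)
  opts <- .sweepOptions(config, evalRadius)
  roi <- circularROI(config$roi$center, config$roi$radius_mm)
  runs <- lapply(misList, function(mis)
    compensationPipeline(NULL, NULL, NULL, roi, mis, options = opts,
                         context = ctx))
  reports <- lapply(runs, function(r) r$report)
  out <- .sweepTable(reports, param, values)
  out$runs <- runs
  out$context <- ctx
  out$config <- config
  if (!is.null(outputDir)) .writeSweepOutputs(out, outputDir, label)
  out
}

#' Misalignment sweeps
#'
#' Repeats the compensated reconstruction over a range of injected
#' registration errors and tabulates the quality metrics with and without
#' bias correction, in the layout metric x misalignment.
#' `sweepIsocenter` sweeps the rotation-center offset (default 0 to
#' 4.483 mm in steps of 0.498 mm), `sweepAngle` the initial view-angle
#' error (default -4.39 to 4.39 degrees in steps of 1.098), and
#' `sweepMagnification` the relative magnification error (default -20% to
#' 20% in steps of 5%, evaluated at the reduced radius where the effective
#' ROIs of all magnifications intersect).
#'
#' @param config a study configuration list.
#' @param context optional accuracy-run [pipelineContext()] to reuse (its
#'   view set is thinned to the sweep sampling).
#' @param outputDir optional run directory for artifacts.
#' @return a list with `tidy` (long-format data.frame), `table` (metric x
#'   misalignment matrix, `Crt.` rows appended), `reference` (the aligned
#'   column label), `runs` and `context`.
#' @export
sweepIsocenter <- function(config = defaultStudyConfig(), context = NULL,
                           outputDir = NULL) {
  sw <- config$sweeps
  offsets <- sw$isocenter_step_mm * (seq_len(sw$isocenter_n) - 1)
  .runSweep(config,
            lapply(offsets, function(o) misalignmentParams(isocenterOffset = o)),
            sw$eval_radius_mm, "position_error_mm", offsets,
            context, outputDir, "sweep-isocenter")
}

#' @rdname sweepIsocenter
#' @export
sweepAngle <- function(config = defaultStudyConfig(), context = NULL,
                       outputDir = NULL) {
  sw <- config$sweeps
  angles <- sw$angle_step_deg * seq(-sw$angle_half_n, sw$angle_half_n)
  .runSweep(config,
            lapply(angles, function(d) misalignmentParams(angleOffset = d)),
            sw$eval_radius_mm, "angle_error_deg", angles,
            context, outputDir, "sweep-angle")
}

#' @rdname sweepIsocenter
#' @export
sweepMagnification <- function(config = defaultStudyConfig(), context = NULL,
                               outputDir = NULL) {
  sw <- config$sweeps
  mags <- sw$magnification_step *
    seq(-sw$magnification_half_n, sw$magnification_half_n)
  .runSweep(config,
            lapply(mags, function(m) misalignmentParams(magnificationError = m)),
            sw$eval_radius_mag_mm, "magnification_error", mags,
            context, outputDir, "sweep-magnification")
}

## ---- artifact writing ----------------------------------------------------

.initRunDir <- function(dir, config) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "previews"), showWarnings = FALSE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

.logLine <- function(dir, ...) {
  cat(sprintf(...), "\n", file = file.path(dir, "run.log"), append = TRUE)
}

.writeAccuracyOutputs <- function(out, dir) {
  .initRunDir(dir, out$config)
  utils::write.csv(out$metrics, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(out$barContrast, file.path(dir, "bar_contrast.csv"),
                   row.names = FALSE)
  utils::write.csv(out$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  win <- c(0, 0.7)
  imgs <- list(compensated = out$run$voi, corrected = out$run$voiCorrected,
               direct_fbp = out$direct, reference = out$run$reference)
  for (nm in names(imgs)) {
    writeAttenuationImage(imgs[[nm]],
                          file.path(dir, "images", paste0(nm, ".tiff")))
    writePreviewPNG(imgs[[nm]],
                    file.path(dir, "previews", paste0(nm, ".png")), win)
  }
  .logLine(dir, "accuracy experiment: recon %d px @ %.4g mm, eval radius %.4g mm",
           out$config$accuracy$recon_grid, out$config$accuracy$recon_pixel_mm,
           out$config$accuracy$eval_radius_mm)
  invisible(dir)
}

.writeSweepOutputs <- function(out, dir, label) {
  .initRunDir(dir, out$config)
  utils::write.csv(out$tidy, file.path(dir, "report.csv"), row.names = FALSE)
  tab <- data.frame(metric = rownames(out$table), out$table,
                    check.names = FALSE)
  utils::write.csv(tab, file.path(dir, paste0(label, "-table.csv")),
                   row.names = FALSE)
  cat(sprintf("reference column: %s\n", out$reference),
      file = file.path(dir, paste0(label, "-table.csv")), append = TRUE)
  win <- c(0, 0.7)
  for (i in seq_along(out$runs)) {
    writePreviewPNG(out$runs[[i]]$voiCorrected,
                    file.path(dir, "previews",
                              sprintf("%s-%02d.png", label, i)), win)
  }
  .logLine(dir, "%s: %d runs, recon %d px @ %.4g mm", label,
           length(out$runs), out$config$sweeps$recon_grid,
           out$config$sweeps$recon_pixel_mm)
  invisible(dir)
}
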