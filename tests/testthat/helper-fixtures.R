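# shared fixtures; expensive objects are built lazily and cached so the
# compensation, study and acceptance files reuse one simulated dataset
.cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .cache)) assign(name, build(), envir = .cache)
  get(name, envir = .cache)
}

# small but physically faithful study setup: full head at 0.25 mm, global
# scan at 1.024 mm pitch / 1440 views, local window at 0.22 mm pitch / 720
# views, reconstruction 384 px @ 0.12 mm
smallGeometries <- function() {
  list(gGlobal = fanBeamGeometry(200, 200, 1.024, 824, 1440),
       gLocal = fanBeamGeometry(200, 200, 0.22, 639, 720))
}

smallOptions <- function(evalRadius = 21) {
  pipelineOptions(reconGridSize = 384, reconPixelSize = 0.12,
                  globalGridSize = 424, globalPixelSize = 0.498,
                  evalRadius = evalRadius)
}

smallContext <- function() {
  cached("smallContext", function() {
    g <- smallGeometries()
    ph <- makeHeadPhantom(840, 0.25, seed = 1)
    pipelineContext(ph, g$gGlobal, g$gLocal, smallOptions())
  })
}

smallROI <- function() circularROI(c(0, 0), 23)

smallRun <- function(mis = misalignmentParams(), evalRadius = 21) {
  key <- sprintf("run_%g_%g_%g_%g", mis@isocenterOffset, mis@angleOffset,
                 mis@magnificationError, evalRadius)
  cached(key, function()
    compensationPipeline(NULL, NULL, NULL, smallROI(), mis,
                         options = smallOptions(evalRadius),
                         context = smallContext()))
}

# tiny configuration for structural study tests (row counts, determinism)
tinyStudyConfig <- function() {
  cfg <- defaultStudyConfig()
  cfg$phantom$base_grid <- 420L
  cfg$phantom$base_pixel_mm <- 0.5
  cfg$phantom$insert_grid <- 130L
  cfg$phantom$insert_pixel_mm <- 0.1
  cfg$phantom$bar_widths_um <- c(100, 150)
  cfg$phantom$insert_oversample <- 1L
  cfg$global_scan$n_views <- 180L
  cfg$local_scan$detector_pitch_mm <- 0.44
  cfg$local_scan$n_views <- 360L
  cfg$accuracy$recon_grid <- 192L
  cfg$accuracy$recon_pixel_mm <- 0.24
  cfg$sweeps$n_views <- 180L
  cfg$sweeps$recon_grid <- 192L
  cfg$sweeps$recon_pixel_mm <- 0.24
  cfg
}

# uniform-disk forward model: analytic line integral at signed perpendicular
# distance s from the disk center (mu in 1/cm, lengths mm)
diskLineIntegral <- function(s, radius = 10, mu = 0.2) {
  2 * mu * sqrt(pmax(radius^2 - s^2, 0)) / 10
}

# perpendicular distances of every detector ray of one view from a point;
# exact fan-beam geometry (source at a*(cos b, sin b))
rayDistances <- function(geom, view = 1, point = c(0, 0)) {
  beta <- interiorCT:::.viewAngles(geom)[view]
  u <- interiorCT:::.detectorCoords(geom)
  s <- c(cos(beta) * geom@sourceToIso, sin(beta) * geom@sourceToIso)
  d0 <- -c(cos(beta), sin(beta)) * geom@isoToDetector
  eu <- c(-sin(beta), cos(beta))
  vapply(u, function(ui) {
    d <- d0 + ui * eu
    dir <- (d - s) / sqrt(sum((d - s)^2))
    rel <- point - s
    cross <- rel[1] * dir[2] - rel[2] * dir[1]
    -cross  # signed distance, positive toward +u
  }, 0)
}
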