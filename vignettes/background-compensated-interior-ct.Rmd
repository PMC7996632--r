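---
title: "Background-compensated interior tomography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-compensated interior tomography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A micro-CT scan of a small volume of interest (VOI) inside a human head —
for instance the temporal bone before a cochlear implantation — measures
line integrals that traverse the *whole* head, but only on the narrow
detector window that covers the VOI.  Reconstructing such laterally
truncated projections directly with filtered backprojection (FBP) yields
images whose structures are visible but whose attenuation values are
shifted and cupped: the interior problem has no unique solution without
extra information.

This package implements the hybrid strategy in which a prior
low-resolution (LR) *global* scan supplies that information.  The global
reconstruction, with the region of interest (ROI) zeroed out, is an
estimate of everything *outside* the ROI.  Digitally reprojecting it along
the local scan geometry predicts the contribution of that background to
every truncated ray, and subtracting this estimate from the measured local
sinogram leaves the pure sinogram of the ROI content:

* `P_ROI = P_global − P_background` for complete data (linearity of the
  line-integral transform), and with truncation,
* `P_VOI = P_local − trunc(P_background)`,

because the local window is chosen to cover the ROI, so the truncated part
of the ROI sinogram is zero.  The compensated sinogram is then
reconstructed with ordinary fan-beam FBP; no iterative interior solver is
needed.  The result is quantitative inside the ROI; outside it the values
are near zero by construction and are not interpreted.

## Forward model and reconstruction

All simulation happens in 2D fan-beam geometry with a flat equispaced
detector and a full 360-degree circular scan of equally spaced views.  The
convention is fixed once and shared by the projector, the backprojector
and the reprojection step: the rotation center is the origin; at view
angle beta the source sits at `a (cos beta, sin beta)`; the detector line
passes through `−b (cos beta, sin beta)` perpendicular to the central ray;
the detector coordinate increases along `(−sin beta, cos beta)`; rotation
is counter-clockwise.  Whether the published system measures the source or
the detector position is immaterial as long as one convention is used
self-consistently, which is the case here.

The projector (`forwardProject`) marches each source-to-bin ray across the
image with bilinear interpolation at a step of half the image pixel, so it
is exactly linear in the image — the property the compensation identity
relies on.  Line integrals are dimensionless (`mu [1/cm] * path [mm] / 10`).
An `oversample` argument averages several sub-rays across one detector bin
aperture; this models the detector's area integration and is used for the
bar-pattern insert, whose 50 um structure would otherwise alias at the
0.055 mm effective sampling instead of blurring.

`fanFBP` applies cosine pre-weighting, a band-limited ramp filter on the
detector coordinate rescaled to the isocenter plane (zero-padded FFT of at
least twice the detector length), and distance-weighted backprojection.
A Hann apodization window is the default (`ram-lak` is available); the
window choice trades resolution for ringing and is deliberately the same
for every reconstruction that is compared to another one.  Pixels outside
the scanned field of view — through which no complete set of rays passes —
are set to zero rather than left with arbitrary values; without this mask
the out-of-view rim of the global reconstruction would be reprojected into
the background estimate and bias it visibly.

`directInteriorFBP` exists to demonstrate the failure mode: it pads each
truncated row with its edge value over one filter-support width and runs
the same FBP.

## Geometry relations

For source-to-isocenter distance `a` and isocenter-to-detector distance
`b` (`c = a + b`), the detector magnification is `M = c/a` and the
focal-spot magnification `M' = c/b`.  The system resolution model combines
the effective detector pixel `d` and the focal spot `x` referred to the
object plane:

`r = sqrt((x / M')^2 + (d / M)^2)`.

The focal-spot term equals the classical penumbra `x (M − 1)/M` because
`(M − 1)/M = 1/M'`.  With `x = 50 um`, `d = 110 um` (a 55 um detector in
2x2 binning) and `M` adjustable between 1.60 and 2.67 (`a`, `b` each in
150–250 mm), the model predicts a resolution close to 50 um and a field of
view between 26 and 44 mm for a 70.4 mm sensor — the regime the package's
default study emulates at `a = b = 200 mm`, `M = 2`.

## Misalignment model

Registration between the global and local frames is never perfect.  The
package injects the three first-order registration errors directly into
the *assumed* geometry used for background reprojection
(`applyMisalignment`):

* **isocenter offset** (mm, along the fixed laboratory x axis): the
  assumed rotation center is shifted;
* **initial view-angle offset** (degrees): added to the assumed start
  angle;
* **magnification error** (fraction): the assumed detector coordinate
  scale is multiplied by `1 + m`, which is how an erroneous `M` enters the
  mapping between the reprojected background and the local detector.

The reprojected background is *labeled* with the nominal geometry, so the
perturbation appears downstream exactly as a mis-registration would: the
estimate is shifted, rotated or scaled relative to the data it is
subtracted from.  The sign convention of the magnification error is fixed
by the phenomenon it must reproduce: an *assumed* magnification
`M (1 + m)` maps detector bins to object-plane coordinates scaled by
`1/(1 + m)`, and the radius of the accurately reconstructed region then
scales by `1 + m` (the "effective ROI") — shrinking for negative `m`.
That is why the magnification sweep is evaluated at
16.8 mm = 21 mm x 0.8, the intersection of all effective ROIs in the
−20 %…+20 % range.

## The synthetic head phantom

The study phantom replaces a real head slice with a generated one
(`makeHeadPhantom`): an elliptical skull ring of cortical bone (1500 HU)
around soft tissue (40 HU) with a seeded smooth random texture (+-25 HU
Gaussian blobs), a frontal air sinus, and a dense temporal-bone-like disk
of 30 mm radius at the isocenter containing a soft-tissue inclusion, two
air cells inside the ROI, and a ring of mastoid-like air cells at 26 mm —
so that, as in temporal-bone anatomy, structured dense bone crosses the
ROI boundary (air = −1000 HU maps to exactly 0 cm^-1).  Tissue values are
implementer-chosen within clinical ranges; attenuation uses an effective
monoenergetic water value of 0.2 cm^-1, the scale on which published
interior-CT error tables place their ground truth.

Tissue boundaries are rendered with 3x3 partial-volume supersampling and
then band-limited with a fixed 0.35 mm Gaussian: the head emulates an
object whose finest content a standard CT scan can actually represent
(the study this package models builds its phantom by bicubic upsampling
of a ~0.5 mm image, so it is band-limited the same way).  Genuine
sub-resolution detail lives in the separately rendered bar-pattern insert
(`embedBarPatterns`; groups of four bars separated by equal gaps, 600 HU
amplitude, 50 and 75 um widths by default, partial-volume coverage along
the modulation axis).

Blob parameters are drawn once per seed, independent of the grid, so the
same object can be rendered at any pixel size; phantom generation is
bitwise reproducible per seed.  What the generator does *not* emulate:
polychromatic spectra and beam hardening, scatter, detector cross-talk,
anatomical detail beyond the shapes above, and 3D structure.  Passing
tests therefore demonstrate the geometry and compensation machinery, not
clinical image quality.

## Desk-scale study sizes

The default study (`defaultStudyConfig`) uses sizes chosen so a full
acceptance run completes on a single CPU in minutes while keeping the
published scan protocol: global scan at 1.024 mm detector pitch with 824
bins and 1440 views; local scan at 0.11 mm pitch over a 35.05 mm window
radius with 1440 views; ROI radius 23 mm; metrics at 21 mm.  Two global
sampling choices matter more than they might appear.  The detector must
be wide enough that the whole head shadow — up to ~209 mm at the
isocenter plane for this head — stays on the detector: a truncated
*global* scan defeats its purpose, and reprojecting the out-of-view rim
of an under-covered reconstruction biases the background estimate
severely.  And the view count must sample the full head adequately at the
global pitch (a clinical scanner acquires on the order of a thousand or
more views per rotation): with only 720 views the angular-aliasing field
of the global reconstruction couples coherently into the reprojected
background and dominates the compensated image's error budget.  The head is rendered at 0.125 mm for projection (1680^2) plus a
0.025 mm bar insert (520^2), the global reconstruction at 0.498 mm
(424^2), and the high-resolution reconstructions at 0.025 mm (2048^2).
The misalignment sweeps run at reduced sampling — 720 local views and
768^2 at 0.06 mm — since they compare error *trends*, not absolute
resolution.  The regression tests use a further-reduced copy of the same
setup (0.22 mm local pitch, 384^2 at 0.12 mm).

By linearity, the head render and the bar insert are projected separately
(the insert with 3x aperture oversampling) and their sinograms summed;
this keeps genuine sub-pixel detail in the patterns without rendering the
whole head at 0.025 mm.

## Background estimation choices

The background is reprojected at the LR global detector pitch with a
subsampled view set ("following the local geometry", but at the sampling
the global data can support), then interpolated to the local sampling:
natural cubic splines along the detector axis, linear interpolation along
the view axis with periodic wrap.  Both axes are interpolated; residual
high-frequency estimation errors largely cancel during backprojection, and
a direct high-resolution reprojection is kept available
(`lrPitch = local pitch`, `viewStride = 1`) as the in-package oracle the
tests compare against.  The LR detector covers 1.3x the local window so
that shifted or rescaled assumed geometries still interpolate rather than
extrapolate; extrapolated bins, if any, are edge-filled and flagged.

## Bias correction

Residual global shifts — dominant under magnification error — are removed
by `biasCorrect`: subtract the difference between the mean over a region
of known attenuation and its target value.  The default reference is a
small disk inside the air cell of the temporal-bone region, with target
0 cm^-1.  The reference must lie *inside* the ROI because the compensated
reconstruction is quantitative only there; an air region elsewhere in the
local window would sample the non-quantitative background-free zone.  A
flat-region mean taken from the global reconstruction works the same way
through the `target` argument.  The correction changes no pixel
difference: output minus input is spatially constant.

## Numerical choices and edge cases

* Ramp filter: discrete band-limited kernel; FFT length is the next power
  of two at least twice the detector count, suppressing interperiod
  artifacts.
* Truncation keeps the central contiguous bins spanning the requested
  width about the central ray, honoring any detector offset; the kept
  window's coordinates are preserved exactly so compensation subtracts
  bin-for-bin.
* Poisson noise (off by default; no level is part of the study design)
  draws transmitted counts at `I0 e^{−p}` and clamps zero counts to half a
  photon before the log.
* Degenerate inputs error early: nonpositive distances, empty images or
  masks, partial angular ranges in FBP, windows that do not cover the ROI.
* Quality metrics: MSE/PSNR/RMSRE/SSIM over a circular mask; RMSRE
  excludes air via a 0.01 cm^-1 ground-truth threshold (relative error is
  undefined at zero attenuation); PSNR uses the masked ground-truth peak;
  SSIM follows the conventional Gaussian-window formulation (11x11,
  sigma 1.5, K1 = 0.01, K2 = 0.03) with the ground-truth dynamic range,
  matching the standard reference implementation on full images.

## Known limitations

* Monoenergetic, noise-free-by-default forward model; no scatter, no
  polychromatic effects, no detector physics beyond aperture integration.
* 2D only; the published workflow's surface-scanner registration chain is
  replaced by ground-truth alignment plus injected misalignment
  parameters, which is the quantity the robustness study actually varies.
* The quality of the compensated image near the ROI boundary depends on
  the global reconstruction's fidelity there; metrics use evaluation radii
  strictly inside the ROI for that reason.
* Full-scan (360 degree) trajectories only; short-scan weighting is not
  implemented.
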