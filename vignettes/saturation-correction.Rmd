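---
title: "Depth-guided correction of detector saturation in short-scan cone-beam CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-guided correction of detector saturation in short-scan cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctsat)
```

## The problem

Flat-panel detectors in C-arm cone-beam CT have a limited dynamic range.
When a thin body part such as a knee is scanned, X-rays crossing the thin
exterior are barely attenuated and drive the detector past saturation: the
recorded value in those pixels no longer reflects the line integral
$\int \mu \, dl$, and after the vendor's nonlinear preprocessing it can
collapse to almost nothing. In the reconstruction the object's outer rim
blurs, streaks appear at the onset of the overexposed bands, and regions of
diagnostic interest near the surface (e.g. the patella) become unreliable.

`cbctsat` implements, end to end and against a fully synthetic test bench,
a correction that uses a consumer depth camera (a Kinect-class RGB-D
sensor) rigidly mounted near the scanner:

1. **Cross-calibration.** A sphere-scaffold phantom observed by the depth
   camera yields the rigid transform from camera coordinates to CT
   coordinates.
2. **Surface modeling.** During the scan, denoised depth frames of the
   patient/phantom give a 3-D surface cloud in CT coordinates.
3. **Projection-domain extrapolation.** For every detector row of every
   view, the surface cloud is sliced by the plane through the X-ray source
   and that row, closed cubic B-spline curves are fitted to the slice, and
   the beam-path length of each ray through the curves becomes the template
   for extrapolating the saturated pixels from their reliable neighbors.
4. **Reconstruction.** A standard short-scan FDK chain (cosine weighting,
   Parker redundancy weighting, Shepp-Logan ramp filter, voxel-driven
   backprojection, Hounsfield scaling, bilateral smoothing) turns the
   corrected projections into volumes, evaluated with circular ROIs at the
   phantom exterior.

Everything runs on simulated data: an analytic phantom bench
(`simulate_projections()`, `render_depth()`) replaces the physical scanner
and camera, which makes every stage quantitatively checkable against
ground truth.

## The simulation bench

The scan geometry follows a clinical C-arm short scan: source-detector
distance 1200 mm, source-axis distance 600 mm, 133 views over 200 degrees,
and a 1240 x 960 flat panel with 0.308 mm pitch. For desk-scale runs the
detector grid is downscaled by an integer factor (default 10x: 124 x 96
pixels at 3.08 mm) while keeping the physical aperture, so fan and cone
angles — and therefore the artifact geometry — are unchanged. All study
sizes below refer to this 10x grid, the package's default problem size.

The "knee" phantom is two water-attenuation cylinders
($\mu_w = 0.02\,\mathrm{mm^{-1}}$, radius 36 mm, separation 112 mm) with
two dense rods (10x water) standing in for bone between them. The bottle
radius and separation are chosen so the phantom spans the full lateral
field of view of the printed geometry (FOV radius $\approx$ 94 mm at the
isocenter) without crossing it: a larger phantom would add lateral
truncation, a different artifact from the one under study. The rods are
flagged invisible to the depth camera (structured-light sensors fail on
dense IR-dark or specular materials, and rays hitting them first return
invalid depth); without that flag, rod surface points seen through the
inter-bottle corridor would corrupt the per-slice clustering.

Saturation is modeled in the line-integral domain: pixels with
$p < p_\text{sat}$ (default 0.85, i.e. chords shorter than about 42 mm of
water) are recorded as 0 and masked; a band of width 0.2 above the
threshold is compressed toward it by a smooth quadratic roll-off, emulating
the vendor preprocessing that drives near-saturated values down. With the
default phantom this clips roughly the outer fifth of each bottle's chord
profile and the whole air background — the same structure as a real
overexposed knee scan.

The depth camera is an ideal pinhole with Kinect-like intrinsics (320 x 240
at f = 290 px, i.e. a 2x-downscaled VGA depth sensor), 700 mm mean
distance, and per-frame Gaussian depth noise (default 5 mm per frame over
20 frames; real Kinect-1 noise is ~25 mm point-to-plane at 1 m, which the
20-frame temporal averaging brings to a comparable working level).

One camera is rigidly mounted and observes *both* the calibration
scaffold and the scanned object — that is the whole point of the
cross-calibration, and the transform it produces is only valid for frames
from that same mount. The default pose (10 degrees azimuth off the
frontal axis, 30 degrees elevation, 700 mm range) balances two competing
constraints: the scaffold's away-pointing rod needs an oblique view (at
azimuth zero its spheres hide behind the vertical rod, and at low
elevation behind the mount cylinder), while the mirror completion of the
knee surfaces wants a frontal view (the union of a visible arc and its
y-mirror only closes when the viewing azimuth is small; at 35 degrees a
~70 degree wedge of each cross-section goes unmodeled and the correction
degrades at the views whose rays cross that wedge).

## Cross-calibration

The calibration phantom is a cylinder (the CT-side calibration phantom
acting as mount) carrying three orthogonal rods with three spheres each
(radius 20 mm, at 80/140/200 mm along each axis). The inner offset keeps
every sphere clear of the mount and the 60 mm spacing keeps the
region-growing segmentations of neighboring spheres disjoint.

Per sphere, a seed pixel (emulating the operator's click) grows a
4-connected region over pixels whose back-projected 3-D point stays within
$1.2\sqrt{2}\,r$ of the seed point — $\sqrt{2}\,r$ is the seed-to-rim
distance of the visible cap, and the factor 1.2 adds noise slack without
reaching a neighboring sphere. The sphere center then minimizes the
geometric residual $\sum_i (\lVert p_i - c \rVert - r)^2$ with the radius
known from the phantom specification (Gauss-Newton, initialized from the
clicked pixel and the mean depth plus half a radius). Fitting the radius
too would be ill-conditioned on a partial cap; the distance-minus-radius
residual is also the only reading under which that initialization makes
sense.

Axis directions come from orthogonal distance regression (SVD of the
centered center matrix), with the sign fixed by the click order; the
scaffold origin is the closest point to the three axes in closed form,
$g = \left(\sum_i (I - v_i v_i^T)\right)^{-1} \sum_i (I - v_i v_i^T)
\bar c_i$; and the rotation is the proper orthogonal Procrustes solution
mapping the three fitted directions onto the CT basis. Fitted axes are
never exactly orthogonal, so projecting onto the rotation group is
preferred over composing the raw directions; the dominant in-plane
rotation is reported separately for diagnostics.

### Depth denoising choices

The denoising pipeline is temporal averaging (20 frames, invalid samples
excluded), then spatial smoothing (Gaussian footprint, $\sigma = 2.5$ px),
then guided filtering (4 px support) with the smoothed depth as its own
guide. Two choices matter and are easy to get wrong:

* **The spatial stage is range-weighted (bilateral).** Plain Gaussian
  convolution of a depth map mixes values across true depth
  discontinuities; at an object rim this drags grazing-incidence points
  toward the camera by many millimeters, which flattens sphere caps
  (biasing the calibration) and shortens the visible arcs of the scanned
  object (biasing the mirror completion below). The range kernel's scale is
  tied to the measured noise (3x the post-averaging temporal standard
  deviation), so smooth regions see an ordinary Gaussian while rims are
  left in place. The guided-filter regularization is tied to the same
  estimate, for the same reason.
* **Denoising strength follows measured noise.** The per-pixel temporal
  variance over the frame stack estimates the sensor noise; when it is
  negligible there is nothing to denoise and the spatial stages are
  skipped. On noiseless synthetic frames the pipeline is then exactly the
  identity, and calibration recovers a known camera pose to numerical
  precision — a useful end-to-end zero check. With a single frame no
  estimate exists and the spatial stages always run.

On the default bench (noise 5 mm, 20 frames), calibration recovers a known
pose to about 0.1-0.35 degrees and 0.3-0.8 mm across seeds; both errors
fall monotonically with the noise level (the test suite checks
{10, 5, 2, 0} mm).

## Projection-domain correction

For one view and one detector row, all rays lie in the plane through the
source and the row's pixel centers. The correction then works entirely in
2-D:

* **Slice.** Cloud points within 1.5 mm of the plane are projected into
  plane coordinates (first axis along global x, second with positive
  global-y component). The default slab half-thickness covers the detector
  row footprint at the isocenter (~0.8 mm) and the typical depth-sample
  spacing (~2.4 mm at 700 mm range), so a slab always catches at least one
  ring of surface samples.
* **Cluster.** Single-linkage clustering at 25 mm separates the two knees
  (the default phantom leaves a 40 mm clearance); clusters below 6 points
  are discarded as stray samples.
* **Mirror.** A single camera sees only the front surface. Each cluster is
  completed by reflecting it about the line through its deepest visible
  point, parallel to the world x-z plane. This is the method's main
  geometric approximation: the reconstructed back side is only as round as
  the front, and the mirror height sits slightly forward of the true
  silhouette (the camera never quite sees the rim), so back-side path
  lengths are systematically a little short. A second camera would remove
  the need to mirror (`mirror = FALSE` in `correction_params()`).
* **Fit.** One closed periodic cubic B-spline per cluster (16 control
  points, angular ordering around the centroid, a small second-difference
  ridge on the control polygon for sparse slices).
* **Profile.** The beam-path length of each ray is the total length of its
  intersection with the curve interiors (even-odd rule per curve, summed
  over curves; crossings found on a dense polygonal sampling, 256 edges
  per curve — tangential grazes produce near-coincident crossings whose
  interval length vanishes, so no special casing is needed).
* **Detect and extrapolate.** Saturated runs are read off the mask; each
  run's flanking normalization value is the mean of the 5 last reliable
  pixels after skipping 3 pixels of roll-off (`k_norm`/`k_skip`). The run
  is replaced by `s(x) * profile(x)` with `s(x)` blending linearly between
  the two end scales; each end scale is normalization value divided by the
  mean profile *over the same pixel window*, so the ratio is an effective
  attenuation measured where the data are reliable (pairing a window
  average with a single-pixel profile would bias the scale where the chord
  changes quickly). Edge-touching runs use the single available scale. A
  window whose modeled path is near zero — or small compared to the run it
  would scale (below 20% of the run's peak profile) — cannot anchor an
  extrapolation and the run is skipped with a flag; rays that miss the
  surface model are set to 0.

Rows with no reliable slice (too few points, fully saturated) pass through
unchanged and are flagged in the status table; the correction never
modifies unsaturated pixels.

On the default clipped bench the corrected stack beats the saturated one
in RMSE over the masked pixels at every one of the 133 views, and about
84% of all saturated pixels end up within 20% of their true line
integral (air pixels count only when restored exactly to zero; over 99%
are). The residual errors concentrate where the mirror approximation is
worst: the visible rim sits slightly forward of the true silhouette, so
the mirrored model misses a posterior band of the object, and rays that
only cross that band — roughly the deeper half of the saturated object
pixels at lateral views — keep their uncorrected zero. This is the
single-camera limitation in its purest form; the projection- and
image-domain improvements above are what the method buys despite it.

## Reconstruction and evaluation

The FDK chain is standard. Cosine weighting uses the physical pixel
offsets; Parker weights use the half-overscan
$\Gamma = (\text{range} - \pi)/2$ with the smooth $\sin^2$ transition, so
conjugate rays weight to exactly one (the scan must cover at least 180
degrees plus the full fan angle); the Shepp-Logan kernel
$h[n] = -2 / (\pi^2 \tau^2 (4 n^2 - 1))$ is applied row-wise by FFT with
zero padding to twice the row length; and the voxel-driven backprojector
accumulates bilinearly interpolated detector samples with the
$\mathrm{SAD} \cdot \mathrm{SDD} / t^2$ distance weight and angular step
range/(n-1). On an unclipped uniform water cylinder the chain recovers the
interior attenuation to well within 1% (the test suite asserts 7%), and
the reconstruction is linear by construction.

Volumes are normalized to Hounsfield units with the simulator's
$\mu_w$ and smoothed with a per-axial-slice bilateral filter (5-voxel
window, 500 HU photometric scale, spatial sigma of width/4). ROI
statistics (mean, population standard deviation, min, max) are taken over
circular ROIs on the central slice; the default layout places five ROIs of
7 mm radius at 0.72 bottle radii toward the lateral, anterior and
anterolateral rims — the saturation-destroyed exterior band on the side
the camera models. The posterior band is deliberately not an evaluation
ROI: it is the single-camera blind side discussed above, where the
correction leaves most pixels untouched and ROI statistics sit at the
uncorrected level. The default grid is 64^3 at 3 mm voxels (the grid is a
configuration value; the printed geometry implies nothing about it).

On the default bench the corrected reconstruction moves the ROI means
closer to the ground-truth reconstruction in all five ROIs and reduces the
ROI standard deviation in all five — the uncorrected volume shows means
~95-160 HU too high with spreads of 230-590 HU, the corrected one sits
within ~12-90 HU of truth at spreads of 12-250 HU. ROI statistics taken in
the posterior band instead sit at the uncorrected level, which is why that
band is reported as the limitation rather than averaged into the
evaluation.

## Numerical and degenerate-input policy

* Rays are full lines against closed-form sphere/finite-cylinder
  intersections (slab-clipped quadratic); misses contribute zero.
* `estimate_origin()` refuses configurations whose projector sum is
  ill-conditioned (condition number above 1e8, e.g. three near-parallel
  axes); `build_transform()` refuses axis triples far from orthogonal
  (pairwise |dot| > 0.2).
* Sphere fits require at least 10 points and error out on coincident
  points or non-convergence; region growing errors on invalid seeds.
* The saturation model records its parameters on the stack; re-applying
  the identical model is a no-op (recorded values are no longer line
  integrals, so re-thresholding them would be meaningless).
* All stochastic operations take explicit seeds; noiseless paths are
  deterministic and byte-stable on disk.

## What the synthetic bench does and does not show

The bench emulates the geometry and the failure mode — saturated exterior
bands, a nonlinear roll-off next to them, noisy depth data, a single
camera seeing one side — with monochromatic pencil-beam physics, ideal
pinhole optics and additive Gaussian depth noise. It does not model
scatter, beam hardening, detector blur or lag, lens distortion,
depth-dependent or structured Kinect noise, patient motion, or the
vendor's actual preprocessing curve. Passing the suite therefore shows the
algorithm chain is correct and effective under the stated model; it does
not certify performance on clinical data. The known structural limitation
— mirror completion of the unseen back side — is visible in the bench
exactly as in practice: correction quality is lowest for rays probing the
mirrored side, and a two-camera setup is the natural upgrade path.

## Problem sizes

Default study sizes, chosen as the package's desk-scale working point: 10x
downscaled detector (124 x 96) with all 133 views for projection-domain
work; 64^3 at 3 mm for volumes; 320 x 240 depth frames, 20 per stack. The
workflow tests in `tests/testthat/` run a further-reduced variant (20x
detector, 21 views, 32^3) so the full four-command pipeline stays cheap.
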