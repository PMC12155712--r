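---
title: "Motion-corrected multi-volume OCT fusion and longitudinal SDD tracking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected multi-volume OCT fusion and longitudinal SDD tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

octfuse processes multi-volume orthogonal raster OCT acquisitions of the
macula: several volume scans acquired back to back with alternating fast
axes are motion-corrected per A-scan, illumination-corrected, flattened
to Bruch's membrane (BrM), and merged into a single high-SNR volume from
which averaged en face slabs are projected. Dot-form subretinal
drusenoid deposits (SDDs) are then detected on the slabs and tracked
across visits. This vignette explains the models behind each stage, the
parameters that matter, and the limits of what the bundled synthetic
data can show.

## The acquisition model

An acquisition is described by an `acquisition_protocol()`: a square
field of view scanned as `n_fast` A-scans per B-scan and `n_bscans`
B-scans per volume, with consecutive volumes alternating the fast axis
between x and y. The default protocol is a 6 × 6 mm field at 500 × 500
A-scans (12 µm transverse spacing), 2.4 s per volume and six volumes.
The per-A-scan timestamp model is

```
t = volume start + bscan_index * (vol_duration / n_bscans) + ascan_index / ascan_rate
```

so fast-axis flyback is folded into the B-scan period. The inter-volume
gap defaults to 0.04 s, which makes six 2.4-s volumes span 14.6 s in
total. Axial sampling defaults to 2 µm/voxel, finer than the 2.7 µm
axial resolution class of instrument being emulated; both are
configurable.

## The retinal phantom

`make_phantom()` renders a layered reflectivity grid: Gaussian bands for
the ILM, the photoreceptor IS/OS junction (ellipsoid zone), the RPE and
BrM, riding on a shared smooth undulation (a Gaussian random field,
default 25 µm peak amplitude with 600 µm correlation length), plus
diffuse inner-retina and choroid fill. Three features give the phantom
the transverse structure that real retinas have and that registration
and illumination estimation rely on:

* a multiplicative reflectivity texture (default 20 % relative sd,
  120 µm correlation length) shared by all layers of a column, emulating
  en face tissue granularity;
* a network of inner-retinal vessels whose shadows attenuate everything
  posterior to the inner retina (default 18 vessels, 45 % attenuation).
  Vessel shadows are the dominant en face registration anchor in real
  OCT, and without them the slow-axis component of motion estimation is
  fundamentally ill-conditioned — a layered retina is nearly
  shift-invariant along the slow axis;
* optional soft drusen (dome-shaped RPE elevations that leave BrM in
  place) and dot SDDs. An SDD is a reflective ball resting on the RPE;
  stage 1 deposits leave the IS/OS unchanged, stage 2 deposits locally
  elevate it, and stage 3 deposits additionally reduce IS/OS
  reflectivity above the deposit.

Eye motion is a per-volume `motion_trace`: an integrated Gaussian random
walk per axis (default 10 µm/√s transverse, 2 µm/√s axial, integrated at
1 ms resolution and stored as piecewise-linear knots) plus a Poisson
process of instantaneous transverse saccades (default amplitude
60 ± 15 µm). `acquire()` samples the phantom at each A-scan's nominal
position minus the displacement at its acquisition time, then applies
multiplicative illumination bias, multiplicative gamma speckle (default
contrast 0.35) and additive detector noise (default sd 0.01). These
defaults are the package's standing synthetic study conditions; all
ground truth (traces, surfaces, SDD lists, bias fields, blink ranges) is
retained for testing and can be serialized bit-exactly with
`write_ground_truth()` (doubles are stored as full-precision strings, so
a write/read cycle is the identity).

What the simulator does *not* model: beam propagation and defocus,
depth-dependent roll-off, rotational/torsional eye motion, intra-A-scan
motion, vascular flow (OCTA), and pathology beyond drusen and dot SDDs.
Passing tests therefore demonstrate correctness of the algorithms under
realistic geometry, noise statistics and motion, not clinical
performance on patient data.

## Blink removal

Blinks zero out whole B-scans. `detect_blinks()` flags B-scans whose
mean intensity falls below 0.3 × the median B-scan mean — a relative
criterion, so detection is invariant to global intensity scaling; a
volume whose median B-scan is itself at the noise floor is rejected as
unusable. Masked B-scans are retained in the data (the motion model
needs the timing continuity) but never contribute samples to any
estimation stage.

## Motion estimation

Eye motion within each volume is modelled as a continuous, time-dependent
3D displacement function with one control point per B-scan period,
interpolated in time (cubic by default). The A-scan is the motion-free
primitive axially; the orthogonality of the fast axes across volumes is
what makes all three displacement components observable.

The estimator minimizes the sum over volumes of squared log-intensity
differences between each volume resampled at displacement-corrected
positions and a reference gridded from the motion-corrected volumes of
the *orthogonal* direction, by multi-resolution block-coordinate
descent (pyramid factors ×4, ×2, ×1 along the fast axis, with the depth
axis halved on the coarse levels). Block-coordinate descent over
per-B-scan shifts was chosen over generic quasi-Newton iterations on all
control points at once: each block subproblem is a tiny, well-understood
search whose solution is exact, the scheme is deterministic, and its
cost is dominated by reusable SSD evaluations. A mild Gaussian pre-blur
(σ = 0.8 voxels in depth and fast axis) tames speckle-driven peak
locking of the SSD minima. Each level runs, per volume:

1. **Rigid stage** — a whole-volume 3D shift from the aggregate SSD over
   all B-scans, which resolves volume-level offsets robustly.
2. **Slow-axis stage** — a single B-scan barely constrains its own
   slow-axis position, so the slow-axis drift is estimated from
   overlapping windows of B-scans (about eight windows per volume),
   each aggregated into one well-conditioned search, robust-fitted over
   window centres and interpolated across the volume. Axial offsets are
   marginalized out of the slow-axis profile because axial misalignment
   otherwise leaks into the transverse estimate through the layer
   slope. This stage runs on the speckle-averaged pyramid levels only;
   at full resolution speckle dominates its SSD contrast.
3. **Per-B-scan residual stage** — fast-axis and axial refinement with
   half-voxel search steps and per-axis marginalized SSD profiles. The
   per-B-scan estimates carry a confidence (the SSD curvature at the
   minimum) and are fused by a confidence-weighted second-difference
   penalized least-squares fit per axis (`mu = 2` relative to the mean
   confidence), with one outlier-downweighting pass. Saccades survive
   this smoothing because candidate steps are detected on a median
   prefilter and the penalty is never applied across a detected step.
   The residual search spans ±3 level-voxels at the coarsest level — so
   saccade-sized jumps are captured where the rigid stage has just
   centred the volume — and ±1 at the fine levels.

The registration objective is invariant to a common constant added to
all volumes' displacements; the estimate is gauge-fixed by constraining
the mean displacement over all volumes to zero per axis. After every
pyramid stage the objective is re-evaluated (on a 2× downsampled pyramid
for cost) and a stage that failed to improve it is rolled back, which
makes the reported objective trace non-increasing by construction. If
the final relative improvement is large (the schedule was still
descending when it ran out of levels) the model is returned with a
convergence warning.

`correct_volume()` applies a model (or a ground-truth trace) purely
geometrically: every unmasked A-scan's nominal position is shifted by
minus the displacement at its timestamp; intensities are untouched.

## Illumination correction

Illumination bias is modelled per volume as a positive gain varying
smoothly along each B-scan's fast axis: eight control points per B-scan,
linearly interpolated, estimated from the log-intensity disagreement
between the volume's motion-corrected A-scans and the mean reference
gridded from all volumes. Continuity along the slow axis arises
implicitly through the orthogonal volumes in the reference, and is
reinforced by smoothing the control values across B-scans (consecutive
B-scans are milliseconds apart). The small control-point count is the
feature-preservation mechanism: variation faster than the control
spacing cannot be represented, and the per-A-scan log-ratios are
averaged over one control interval before the fit so fast structure
cannot bleed into the edge control points either.

Only relative gains between volumes are observable: any smooth
transverse field attributed to *all* volumes at once leaves the data
unchanged. The estimate is therefore gauge-fixed to zero mean log gain
per position, which also makes apply-then-re-estimate a fixed point.
Cross-volume comparisons should use `gain_field_image()`, which expands
each volume's curves into the common transverse frame. Overall
brightness is handled separately: `match_brightness()` computes a
scale-equivariant robust mean per volume (mean of voxels between the
volume's own 50th and 90th percentiles) and scales every volume up
toward the brightest one, so all scale factors are ≥ 1.

## BrM segmentation, flattening and fusion

BrM is found per B-scan by a deterministic dynamic-programming shortest
path: one depth per A-scan, slope-limited to 2 axial voxels per A-scan,
through a cost image that rewards bright voxels and penalizes bright
signal strictly deeper than the candidate (with an 8 µm guard gap so a
band's own posterior tail does not penalize its centre). The threshold
for "bright" is relative to each column's robust maximum, because the
reflectivity texture scales all bands of a column together. This makes
the path follow the posterior-most bright band — BrM — and stay put
underneath drusen. A sub-voxel band centre is refined by an
intensity-weighted centroid. The posterior RPE edge (pRPE) is then
located per A-scan as the strongest negative axial gradient between the
RPE brightness peak (searched up to 120 µm above BrM, enough for large
drusen) and BrM, followed by a running-median smoothing.

Per-volume surfaces are displacement-corrected and averaged on the
common transverse raster (`mean_surface()`); holes (blinked B-scans,
uncovered corners) are filled by nearest-valid interpolation before
flattening. `flatten_and_merge()` shifts every sample axially so the
reference surface lands on a constant target row — by default 75 % of
the axial extent, leaving the retina above and a choroid margin below —
and bins all volumes' samples into the output grid with trilinear
weights; voxel intensity is the weighted mean and the accumulated
weights are stored as per-voxel contribution counts. Mean (rather than
median) combination maximizes the SNR gain of averaging; with six
independently speckled volumes the background noise sd drops by about
1/√6.

## En face slabs

A slab is the set of voxels in the half-open interval
`[lower, upper)` µm *above* (anterior to) the flattened reference
surface; the default is the 50 µm slab from 27 to 77 µm above BrM used
for dot-SDD grading. The half-open convention keeps adjacent slabs
disjoint, so sub-slab means combine exactly to the full-slab mean.
Projection is the unweighted mean over in-range voxels with positive
contribution count; pixels with no valid voxel are masked. Referencing
the posterior RPE instead (via `fuse_to_reference()`) removes soft-druse
elevation from the slab. The projection statistic is the mean; an
"averaged" slab admits either mean or median, and the mean is both the
natural companion of mean-combined fusion and exactly verifiable against
direct summation.

## Longitudinal tracking

Visits are registered rigidly in 2D: phase correlation for the
translation, then a small-angle rotation refinement (±5° bound)
maximizing normalized cross-correlation, both with parabolic sub-sample
refinement. Pairs whose score stays below the floor (0.2) are reported
unregistrable.

`detect_sdd()` is scale-space blob detection — difference-of-Gaussians
over blob radii 25–125 µm on the background-subtracted slab, local
maxima above a contrast threshold relative to the slab's median
brightness, non-maximum suppression by centre distance, and rejection of
peaks hugging the image border or masked regions. It stands in for the
human grading of the clinical workflow so the tracking logic is testable
end to end.

`classify_changes()` maps baseline detections through the visit
transform and assigns each its nearest follow-up detection within the
match radius (default 60 µm, five transverse voxels — well below typical
dot-SDD spacing). Baselines sharing one nearest follow-up are `fused`;
a mutual nearest-neighbour pair is `stable`; a baseline with no
follow-up within the radius (or whose candidate prefers another
baseline) is `regressed`; unclaimed follow-ups are `new`. Distance ties
break toward the lower detection id, making the output deterministic.
Quadrants are assigned about a configurable fovea (default: slab
centre, since fovea localization is out of scope) under the fundus
convention: smaller row = superior; nasal is toward smaller x for OD and
larger x for OS; ties break toward superior and nasal. Summary
percentages are rounded half-up to one decimal, which reproduces every
printed value from the corresponding counts (e.g. 278/326 → 85.3).

`summarize_changes()` takes an explicit record set and does not decide
how "new" SDDs enter the baseline quadrant distribution — the quadrant
table simply counts the quadrant labels present in the records, so the
caller controls the pooling.

## Numerical choices and degenerate inputs

* All grids use 0-based voxel indices with x the fast axis of an x-fast
  volume and z increasing posteriorly; physical positions are µm at
  voxel centres.
* Trilinear interpolation is used for sampling, gridding and SSD
  scoring throughout; NaN marks holes and any invalid corner
  invalidates a sample.
* Layer-ordering violations after undulation or drusen insertion abort
  phantom rendering with a configuration error rather than clipping.
* An empty sample list, a grid/sidecar dimension mismatch, a slab
  outside the axial range, an unregistrable visit pair, a non-positive
  gain and a non-positive match radius all raise structured errors.
* Empty record sets summarize to zero counts with masked percentages.

## Problem sizes used in the tests

The bundled tests exercise the pipeline on phantoms between 40² and 80²
A-scans, the full-scale motion-recovery checks on a 200 × 200 × 256
phantom with four volumes, and the end-to-end longitudinal scenario on a
120² field with ten baseline SDDs. These sizes were chosen so the whole
suite exercises every code path at realistic noise levels while staying
comfortable to run on a laptop; the algorithms themselves are
size-agnostic and run unchanged on full 500 × 500 × 6 acquisitions.

## Known limitations

* Torsional eye motion and transverse scan-field distortion are not
  modelled or corrected; the displacement model is pure translation per
  time point.
* The slow-axis displacement component is estimated at window
  resolution (roughly an eighth of a volume), so slow-axis saccade
  components are recovered as short ramps rather than sharp steps.
* The BrM finder assumes BrM is the posterior-most bright band; severe
  choroidal hyperreflectivity could distract it.
* SDD detection is intentionally simple (isotropic blobs); ribbon-form
  SDDs and confluent deposits are out of scope, as is automated stage
  grading from B-scans.
* "Stable" means present at both visits within the match radius; growth
  or shrinkage of a stable deposit is not measured.
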