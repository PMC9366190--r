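---
title: "Detecting LV wall motion abnormalities from volume renderings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting LV wall motion abnormalities from volume renderings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Regional wall motion abnormalities (WMA) of the left ventricle — segments of
the wall that contract weakly (hypokinesis) or not at all (akinesis) — are an
independent predictor of adverse cardiac events. ECG-gated cardiac 4DCT
captures the full 3D motion of the LV blood pool over a heartbeat, but the
conventional reading workflow reformats the 4D data into 2D short- and
long-axis planes, where through-plane motion confounds the assessment.

`vrwma` implements an alternative pipeline: dynamic *volume renderings* (VR)
of the isolated LV blood pool, viewed from six fixed angles around the long
axis, turn the 4D dataset into six short grayscale videos in which regional
endocardial motion is directly visible. A sequence classifier then decides,
per video, whether a wall motion abnormality is present; a simple counting
rule aggregates the six video calls into a study-level call. Ground truth
comes not from human readers but from a quantitative strain surrogate
computed on the segmented blood pool: regional shortening,

$$RS_{CT} = \frac{Area_{ES}}{Area_{ED}} - 1,$$

the fractional change of a local endocardial patch area between end-diastole
(ED, largest blood-pool volume) and end-systole (ES, smallest). Healthy
myocardium shortens the endocardium, making $RS_{CT}$ clearly negative;
patches with $RS_{CT} \ge -0.20$ are treated as impaired. A video is labeled
abnormal when more than 35% of its visible endocardial pixels are impaired
(strict inequality), and a study is abnormal when at least 2 of its 6 videos
are abnormal. All three thresholds are configurable
(`rsct_cut`, `frac_cut`, `study_cut`).

Because no clinical cohort ships with the package, every quantitative claim
is exercised on a synthetic 4D LV phantom with analytically known regional
shortening, plus the published confusion-matrix counts of the clinical
validation cohort bundled as reference data (`clinical_reference_counts()`).

## The phantom and its deformation model

The phantom (`phantom_spec()`, `generate_study()`) models the blood pool as
a truncated ellipsoid: semi-axes $(a, a, b)$ (defaults 25 and 45 mm), apex
at the bottom, cut by a flat basal plane at half the upper semi-axis. Voxels
inside the surface receive contrast-enhanced blood intensity (520 HU by
default, matching the median blood-pool intensity of clinical studies) plus
Gaussian noise (`noise_sd`, default 30 HU); the background stays exactly at
`background_hu`, because the pipeline's inputs are already blood-pool
isolated images.

Wall motion is a *direction-dependent similarity scaling about the ellipsoid
centre*: a surface point at azimuth $\varphi$ and apex-to-base fraction $v$
moves as $X \mapsto C + s_t(\varphi, v)\,(X - C)$. This choice is the key to
an exact analytic oracle: wherever $s$ is locally constant, a surface patch
scales by $s$ in *both* tangent directions, so its area scales exactly by
$s^2$ and

$$RS_{CT}(\varphi, v) = s_{ES}(\varphi, v)^2 - 1$$

in closed form (`analytic_rsct()`). A radius-only contraction would instead
leave meridional lengths unchanged and give an area ratio closer to $s$ than
$s^2$; the similarity scaling also produces the physiological long-axis
shortening of a real LV. With the default ED-to-ES contraction
$s = 0.8$ the normal wall has $RS_{CT} = -0.36$ and the ejection fraction is
$1 - 0.8^3 \approx 0.49$.

Defects are angular sectors (`defect_spec()`): inside a sector the local
scale is raised toward 1 in proportion to `severity`
($s = g + (1-g)\,\sigma$, so severity 1 is akinetic, $RS_{CT} = 0$).
Sector edges use a raised-cosine transition over 10 degrees (and 0.05 of the
long-axis fraction) so that per-face truth values are stable against mesh
discretisation at the boundary. Severity is monotone by construction:
raising it can only raise $RS_{CT}$ anywhere in the sector.

The temporal profile is a cosine ease from ED (frame 1) to ES and a
symmetric cosine relaxation back over the remaining frames, giving a volume
curve with a unique maximum at frame 1 and a unique minimum at the ES frame,
which is placed at the frame nearest 40% of the cycle (a typical systolic
fraction that leaves at least two interior systolic frames for the
classifier's frame selection). Ten frames per cycle is the default.

The endocardial mesh is built once at ED on a UV grid over azimuth
$\times$ long-axis fraction (96 x 48 by default) and deformed per frame with
the same map, so all frames share topology and face indices — exact surface
correspondence by construction. This stands in for the surface
feature-tracking algorithm used on clinical data, which is prior published
work and out of scope here; the labels depend only on the $RS_{CT}$ values,
which the phantom supplies exactly.

## Orientation and the six views

The canonical frame puts the apex at low $z$, the base at high $z$, and the
anterior wall centred on $+y$ ("12 o'clock"). Wall-centre azimuths, in math
convention, are anterior 90, anterolateral 30, inferolateral -30, inferior
-90, inferoseptal -150, anteroseptal 150 degrees. The six projection views
$\theta = 60n$ pair with foreground walls as anterolateral, inferolateral,
inferior, inferoseptal, anteroseptal, anterior for $n = 0..5$
(`view_table()`); the camera for view $n$ sits on its foreground wall's
azimuth, $30 - 60n$ degrees. The convention is applied uniformly; since the
published description does not fix handedness, this is one concrete
realisation, and the package's own rotation test (rotating the volume by
-60 degrees maps view $n$ onto view $n+1$) pins it down.

`align_long_axis()` maps a landmarked volume (apex, base centre, RV
insertion) into this frame by one trilinear resampling: apex-to-base becomes
$+z$, and the projection of the RV insertion perpendicular to the long axis
is sent to azimuth 180 degrees (mid-septum), which centres the anterior wall
on $+y$. Voxel convention throughout: 0-based indices, world coordinates at
voxel centres, millimetres.

## Volume rendering

`render_frame()` casts perspective rays from a source point at 3 long-axis
lengths from the LV centroid on the view azimuth (look-at the centroid, up
$= +z$, field of view chosen so the LV fills about 80% of the frame). Along
each ray, samples at half the smallest voxel size are composited
front-to-back; opacity ramps linearly from 0 at $WL - WW/2$ to 1 at
$WL + WW/2$ and the emitted grayscale equals the opacity, making the
rendering invariant to any constant HU shift applied to both the volume and
the level. The window width is fixed at 150 HU for every study; the level is
study-specific, the mean intensity in a small spherical ROI (5 mm default)
at the blood-pool centroid (`compute_window_level()`). Rendering runs at
native volume resolution; frames are resampled to 299 x 299 only at the
classifier input. The canonical stored format is a lossless PNG sequence
(`write_video_png()`); grayscale is used rather than a colour transfer
function since the classification rests on shape and motion.

The per-pixel *visibility map* records, for the ED frame, the endocardial
face nearest to the first point where the accumulated opacity crosses 0.5.
Pixels whose crossing lies farther than 5 mm from any face centroid (the
basal cap, the apex hole of the open mesh) carry no visibility and are
excluded from label fractions. This map is what projects the face-wise
$RS_{CT}$ ground truth into each view (`project_rsct_to_view()`): the
abnormal fraction's denominator is the count of visible endocardial pixels
in that view.

## The mask-to-mesh path

For real segmentations (and for validating the phantom against itself),
`extract_endocardial_mesh()` extracts the 0.5 iso-surface of the Gaussian
smoothed (1 voxel) mask. Because an isolated LV blood pool is star-shaped
about its long axis, the surface is sampled on the same azimuth x long-axis
UV grid by horizontal rays from the axis, with apex and base located at
sub-voxel precision along the axis. Along each azimuth the rows sit at equal
fractions of the meridian's *arc length*: when the wall deforms by a
per-meridian similarity — the phantom's motion model, and the dominant
motion of a contracting LV — equal arc fractions are material points, so
rows of meshes from different frames correspond. All frames of a study are
extracted about the ED long axis (`axis_xy`), and since same-resolution
meshes share topology, `establish_correspondence()` reduces to the
identity. For meshes with unrelated topology it falls back to greedy
one-to-one nearest-centroid matching (re-querying displaced faces against
the remaining targets) and errors out when more than 20% of faces stay
unmatched.

Median $|RS_{CT}^{mesh} - RS_{CT}^{analytic}|$ on a globally contracting
phantom is below 0.03 at 1 mm voxels and shrinks with resolution — the
package's oracle-equivalence check. The known limitation of this
non-tracking correspondence: when *longitudinal* shortening varies around
the circumference (an akinetic sector beside contracting wall), whole-
meridian arc normalisation compresses the static sector's rows and biases
its $RS_{CT}$ by roughly $-0.1$. That bias stays far from the $-0.20$
impairment threshold, so view and study labels are unaffected (the test
suite asserts this), but per-face values in such sectors are approximate;
exact per-face ground truth on phantoms always comes from the
shared-topology mesh path.

## The classifier

Four frames span systole: ED, ES and two interior frames evenly spaced
between them (`round(seq(ed, es, length.out = 4))`). Each 299 x 299 frame
becomes a 2048-long feature vector; the four vectors stack into a (4, 2048)
matrix. Two extractor backends share this contract. The default
`projection_stub` downsamples the frame to 32 x 32 and applies a fixed,
seeded Gaussian random projection to 2048 dimensions — deterministic and
self-contained, so the whole pipeline trains and tests offline. The
`pretrained_cnn` backend designates the 2048-wide global-average-pooled
penultimate layer of an ImageNet-pretrained Inception-v3 (the only layer of
that width); the package bundles no CNN weights, so selecting it without
externally supplied weights is an error. Swapping backends changes no
shapes or downstream interfaces.

The sequence model (`train_classifier()`) is an LSTM with 2048 units (tanh
activation, sigmoid recurrent activation) over the four time steps, followed
by a fully connected softmax head over the two classes, trained end-to-end
with categorical cross-entropy. It is implemented from first principles in
single-precision RcppArmadillo (forward, backpropagation through time,
Adam); a finite-difference gradient check is part of the test suite, and
training is bit-reproducible for a given seed because all randomness
(initialisation, shuffling) comes from an internal generator. Class order is
(abnormal, normal), and an exact 0.5 tie breaks to normal — the
specificity-favouring choice. Features are standardised per dimension with
training-set statistics. Whether training balanced the classes was left
open in the original description; here the cross-entropy weights each class
inversely to its training frequency by default (`class_weight =
"balanced"`), since abnormal videos are the minority in realistic cohorts
and unweighted training visibly biases the model toward the normal call.
Remaining defaults follow common practice where the original description is
silent: Adam at learning rate 1e-4, batch 16, up to 200 epochs with
early-stopping patience 20 on validation loss, restoring the
best-validation weights.

Splitting (`make_splits()`) is at the study level — all six videos of a
study travel together — 60% into a cross-validation pool and 40% held out,
the pool dealt into five equal-as-possible folds; a 205-study pool yields
the 41-validation / 164-training fold sizes of the clinical protocol.

## Evaluation arithmetic

`confusion_matrix()` (prediction rows, truth columns, abnormal positive),
`sens_spec_acc()` (undefined rates flagged as NA, never coerced to 0), and
`cohens_kappa()` with the asymptotic standard error
$\sqrt{p_o(1-p_o)/(N(1-p_e)^2)}$ — this simple form reproduces the published
cohort's printed intervals (e.g. [0.83, 0.89] for the per-video
cross-validation kappa at N = 1230) to two decimals, which is why it was
chosen over the Fleiss variant. `rebin_by_view()` re-bins per-video results
into the six regional views; `stratify_by_lvef()` uses bins
$(<0.40)$, $[0.40, 0.60]$, $(>0.60)$ with both boundary values assigned to
the middle bin (the published strata overlap at the boundaries, so a
convention had to be fixed). The two-proportion z-test uses the pooled
variance; the pairwise chi-squared tests use no continuity correction and no
multiplicity adjustment (both configurable, both unstated in the original
description). Multi-class severity grading (hypokinetic / akinetic /
dyskinetic) is deliberately out of scope — inter-expert agreement on it is
poor and the framework collapses it to one abnormal class.

## The recovery experiment

`run_phantom_experiment()` is the end-to-end check: a 60-study cohort, half
with severity-1 defects, 150 degrees wide and spanning 10-90% of the
apex-to-base extent — wide enough that the impaired surface exceeds the 35%
label fraction in at least two adjacent views. Defect centres sit on the six
AHA wall-centre azimuths, emulating infarcts centred on coronary
territories; this keeps every view's impaired fraction well away from the
0.35 threshold, so the ground-truth labels the classifier must recover are
unambiguous (an optional jitter parameter relaxes this). Anatomy varies
across studies (radii about 8%, contraction SD 0.02). Cohort labels come
from the phantom's analytic per-face truth projected through the rendered
views, keeping mesh discretisation error out of the classifier evaluation;
the mask-to-mesh path is validated separately against the analytic oracle.

The experiment follows the 60/40 + 5-fold protocol: each fold's model early
stops on its own validation fold, and the five fold models' softmax outputs
are averaged on the held-out 40%, per video and per study. Training doubles
its data with horizontal mirroring (a mirror-image ventricle carries the
same label, and defects sit left or right of the camera symmetrically), and
prediction averages each video with its mirrored copy. The experiment caps
training at 20 epochs with patience 4 and learning rate 1e-3 at batch 64 —
on this cohort size every fold converges well within that budget. With
akinetic defects, held-out per-video and per-study accuracy reach at least
0.95; with subtle defects (severity 0.5, regional shortening just at the
impairment threshold) accuracy degrades yet stays well above chance,
qualitatively mirroring the harder intermediate-LVEF stratum of the
clinical cohort.

Problem sizes were chosen to keep a full experiment to a few minutes on one
CPU: 64^3 voxels at 2 mm, 10 frames per cycle, 128 x 128 rendered frames,
six views, 60 studies (360 videos). The mesh-oracle check runs one 120^3
study at 1 mm.

## What the phantom does and does not show

The phantom emulates the properties the pipeline actually consumes —
blood-pool contrast around 520 HU against a clean background, a full-cycle
volume curve with unique ED/ES, angular sectors of impaired inward motion
with exact per-face ground truth, and six-view renderability. It does not
emulate papillary muscles, trabeculation, pacing-lead artifacts, contrast
timing gradients, irregular gating, segmentation error, or realistic infarct
geometry (transmurality, multiple territories). Passing the recovery
experiment therefore shows that the implementation is internally coherent —
rendering, labeling, features, training and evaluation compose correctly and
the classifier can extract regional-motion signal from rendered videos — not
that the reported clinical accuracies transfer to real 4DCT data. The
clinical-cohort statistics in the package are recomputed from published
counts, not re-measured.

## Numerical choices and degenerate inputs

* Ray step: half the smallest voxel; trilinear sampling everywhere; ray
  marching, resampling and smoothing are deterministic C++.
* Volumes in mL are voxel count x voxel volume, no partial-volume
  correction.
* ED/ES ties break to the earliest frame; a constant volume curve is an
  error (no identifiable systole).
* Fewer than two interior frames between ED and ES duplicates the nearest
  frames with a warning.
* Empty masks, multi-component masks, degenerate landmark geometry,
  single-class training sets, and non-6 video-label counts are errors, not
  silent fallbacks.
* A mask centroid outside the blood pool (strongly concave pools) falls
  back to the mask-wide mean window level with a warning.
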