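# vrwma

Detection of left-ventricular **wall motion abnormalities (WMA)** from
dynamic **volume renderings** of cardiac 4DCT blood-pool volumes.

Cardiac 4DCT encodes the full 3D motion of the LV endocardium, but reading
it on reformatted 2D planes is confounded by through-plane motion. This
package implements an alternative pipeline for researchers in cardiac
functional imaging:

1. **Six-view VR videos.** The isolated LV blood pool is aligned to a
   canonical frame (apex to base along +z, anterior wall at 12 o'clock) and
   ray-cast from six perspectives 60° apart around the long axis, each
   facing one mid-cavity AHA wall. Windowing is study-specific: level = mean
   HU in a small ROI at the blood-pool centroid, width fixed at 150 HU.
2. **Quantitative ground truth.** On the segmented blood pool, regional
   shortening of each endocardial surface patch,

       RS_CT = Area_ES / Area_ED − 1,

   is computed between end-diastole and end-systole on corresponding mesh
   faces. Pixels whose visible face has RS_CT ≥ −0.20 are impaired; a video
   is abnormal when > 35 % of its visible endocardial pixels are impaired;
   a study is abnormal when ≥ 2 of its 6 videos are.
3. **Sequence classifier.** Four frames (ED, two systolic, ES) are reduced
   to 2048-long feature vectors (pluggable extractor; the default is a
   seeded projection stub, an Inception-v3 interface is declared), stacked
   into a (4, 2048) matrix and classified by an LSTM (2048 units) with a
   fully connected softmax head, trained with categorical cross-entropy
   under a study-level 60/40 split with 5-fold cross-validation.
4. **Evaluation arithmetic.** Confusion matrices, sensitivity / specificity
   / accuracy, Cohen's κ with 95 % CI, per-view re-binning, LVEF
   stratification, two-proportion z-tests, pairwise chi-squared tests.

No clinical images ship with the package. A fully analytic 4D LV phantom —
a truncated ellipsoid contracting by a direction-dependent similarity
scaling, with angular defect sectors of controllable severity and exact
closed-form RS_CT — stands in for the cohort, and the published cohort's
confusion-matrix counts are bundled as reference data.

## Worked example

```r
library(vrwma)

# a phantom study with an akinetic 150° inferolateral defect
spec <- phantom_spec(defects = list(
  defect_spec(azimuth_center = -30, azimuth_width = 150,
              long_axis_extent = c(0.1, 0.9), severity = 1)), seed = 7)
study <- generate_study(spec)
study
#> phantom 4DCT study: 10 frames, 64x64x64 voxels
#>   ED frame 1 (98.1 mL), ES frame 5 (63.0 mL), LVEF 0.36
#>   defects: 1

lab <- label_phantom_study(study)
round(lab$abnormal_fractions, 2)
#> [1] 0.50 0.79 0.50 0.09 0.00 0.09
lab$study_label$abnormal
#> [1] TRUE
```

The six abnormal fractions are the per-view shares of visible endocardial
pixels with impaired shortening: the defect faces view 1 (inferolateral
camera), spills into the two adjacent views (0.50 each, still above the
0.35 cut), and is invisible from the opposite side — so 3 of 6 videos are
abnormal and the study is called abnormal by the ≥ 2 rule.

Agreement arithmetic on the bundled clinical counts:

```r
cm <- confusion_counts(tp = 443, fp = 36, fn = 49, tn = 702)
unlist(sens_spec_acc(cm)[1:3])
#> sensitivity specificity    accuracy
#>   0.9004065   0.9512195   0.9308943
k <- cohens_kappa(cm); c(k$kappa, k$ci)
#> [1] 0.855393 0.825732 0.885054
```

## Scope

Out of scope by design: clinical image segmentation (a U-Net in the
original workflow), pacing-lead artifact removal, the validated surface
feature-tracking algorithm (the phantom's shared-topology meshes replace
it; a nearest-centroid fallback covers independent meshes), ImageNet
pre-training, severity grading beyond binary WMA, and diastolic indices.
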