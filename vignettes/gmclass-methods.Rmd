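---
title: "Classifying temporal lobe epilepsy from grey-matter maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying temporal lobe epilepsy from grey-matter maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmclass)
```

## The problem

Left medial temporal lobe epilepsy (MTLE) is radiologically associated with
hippocampal and medial-temporal atrophy, but in roughly half of surgically
confirmed cases no abnormality is visible to human readers. The classification
task is therefore: given a 2D coronal grey-matter (GM) density image of a
subject — a per-pixel GM probability in [0, 1] produced by tissue
segmentation — predict whether the subject is a healthy control (HC, label 0)
or a patient with left MTLE (TLE, label 1). `gmclass` implements the whole
study pipeline around that task: cohort simulation, smoothing, class
balancing, two convolutional classifiers, a repeated stratified evaluation
protocol with a permuted-label null, and forward-activation-map
visualization.

Real cohorts of this kind are not freely distributable, so the package ships
a synthetic-cohort generator whose outputs have the statistical structure the
protocol assumes. Everything downstream of the generator treats its images
exactly as it would treat segmented GM maps supplied by the user as NIfTI
volumes.

## The synthetic cohort generator

`make_template()` builds a procedural coronal "anatomy": an elliptical
cortical ribbon, a central subcortical nucleus, and two bilateral
medial-temporal blobs, plus a seeded smooth texture so images are not
piecewise constant. The template is procedural rather than an atlas slice on
purpose: the upstream spatial normalization and segmentation performed by
external neuroimaging tools are out of scope here, and a procedural template
keeps the package free of any data download while still giving the classifier
a ribbon-plus-structures geometry to learn from. "Left" is simply the
low-column half of the image; no radiological flip is applied.

`sample_subject()` derives one subject from the template:

* **Atrophy** is a multiplicative intensity reduction on the left
  medial-temporal ROI (`medial_temporal_effect`, a fraction in [0, 1)),
  optionally with rim erosion to emulate volume loss, plus a weaker reduction
  over the whole neocortical ribbon (`extrahippocampal_effect`) reflecting
  the distributed, extra-hippocampal component of MTLE pathology. Controls
  receive no reduction.
* **Jitter** is a uniform integer translation of up to `jitter_px` pixels
  per axis, standing in for residual individual differences in sulcal and
  gyral positioning after normalization.
* **Noise** is additive Gaussian with `noise_sd`, clipped back to [0, 1]
  because GM probability maps are bounded; at the default noise level the
  clipping bias is negligible (the Monte-Carlo tests verify the realized ROI
  reduction matches the nominal effect to within 0.03).

`cohort_config()` defaults encode the study composition this pipeline
emulates: 95 TLE (48 "lesional" with visually evident atrophy, 47
"non-lesional"; 57 seizure-free post-surgically, 29 + 28 by subgroup) versus
202 HC across three sites in proportions 30/33/32 and 49/74/79. One report
passage counts 203 controls; the demographic table and participant section
say 202, so 202 is the default and the count is configurable. Default effect
sizes are a choice the data cannot dictate: the lesional subgroup gets a 30%
medial-temporal reduction (clearly visible against the ~6% pixel noise, as a
radiologically evident atrophy should be) and the non-lesional subgroup 10%
(at the edge of visual detectability), with 4–5% distributed neocortical
reduction for both. The constraint that the lesional effect is at least the
non-lesional effect is enforced.

## Smoothing

`smooth_gm()` applies a Gaussian kernel specified by its FWHM in
millimetres, the convention of voxel-based morphometry; the study smooths at
8 mm. `fwhm_to_sigma()` is the exact conversion sigma = FWHM / (2·sqrt(2·ln 2)).
Boundary handling is reflective padding with a normalized discrete kernel,
so constant images pass through unchanged and interior mass is conserved —
properties the tests assert directly. Smoothing may be applied to 3D volumes
(per-axis voxel sizes respected) or to extracted 2D slices; the original
study does not state the order, so the operator simply acts on whatever
representation it is given. Both smoothed and unsmoothed images flow through
the same pipeline (`fwhm_mm = 0` disables smoothing), mirroring the study's
paired analyses. Coronal planes are indexed 1-based along the second array
axis, matching the "plane 113 (out of 156)" convention.

## SMOTE for images

With 95 patients and 202 controls, a classifier can reach 68% accuracy by
always answering "control" (`majority_baseline_accuracy(95, 202)`), so
training sets are balanced by a k-nearest-neighbour SMOTE over flattened
pixel vectors (k = 5 by default, Euclidean distance, ties broken by index).
Two displacement conventions are provided because the printed formula
differs from classic SMOTE in two respects:

* `as_printed_uniform_mean0_sd1` (default): `Xs = Xm + (Xm − X̂)·Rd` with
  Rd drawn from the *unique* uniform distribution with mean 0 and standard
  deviation 1, i.e. U(−√3, √3). Displacements can point away from the
  neighbour and overshoot.
* `classic_uniform01`: `Xs = Xm + (X̂ − Xm)·Rd`, Rd ~ U(0, 1); the synthetic
  sample lies on the segment between parent and neighbour.

Synthesized images are clipped to [0, 1] to stay in the input domain. When
more synthetic samples are needed than there are minority subjects, parents
cycle round-robin (a random-parent mode exists); the source does not specify
this, so it is configurable and logged. Every synthetic sample's parent,
neighbour and Rd are returned as an audit log. Balancing is applied only
inside training data after splits — never to validation held-out folds or
the test set — so the imbalance is never leaked into evaluation.

## The classifiers

Both models use three convolution layers and one fully connected
classification layer. Kernels are square, the stride equals the kernel size
and there is no padding, so each layer is a non-overlapping patch
decomposition with output side `floor((n − k)/k) + 1`; this reduces every
convolution to a single dense matrix product, which is why the models train
quickly in plain R. The DAG variant adds an addition layer with two inputs:
the first convolution layer's (fine-scale) feature maps and the third
layer's (coarse) maps. Because their shapes differ, the first-layer maps
pass through deterministic nearest-neighbour spatial resampling onto the
third layer's grid followed by a learnable 1×1 channel projection — the
minimal extra capacity that preserves the "subtle + coarse" additive
reading of the architecture.

Choices the architecture description leaves open, resolved as the defaults
of the toolbox family it describes: ReLU after each convolution; softmax
with cross-entropy at the classifier; stochastic gradient descent with
momentum 0.9; batch size 16. Convolution weights are He-initialized with a
small positive bias (0.05) so that ReLU units start active — with all-zero
biases, small strided networks on non-negative inputs frequently started in
a dead-ReLU plateau and degenerated to majority prediction. All randomness
(initialization, batch order) comes from one stream fixed by the training
seed, so fitted parameters are bit-reproducible.

The documented full-scale optima (CNN: learning rate 6e-4, 160 epochs,
validation every 80 epochs, layers 40×20², 10×10², 15×20²; DAG: 4e-4, 160
epochs, validation every 10, layers 10×30², 40×15², 20×15²) are kept as the
spec defaults for reference. Note one quirk the tests pin down: under the
stride-equals-kernel rule the 20→10→20 kernel chain cannot fit any
realistically sized image (a 160×160 input leaves 8×8 maps after layer 1,
too small for a 10×10 kernel), so reduced-scale analyses use shorter chains
such as 16→2→2 on 64×64 images. One report passage also describes the CNN's
third layer as 15×15 rather than 20×20; both are expressible through
`cnn_spec()`, and the parameter-list reading (20×20) is the default.

## Evaluation protocol

`run_protocol()` repeats four steps: (1) stratified 80/20 split
(per-class test counts use the floor rule, so 95/202 gives a 19 + 40 test
set); (2) 10-fold stratified grid search over `hyper_grid()` combinations,
SMOTE-balancing each fold's nine training folds only; (3) selection of the
(combination, fold) with the highest validation accuracy, ties to the first
in the deterministic enumeration order; (4) evaluation on the untouched
test split. Step 4's "model constructed using the optimal parameters" is
read as retraining on the full balanced training+validation split (default);
reusing the winning fold model directly is available via `retrain = FALSE`.
Unbuildable grid combinations are skipped and logged rather than failing the
search.

Metrics are PPV, NPV, SEN, SPC, AUC and ACC from the 2×2 confusion matrix
with TLE positive. The AUC estimator is not specified in the source, so the
rank (Mann-Whitney) estimate is used, ties counted 1/2; the tests verify it
against a brute-force all-pairs concordance oracle and an independent ROC
implementation. Metrics with zero denominators are reported as explicit `NA`
markers and excluded from distribution means with a logged count — at
chance-level performance PPV is frequently undefined because no test subject
is predicted positive, and silently coding those as 0 would bias the null
summaries.

`run_permutation_null()` estimates the chance distribution: per repeat, a
fresh split is drawn (re-drawing per repeat mirrors the protocol's
independent pipelines; sharing the correct run's split would be an
alternative reading), the training+validation labels are permuted, 10-fold
CV runs at fixed hyperparameters, the best fold model is selected and scored
on the test split with true labels. `p_value()` is the plain exceedance
proportion — the fraction of null values at or above the observed mean, no
continuity correction — matching the "greater than 98% of null accuracies ⇒
P = 0.02" rule.

Per-repeat seeds derive from the master seed by a fixed affine counter
(`derive_seed()`), so any repeat is recomputable in isolation. Leakage is
auditable: each repeat records test ids, training ids and SMOTE parent ids,
and the tests assert the intersections are empty.

The demographic worked examples are implemented as plain functions:
`pooled_t()` (the age comparison, |t| = 1.46 from means 39.4/42.3, SDs
18.7/14.5, n 95/202) and `majority_baseline_accuracy()`. The demographic
table's gender χ² (4.6 with P = 0.31 on one degree of freedom) is mutually
inconsistent and not reproducible from the printed percentages; it is
deliberately not implemented.

## Visualization

For each test image and convolution layer, the layer's pre-nonlinearity
maps are computed (raw responses, which can be negative — the procedure's
absolute-value step is what makes sign irrelevant); the absolute map with
the largest total is selected, normalized to [0, 1] by its maximum, and
upsampled to image resolution by nearest-neighbour block expansion aligned
to the stride grid (each map pixel covers exactly its receptive field).
Maps aggregate across test images by summation and renormalization. An
all-zero map is returned unchanged with a `zero_map` flag instead of being
divided by zero. The localization property the tests assert: on
strong-effect cohorts, the aggregated layer-2 or layer-3 peak falls inside
a 2-pixel dilation of the injected left medial-temporal ROI in at least 80%
of seeded runs. The source's visualization repeat count is internally
inconsistent ("repeated 100 times … resulted in 1000 maps"); here the
aggregation count simply follows the number of test images and repeats
actually run.

## Problem sizes and numerical choices

The package's own studies run at reduced scale: 64×64 images, cohorts of
40 patients / 80 controls (test split 8 + 16), an 8–8–8-filter 16→2→2
kernel chain (~2.2k parameters), learning rates 0.02–0.05, 12–60 epochs,
and 20–50 protocol repeats instead of 1000. These sizes were chosen so a full
permutation-null calibration (50 repeats × 10 folds) completes in a few
minutes on one CPU while keeping every structural element of the full-scale
protocol — imbalance, SMOTE-in-fold, stratification, best-fold selection —
intact. At 50 repeats the null AUC mean has a standard error of ~0.017
(per-repeat SD ≈ 0.12, matching the full-scale report's null AUC SD), which
is why the calibration band is ±0.05.

Degenerate inputs are handled explicitly: single-class datasets are
rejected for training and flagged untrainable at generation; pools smaller
than k fail SMOTE with a size error; kernel chains that collapse below 1×1
raise an architecture error at build time; empty test classes surface as
`NA` metrics.

## What passing tests do and do not show

The generator produces bounded, spatially smooth images with a localized
multiplicative group effect, anatomical jitter and pixel noise. It does not
emulate MRI physics (bias fields, contrast variation), true inter-subject
anatomical variability, site effects on intensity, or segmentation error.
Passing the recovery and calibration suites therefore demonstrates that the
pipeline is correct and unbiased — that it finds real, localized effects,
does not find permuted ones, and never leaks test data — not that any
particular accuracy level transfers to clinical MRI. Conversely, the
worked-example statistics and the null calibration are
implementation-independent quantities and should reproduce anywhere.
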