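---
title: "Automated aortic diameter measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated aortic diameter measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In trauma patients with massive hemorrhage, the aortic diameter (AoD)
contracts with blood loss and re-expands under resuscitation. Interventions
such as REBOA (resuscitative endovascular balloon occlusion of the aorta)
need an accurate, current diameter — an undersized estimate risks balloon
under-occlusion, an oversized one risks vessel injury. On axial CT the
aortic cross-section is approximately elliptical: the vessel is a cylinder
cut obliquely by the scan plane, so the *minor* axis of the cross-section,
not the major axis, approximates the true lumen diameter. `aodmeter`
implements a fully automated pipeline around that observation:

1. segment the aorta on each axial slice with a shallow-attention
   convolutional network;
2. extract the predicted region's contour and fit an ellipse by direct
   least squares;
3. reject slices whose segmentation does not look like exactly one vessel;
4. report `2b` (the minor axis) converted to millimetres through the
   DICOM pixel spacing and the working-resolution scale ratio;
5. evaluate with subject-level ten-fold cross-validation, reporting Dice
   and IoU with and without the rejection filter.

## The segmentation network

The network is an encoder–decoder. Each encoder stage halves the spatial
resolution (3×3 convolution with stride 2, per-channel normalization, ReLU)
and then applies a multi-scale residual block in the Res2Net style: the
channels are split into $s$ groups $x_1,\dots,x_s$; group 1 passes through,
and each later group is convolved after receiving the previous group's
output,

$$y_1 = x_1, \qquad y_i = \mathrm{ReLU}\,K_i(x_i + y_{i-1}), \; i \ge 2,$$

so group $i$ has an effective receptive field that grows with $i$. The
groups are concatenated, fused by a 1×1 convolution, and residual-added to
the block input. With $s = 1$ the block degenerates to a standard residual
convolution block. The default $s = 4$ is the canonical setting for this
backbone family.

The decoder computes, per stage $k$, a head $H_k$ (1×1 convolution +
normalization + ReLU) and — on the attention variant — a *shallow attention
map* $M_k = \mathrm{ReLU}(\mathrm{Conv}_{1\times1}(F_k))$ from the stage's
feature map $F_k$. The attention recursion starts from the deepest head and
gates upsampled deeper features with the shallower stage's map:

$$F^{SA}_K = H_K, \qquad F^{SA}_k = \mathrm{up}\!\left(F^{SA}_{k+1}\right)
\otimes M_k .$$

The published description of this recursion mixes its stage indices; the
reading implemented here — the shallow stage's own ReLU-activated 1×1-conv
map gates the upsampled deeper feature, at every stage — is the one
consistent with the module's stated purpose (suppressing background in the
shallow, high-resolution features, where the vessel/background contrast
lives). All attention entries are non-negative by construction, which the
test suite asserts on every forward pass.

The final mask head concatenates all per-stage heads (upsampled to the
finest stage) together with the gated attention stream, applies a 1×1
convolution, upsamples bilinearly to the working resolution, and applies a
sigmoid. Binarization uses a 0.5 threshold by default — the sigmoid
midpoint; nothing in the method constrains it otherwise.

The plain encoder–decoder baseline (`backbone = "unet"`) is the same
network with $s = 1$ blocks and no attention gating.

### Why the network is implemented in-package

The network, its layers, and the training loop are implemented directly in
R on a compact reverse-mode autodiff core (im2col convolutions on BLAS,
per-channel normalization with running statistics, Adam). At the scales
this package targets — 96×96 working resolution, 3 stages of 8/16/32
channels, a few hundred slices — a CPU forward+backward pass takes ~50 ms,
and the full scaled-down experiment trains in about two minutes. Gradients
are verified against central finite differences in the test suite.

### Training protocol and the learning rate

The loss is weighted binary cross-entropy plus soft Dice — the standard
pairing for small-foreground segmentation, and the differentiable
counterpart of the reported metric. The published protocol states Adam
with a learning rate of 0.4, batch size 16, 100 epochs at 352×352. A 0.4
learning rate with Adam is almost certainly a typo (it diverges on any
network of this family); `model_config()` keeps 0.4 as the documented
default for fidelity, and the recommended practical value is `1e-4` at
full scale. The tiny preset (`tiny_model_config()`) uses `1e-3`: it has
roughly 20× fewer parameters and an order of magnitude fewer optimization
steps at desk scale, and the larger step is what converges within its
12–30 epoch budget.

The normalization layers in the stage transitions and heads use
**per-sample spatial statistics** with learned affine parameters (instance
normalization): each optimization step accumulates gradients across the
batch, but every image is normalized by its own statistics, in training
and at inference alike. The alternative — normalizing with running
averages at inference — creates a train/inference mismatch that proved
unstable here: per-image feature statistics vary strongly across phantom
slices, and held-out Dice degraded non-monotonically with training length
under running-average inference. With per-sample statistics the two paths
coincide exactly, the forward pass is a deterministic function of weights
and input, and checkpoints restore probability maps bit-identically.

## Ellipse calibration and the rejection rule

The predicted mask is labelled into 8-connected components; components
smaller than `min_area` (default 10 px at working resolution — specks,
not candidate vessels; the threshold is configurable and logged in the
measurement table) are discarded *before counting*. Then:

* **0 candidates** → rejected (`empty_mask`);
* **≥ 2 candidates** → rejected (`multiple_candidates`) — decided on the
  count alone, before any fitting;
* **1 candidate** → its outer contour is fitted by the direct
  least-squares conic method constrained to an ellipse (generalized
  eigenproblem of the design scatter against the ellipticity constraint
  $4AC - B^2 > 0$). A failed fit (fewer than 5 points, collinear points,
  no elliptical eigenvector) rejects the slice as `fit_failed`.

Rejected slices carry no diameter and are intended for expert review;
the rejection report counts each reason.

Two numerical details matter:

* **Half-pixel boundary compensation.** The fitted contour consists of
  outer *boundary pixel centres*, which lie on average half a pixel inside
  the true region edge; the raw fit therefore underestimates each semi-axis
  by ≈ 0.5 px (≈ 6 % of area at 8-px axes). `measure_aod()` adds 0.5 px to
  each fitted semi-axis before forming the diameter. With this correction
  the measured ellipse's area matches the mask pixel count to within 3 %
  and the mm conversion reproduces its worked example.
* **Effective pixel spacing.** DICOM allows anisotropic spacing, but the
  minor axis has no fixed alignment with the image axes, so a scalar
  conversion is required. The mean of row/column spacing is used, with a
  hard error when they differ by more than 5 %.

The conversion is
`diameter_mm = 2b × scale_ratio × pixel_spacing`, with `scale_ratio` the
original/working resolution ratio — measurements are taken at working
resolution and rescaled, not re-measured on the original grid.

## Evaluation protocol

Dice and IoU are computed **per image** and averaged (not pooled over
pixels). Conventions: both masks empty → Dice 1 (agreement on absence);
exactly one empty → 0. Two IoU modes are provided: `foreground` (the usual
$|P\cap G|/|P\cup G|$, which satisfies $\mathrm{IoU} = D/(2-D)$ and can
never exceed Dice) and `global` (mean of per-class IoU over foreground and
background). The global mode exists because background-dominated slices
push it far above Dice — reported IoU values near 0.999 alongside Dice
0.865 are only consistent with a background-inclusive definition, so
reports label which mode is used.

Cross-validation is **by subject, never by slice**: test sets are
contiguous blocks of subjects in input order (fold 1 tests the first
block, fold 2 the next, …), with any remainder distributed one subject at
a time to the leading blocks. The non-test subjects split 8:1
train:validation through a seeded draw. Fold averaging is the unweighted
arithmetic mean, rounded to 4 decimals for reporting. The AoD error
summary uses linear-interpolation (type-7) quantiles — the rule is stated
because the summaries it feeds do not define one.

## The phantom generator

Clinical CT data cannot ship with the package, so every stage is exercised
on synthetic phantoms: one bright elliptical "vessel" per slice on a
structured background (a large torso-like outline and a spine-like blob
below centre), Gaussian pixel noise, and per-slice metadata. The defaults
are the study conditions the pipeline targets: 5–25 slices per subject,
pixel spacing 0.6–0.9 mm/px (held constant within a subject, as a scanner
property), vessel minor diameters 12–30 mm (spanning hypovolemic to normal
aortas), aspect ratios 1.0–1.6, uniform orientation. In a configurable
fraction of slices (default 0.1, mirroring the ≈ 9 % clinical rejection
rate) a distractor blob *intensity-matched to the vessel* is painted
disjoint from it — these slices are what the rejection rule is for: a
segmenter that picks up the distractor produces two candidates and the
slice is rejected rather than mismeasured. Intensity levels (vessel 0.85,
spine 0.55, torso 0.35, background 0.15, noise sd 0.05) were chosen once
so that a fixed threshold is imperfect but a trained network separates the
vessel cleanly.

Ground truth is exact by construction: `truth_aod_mm = 2b × spacing`, and
the truth mask is the pixel-centre rasterization of the truth ellipse.
Rasterization uses one convention everywhere: 0-based coordinates, x =
column, y = row, orientation counter-clockwise from +x in degrees, a pixel
is foreground iff its centre satisfies the ellipse inequality.

What the phantoms do **not** emulate: Hounsfield calibration and contrast
phases, anatomy-dependent vessel position, dissection flaps or mural
thrombus, 3D continuity between slices, and scanner noise spectra. Passing
phantom tests therefore demonstrates the pipeline's geometric and
statistical correctness — calibration accuracy, rejection behaviour,
metric arithmetic — not clinical segmentation performance.

## Scaled-down experiment sizes

The package's end-to-end experiment — reproduced by both the test suite
and `scripts/acceptance.R` — trains the tiny preset (96×96 inputs,
channels 8/16/32) for 12 epochs on 200 phantom slices from one set of
subjects and evaluates on 50 slices from disjoint subjects, all at
128×128 original resolution. These sizes were chosen as the smallest
configuration at which held-out behaviour is stable: held-out mean Dice
lands around 0.94–0.96 across seeds, the calibrated-diameter MAE around
0.3–0.6 mm (well below one pixel-equivalent, ≈ 1 mm at these spacings),
and the rejection filter removes the multi-candidate slices, raising the
retained-set Dice above the unfiltered mean.

## Known limitations

* Orientation of a rasterized ellipse is genuinely indeterminate near the
  circular limit: below a 3-px difference between semi-axes the raster
  does not constrain the major-axis direction to within 2°, so round-trip
  checks compare orientation only above that difference.
* The minimal DICOM adapter reads and writes explicit-VR little-endian,
  single-frame, 16-bit monochrome files only — enough for interchange and
  I/O testing, not DICOM conformance.
* Anisotropic pixel spacing beyond 5 % is refused rather than
  approximated.
* Training is single-threaded CPU; the implementation targets desk-scale
  experiments, not clinical-scale training runs.
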