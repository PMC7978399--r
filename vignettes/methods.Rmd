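---
title: "Synthetic CT from single-channel MR: model, training protocol and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT from single-channel MR: model, training protocol and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sucgan)
```

## The problem

Radiotherapy planning and PET attenuation correction need electron-density
information, which CT provides and MR does not. For pelvic (cervical-cancer)
workflows the diagnostically preferred sequence is a single T2-weighted
turbo-spin-echo single-shot MR acquisition; acquiring a planning CT on top of
it costs registration accuracy, money and radiation dose. The method in this
package translates a single-channel T2-weighted MR volume, slice by slice,
into a synthetic CT (sCT) in Hounsfield Units, so that one MR sequence can
serve diagnosis, attenuation correction and dose planning.

The translator is a conditional generative adversarial network (cGAN) in the
image-to-image tradition: a generator `G` maps an MR slice `y` to a CT-like
slice `G(y)`, while a conditional discriminator `D` sees the MR slice stacked
with either the measured CT `x` or the candidate `G(y)` and scores
real-versus-synthetic. The distinguishing choice is a *shallow* U-Net
generator with encoder/decoder depth 2 ("sU-Net"): two 2x2 max-poolings on
the way down, two 2x2 up-convolutions on the way up, with skip
concatenations. Keeping the network shallow reduces trainable parameters by
about a third relative to the conventional depth-3 U-Net benchmark,
mitigates vanishing gradients, and suits small cohorts.

## Objectives

With sigmoid discriminator scores, training alternates two updates per
slice (minibatch 1):

* discriminator: minimise `-[log D(x|y) + log(1 - D(G(y)|y))]`, averaged
  over the patch score map;
* generator: minimise `-log D(G(y)|y) + lambda * L1(G)` with
  `L1(G) = mean |x - G(y)|` and `lambda = 100`.

The generator's adversarial term uses the non-saturating `-log D` form
rather than `+log(1 - D)`; the fixed points are identical and the gradients
do not vanish when the discriminator wins early. Scores are clamped to
`(1e-7, 1 - 1e-7)` before logs. The score map is aggregated by arithmetic
mean, which is stable across input sizes for a fully convolutional
discriminator.

Optimisation is Adam with learning rate `2e-4` and moment decays
`(0.5, 0.999)` — the image-to-image cGAN lineage's settings, stated
explicitly because the training protocol fixes only minibatch 1, 200 epochs
maximum, and left/right flip augmentation. There is no learning-rate
schedule and no early stopping. All of this lives in `train_config()`.

## Reference architectures and the parameter checksums

The published description fixes the layer *types* (convolution, batch
normalisation, ReLU, 2x2 max-pooling, up-convolution, skip concatenation;
three discriminator blocks plus a final convolution and sigmoid) and two
exact anchors: the total trainable-parameter counts, 3,163,142 for the
shallow model and 4,868,614 for the depth-3 benchmark (a difference of
1,705,472, or 35%). Feature counts and kernel sizes per layer are shown
only in a figure, so the reference specs here were fixed by a constrained
search over coherent U-Net/patch-discriminator families until the realised
layer inventory reproduces both totals exactly:

* **Generator (depth 2)**: 4x4 convolutions, one conv + batch norm + ReLU
  per stage, stage features 32 and 64, bottleneck 128; decoder stages use a
  4x4 stride-2 up-convolution (with batch norm), concatenate the matching
  encoder features, and apply one convolution that *keeps* the concatenated
  width (the decoder operates on the concatenated maps); final 3x3
  convolution to one channel, linear output. 690,753 parameters.
* **Benchmark generator (depth 3)**: the same recipe with stage features
  32, 64, 128 and a 128-feature bottleneck. 2,396,225 parameters.
* **Discriminator**: three blocks of two 3x3 conv + batch norm + ReLU
  layers (stride 2 on each block's first convolution), block features 94,
  188, 376, then a single 2x2 convolution to a one-channel score map and a
  sigmoid. 2,472,389 parameters.

`count_trainable_parameters()` sums convolution/up-convolution weights and
biases and batch-norm scale/shift pairs; batch-norm running statistics are
state, not parameters. The two totals and their difference act as
checksums: `build_sunet_generator()` + `build_discriminator()` count to
3,163,142 exactly, and swapping in `build_unet3_generator()` gives
4,868,614. Within the family that satisfies the layer-type description
these checksums pin the architecture tightly; residual freedom (for
instance the discriminator's exact feature counts) cannot be resolved from
text, and the spec realised here is the one coherent solution found whose
generator ladder is the standard doubling 32-64-128.

Weights are He-initialised: zero-mean normal with variance `2 / fan_in`,
`fan_in` = kernel area times input channels, deterministic under a seed.

## Numerical engine

No deep-learning runtime is used: tensors are plain R arrays `(H, W, C)`.
Two small compiled primitives (plain Rcpp) carry all the memory movement —
an im2col gather that unrolls receptive fields into a patch matrix, and
its scatter-add adjoint (col2im) — so that every convolution, every
convolution gradient and the 2x2-upsampling transposed convolution reduce
to BLAS matrix products; spatial batch normalisation is likewise compiled.
The transposed convolution is defined as the exact linear adjoint of the
stride-2 'same' convolution, which makes its gradient the forward
convolution again. Gradients of every operation are verified against
central finite differences in the test suite, the convolution against a
naive triple-loop oracle, and the adjoint identity
`<tconv(x), y> = <x, conv(y)>` is asserted directly.

Batch normalisation with minibatch 1 normalises over the spatial plane.
During training the batch (slice) statistics are used and running averages
are tracked; at prediction the package follows the pix2pix convention of
using the test slice's own statistics (instance-norm behaviour), which on
the phantom recovery experiments is clearly better calibrated in HU than
frozen running averages. Dropout (rate 0.5 in decoder stages by default)
is treated as the model's noise source and is active at training and, by
default, at prediction, driven by an explicit seed; it can be disabled per
call.

## Data handling

Volumes are read and written as NIfTI with spacing from the header
(`read_volume()`, `write_volume()`). DICOM series import is declared in the
interface but not available in this build; convert series to NIfTI
upstream. Intensities are normalised per volume to [0, 1] by min-max
(`normalize_to_unit()`), and the scale is retained for inversion. Two
choices deserve emphasis:

* **Normalization scope.** The protocol statement "normalized to [0, 1]"
  does not say per-volume or per-cohort; per-volume is the simplest reading
  and is what `normalize_to_unit()` does for the MR input.
* **CT scale for training and recovery.** Generator targets and synthetic-CT
  recovery use one fixed global HU scale (default -1024..3071, exposed in
  `train_config()`), not the per-subject CT min-max: at prediction time the
  held-out subject's CT is unknowable, and training targets must live on
  the same scale that prediction inverts.

The body ("air") mask thresholds the CT (default -400 HU), closes the
result in-plane, keeps the largest 3-D connected component and fills
enclosed cavities, so interior air (bowel, rectal lumen) stays inside the
mask while exterior air is excluded. The threshold and closing radius are
exposed; the algorithm is a design choice — the source protocol names the
mask but not its construction. Left/right flipping (`flip_lr()`) reverses
the first in-plane axis of both modalities; transverse slices are the third
array axis, 0-based in slice objects.

## The digital pelvis phantom

The clinical cohort is private, so the package ships a procedural phantom
(`phantom_config()`, `generate_cohort()`) that emulates its *structure*: 11
subjects, 144x144 in-plane grid, 44 or 50 slices each (subjects 1, 2, 3, 5
have 50; 508 slices in total), 3.2 x 3.2 x 5 mm spacing, and five contoured
structures (GTV, right/left femur, bladder, anorectum) plus a body mask.
Geometry is ellipse-and-blob: an elliptical torso with a subcutaneous fat
rim, circular femurs with a cortical rim and medullary core, an ellipsoidal
fluid bladder, a tubular anorectum with an air lumen, and a tumor blob
between bladder and anorectum; per-subject seeds (`seed + index`) jitter
centres and radii by 5–10%.

Every voxel carries a latent texture value `u` in [0, 1] and a tissue
class; MR and CT intensities are the same fraction `u` of the tissue's MR
and HU ranges, plus optional Gaussian noise. Tissue HU ranges are free
parameters of the phantom, *not* estimates of the clinical data (air
-1010..-990, fat -120..-80, soft tissue 20..60, fluid -5..15, tumor 30..70,
bone 200..1300); MR contrast is T2-like (fluid > tumor > soft > fat >>
bone, air). Because MR and CT share `u`, the map `true_forward_map()` is
exact at zero noise: the phantom has a known ground truth, which turns
training into a parameter-recovery experiment. What passing recovery tests
shows is that the pipeline can learn a deterministic, tissue-wise monotone
MR-to-CT mapping from paired slices; it says nothing about registration
error, scanner artefacts, anatomical variability or any other property of
real clinical data.

## Evaluation

`mape()` (mean absolute prediction error — the field's name for a mean
absolute error in HU, kept here with the misnomer documented), `rmse()`,
`psnr()` and `ssim_global()` operate over a mask: the body mask for
whole-volume reports (air outside the body excluded first), the structure
mask for per-contour reports (`contour_metrics()`). Conventions that the
source leaves open, pinned here and reported with results: PSNR's `MAX`
defaults to the masked measured-CT maximum; SSIM is the single global
(non-windowed) statistic with stabilizers `c1 = (0.01 L)^2`,
`c2 = (0.03 L)^2`, `L` the CT dynamic range (default 4095); identical
volumes yield an infinite PSNR sentinel rather than an error; HU histograms
default to 50 uniform bins on -1024..1600 with out-of-range voxels clipped
into the end bins. `summarize_cohort()` reports mean and sample SD across
subjects per region and metric, flagging single-subject summaries.

## Leave-one-out experiments

`loo_splits()` builds one experiment instance per subject; on the
default-shaped cohort the training/prediction slice counts reproduce the
published split table: four instances of (458, 50) and seven of (464, 44)
— split sizes count raw slices, with the flip-augmented pool size (x2)
recorded separately in the manifest. `run_loo_experiment()` re-initialises
both networks freshly per split (seed = base + split index), trains,
predicts the held-out subject, evaluates per contour, persists artifacts
(checkpoint, sCT NIfTI, CSV report, CSV history) and writes a JSON manifest
plus the cohort summary. Split failures are recorded and skipped, not
fatal. Whether the clinical study warm-started weights between splits is
unstated; fresh initialisation is standard leave-one-out hygiene and is
what is done here.

## Desk-scale study conditions

The clinical experiment (11 subjects of 144x144x44–50 voxels, 200 epochs
per split, GPU hours per experiment) is far beyond a CPU test suite, and
its Tables of clinical metric values depend on private data; they are out
of scope here. The package's correctness claims rest on properties the
phantom can decide:

* the architecture checksums above (exact);
* split-size arithmetic on the default-shaped cohort (exact);
* metric implementations against naive-loop oracles at 1e-10 (exact);
* training progress and mapping recovery: on a noise-free 64x64 phantom
  cohort (8 subjects of 2 slices each; one held out, seven train), with
  desk-scaled feature ladders (generator 16-32-64, discriminator 8-16-32)
  and 40 epochs, the epoch-mean L1 term strictly decreases from first to
  last epoch for every seed tried, and the held-out body MAPE beats the
  constant-prediction baseline (synthetic CT set everywhere to the
  training cohort's mean body HU). Held-out accuracy is limited by
  subject-level geometric diversity, not slice count, so the cohort
  spends its budget on subjects.

For the recovery experiment the dropout noise source is disabled: the
phantom is noise-free and the quantity being recovered is the deterministic
per-tissue mapping. Problem sizes (grid, slice counts, feature widths,
epochs) are the package's choices for a desk-scale experiment; they are
stated in the tests and in `scripts/acceptance.R` and were fixed from
convergence diagnostics on the phantom, not from clinical data.

## Known limitations

* The reference feature ladders are checksum-calibrated reconstructions of
  an under-documented figure; layer types and totals are faithful, but the
  clinical implementation could differ in details with the same count.
* 2-D slice-wise translation only; no 3-D context (named as future work in
  the source line of research).
* No DICOM import, no registration or bias-field correction: inputs are
  assumed co-registered on a common grid (the phantom is constructed so).
* The phantom's anatomical realism is deliberately minimal; clinical
  performance claims cannot be derived from it.
* Training at the clinical scale (144x144, reference widths, 200 epochs,
  11 subjects) is possible with this code but slow on one CPU; the
  package's own experiments run at reduced scale.
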