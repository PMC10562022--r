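---
title: "Contrastive unpaired CBCT-to-synthetic-CT translation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive unpaired CBCT-to-synthetic-CT translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cutct)
```

## The problem

Cone-beam CT (CBCT) is acquired on the treatment machine at every fraction of
a radiotherapy course, but scatter, limited collimation and lower beam energy
leave it with shading artifacts, noise and Hounsfield-unit (HU) values that
are too inaccurate for dose calculation. Adaptive radiotherapy would like to
re-plan on the on-table image; that requires an image with fan-beam-CT (FBCT)
HU fidelity. `cutct` implements an unpaired image-to-image translation
pipeline that maps CBCT volumes to synthetic CT (sCT): no voxel-aligned
CBCT/FBCT training pairs are needed, only a set of CBCT-like and a set of
FBCT-like axial slices.

## The model

The translator is a contrastive unpaired translation (CUT) system with three
networks:

* a ResNet **generator** `G` (7x7 stem, two stride-2 downsampling
  convolutions, nine 256-channel residual blocks, two stride-2 transposed
  convolutions, 7x7 output convolution, tanh output; reflection padding,
  instance normalisation without learned affine) — 11,378,179 parameters at
  the reference width of 64 filters;
* a 70x70 **patch discriminator** `D` (4x4 convolutions, widths
  64/128/256/512, strides 2/2/2/1, leaky rectifier 0.2) that scores a spatial
  map of patches rather than the whole image — 2,764,737 parameters;
* a multi-layer patch **projector** `H`: a two-layer perceptron per encoder
  tap (taps at the input, the two downsampling convolutions and two residual
  blocks; widths 3/128/256/256/256 into a 256-wide embedding), with outputs
  normalised to unit length — 560,384 parameters.

Training minimises

```
L = L_GAN(G, D, X, Y) + lambda_X * L_PatchNCE(G, H, X) + lambda_Y * L_PatchNCE(G, H, Y)
```

with `lambda_X = lambda_Y = 1`. The adversarial term is the least-squares
form (scores pushed to 1 for real, 0 for fake). The PatchNCE term samples
patch locations in the encoder feature stack of the input `x` and of the
translation `G(x)`; each translated patch (the *query*) must identify its
corresponding input patch (the *positive*) against the other sampled patches
of the same image (the *negatives*) in an (N+1)-way softmax classification at
temperature `tau`. The same loss applied to target-domain images (`y` versus
`G(y)`) is the identity term: it discourages the generator from altering
images that already look like FBCT. Because negatives come from within the
image, a single generator and discriminator suffice — roughly half the
parameters of a cycle-consistent pair (14,703,300 versus 28,285,832; see
`network_parameter_table()`).

Why these exact layer shapes matter: the published parameter counts are used
as an acceptance check, so the architecture (filter counts, strides, kernel
sizes, bias and normalisation policy) is pinned in
`generator_spec()` / `discriminator_spec()` / `projector_spec()`, and
`count_parameters()` is an exact, platform-independent function of the spec.

## HU channelization codec

The full calibrated HU range `[-1024, 3071]` is kept — clipping it would
make dose calculation impossible — by partitioning it into three equal
segments `[-1024, 341]`, `[341, 1706]`, `[1706, 3071]` and carrying each
segment in one 8-bit channel (`partition_edges()`, `encode_slice()`). The
package uses a saturating ("thermometer") fill: a pixel's channels below its
active segment hold 255, channels above hold 0. That makes the decoder a
simple affine function of the channel sum,

```
h = e0 + sum_c (v_c / 255) * (e_{c+1} - e_c),
```

keeps encoding monotone in HU, and bounds the round-trip error by half a
quantisation step, `(1365/255)/2 = 2.68` HU (verified exhaustively over every
integer HU in the range). Quantisation rounds half away from zero so the
bound is exact on every platform. The saturating fill and the sum-decoder
are this package's definitions; alternatives (e.g. one-hot segment masks)
would decode ambiguously at segment boundaries.

## Preprocessing

`extract_body_mask()` thresholds with Otsu's method (256 equal-width bins
over the volume's value range; the threshold maximising the between-class
variance, ties to the smallest candidate), keeps the largest 6-connected 3-D
component and fills internal cavities slice by slice. The treatment couch is
a separate connected component and is therefore removed without any
couch-specific logic; interior gas pockets stay inside the mask. Masked-out
voxels are set to -1024 HU (air) so they encode to all-zero channels.
Volumes are clipped to the calibrated range and can be resampled to a target
spacing (`resample_volume()`; output grid size `ceil(n * in / out)` per axis,
trilinear for images, nearest-neighbour for masks).

## Training schedule and optimisation

`train_config()` follows a 3 + 3 schedule: a constant base learning rate for
three epochs, then linear decay to exactly zero over three more
(`lr_at()`). Batch size is 1; samples are axial 2-D slices, shuffled each
epoch, drawn unpaired from the two domains. The optimiser is Adam with
momentum parameters (0.5, 0.999). Each iteration updates the discriminator
on one real target slice and the current translation (the two least-squares
terms halved, as is conventional), then updates generator and projector
jointly on the total objective, with queries and positives sampled at shared
locations. The default base rate is 2e-4, the stable convention for this
architecture family — rates orders of magnitude larger diverge. Runs are
bit-reproducible from the config seed; checkpoints store weights, specs and
seed, and loading validates the spec.

Tunable parameters that matter:

| parameter | default | meaning |
|---|---|---|
| `temperature` | 0.07 | softmax sharpness of the contrastive loss |
| `n_patches` | 256 | sampled locations per encoder tap |
| `lambda_x`, `lambda_y` | 1, 1 | weights of the two PatchNCE terms |
| `base_lr` | 2e-4 | Adam step size before decay |
| `epochs_constant`, `epochs_decay` | 3, 3 | the 3+3 schedule |

## The phantom simulator

Real paired CBCT/FBCT cohorts are institutional and not redistributable, so
`make_phantom()` generates pelvis-like digital phantoms that give every
pipeline stage exact ground truth: an elliptical body (fat background) with
per-slice axis jitter, an interior muscle compartment, a bladder, two
femoral heads and a sacral arc (cortical shell, trabecular core), 0-3
fiducial seeds of 1-3 voxel radius inside a central prostate region at
+3000 HU, and a treatment couch slab separated from the body by an air gap.
Each voxel is painted at its tissue's nominal HU and the label map is
returned alongside. `degrade_to_cbct()` applies cone-beam-like corruptions
to the attenuation-like quantity HU + 1000: multiplicative radial
shading/cupping (default +-8%), scatter-like leakage of a Gaussian-blurred
copy (8%, sigma 12 mm), white noise (10 HU), and a global +30 HU bias —
chosen so the degraded-versus-clean error (about 27 HU MAE in-mask) matches
the magnitude of clinical CBCT HU error. `make_unpaired_dataset()` builds
per-patient clean and degraded volumes with *different* geometry seeds for
the two training domains (so training really is unpaired) while retaining
aligned clean/degraded pairs for evaluation only.

What the phantoms do **not** emulate: real anatomical texture and shape
variation, projection-domain physics (beam hardening, partial volume,
reconstruction artifacts), metal streaks, or scanner-specific calibration.
Passing phantom tests therefore demonstrates that the machinery — masking,
codec, losses, gradients, schedule, evaluation — is correct and that the
adversarial system trains stably; it does not certify clinical image
quality.

## Evaluation

`mae()`, `rmse()` and `ssim()` are computed per volume over the body mask;
SSIM uses the single-expression global-moments form with
`c1 = (0.01 * 4095)^2`, `c2 = (0.03 * 4095)^2` over the full HU dynamic
range (a windowed mean-of-local-SSIM variant is available but not the
default, since the global expression is the package's reference definition).
`fid()` is the Fréchet distance between Gaussian fits of per-slice deep
features, `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, with a
symmetric matrix square root and clamping of tiny negative eigenvalues. The
canonical feature backend (ImageNet Inception v3 pooling features) needs
pretrained weights that this package does not ship; the default
`fixed-projection` backend — average-pooling to 16x16 followed by a seeded
random Gaussian projection — is deterministic, dependency-free, and
sensitive to distribution shifts, which is what the phantom studies need.
Values from the two backends are not comparable. Fold summaries report the
arithmetic mean with standard error `sd/sqrt(k)` (`aggregate_folds()`).

## The end-to-end phantom study, and its honest limits

`run_phantom_experiment()` ties everything together: 20 simulated patients
at 64 x 64 x 16 voxels, one patient fold (of five) held out, CUT trained on
the remaining patients' unpaired slices for the 3 + 3 schedule, and the
held-out degraded volumes translated and scored against their clean truth.
At this scale the package uses a width-8, two-block generator with a
matching discriminator, 128 patches per tap and a base learning rate of
4e-3 — ellipse phantoms need nowhere near the reference capacity, this
size keeps a full run in the minutes range on one CPU core, and with only
~1.5k updates available the highest stably converging rate beats the
reference 2e-4 setting on convergence per step.

One structural fact dominates the outcome: with batch size 1, 16 training
patients x 16 slices x 6 epochs is 1,536 generator updates. Adversarial
value fidelity develops over tens of thousands of updates (a clinical-scale
run sees roughly 60,000+), so at desk scale the held-out MAE of the
synthetic CT decreases monotonically across epochs but typically has not yet
crossed below the degraded input's own MAE when the schedule ends; the
residual is within-tissue texture variance rather than tissue-level bias
(per-tissue output means land close to the true HU table). The acceptance
suite runs this study for five seeds and records the comparison honestly;
the numbers it produces are computed fresh each run by
`scripts/acceptance.R`. Users who want a converged phantom translator can
simply raise `epochs_constant`/`epochs_decay` — the limit is the pinned
step budget, not stability (losses stay finite and outputs remain
input-dependent throughout).

## Numerical choices and degenerate inputs

* Otsu requires at least two distinct values; constant input is an error,
  as is an all-air volume (no foreground).
* Between-class variance is computed on bin midpoints; candidate thresholds
  are interior bin edges; ties break to the smallest.
* Instance normalisation uses eps = 1e-5; projector outputs are normalised
  with a 1e-12 floor on the norm.
* The 8-bit quantiser rounds half away from zero (platform-stable).
* `fid()` needs at least two vectors per set; eigenvalues below zero are
  clamped before the square root.
* Resampling clamps out-of-range sample coordinates to the grid edge.
* Networks reject inputs too small for their stride stack rather than
  returning empty maps.

## Known limitations

* The trained-at-desk-scale generator is under-converged by design; see
  above.
* Inception-based FID is a capability error unless pretrained weights are
  supplied through some external mechanism; the fixed projection is not
  numerically comparable to published FID magnitudes.
* Only axis-aligned geometry (no direction cosines, no registration); the
  pipeline assumes pre-aligned grids, as the phantom data are by
  construction.
* 2-D slice-wise translation: through-plane consistency relies on the
  volume-level mask and codec, not on a 3-D network.
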