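---
title: "Synthesizing paired brain-tumor MRI slices by label compositing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing paired brain-tumor MRI slices by label compositing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Voxel-accurate tumor annotations are the scarcest resource in brain-MRI
segmentation: each labelled patient costs expert hours, and simple geometric
augmentation (flips, rotations) cannot produce new lesion shapes, locations
or pathologies. `lesiongan` expands a labelled cohort combinatorially
instead. From $n$ patients it can address $n^2 - n$ *virtual* patients: for
an ordered donor pair $(A, B)$ it pastes the tumor region of $A$'s semantic
label onto the brain background of $B$'s label, producing a composite label
$s_{ab}$ that mimics "patient $B$ carries patient $A$'s lesion". A
conditional generator $G$ is then trained to render $(s_{ab}, x_a)$ — the
composite label one-hot encoded and concatenated with the tumor donor's
image — into a synthetic slice $y$ that looks like $B$'s anatomy carrying
$A$'s tumor. The emitted $(y, s_{ab})$ pairs are drop-in additional training
data for any segmentation network.

Because no ground-truth image exists for a virtual patient, supervision is
assembled from three regional sources:

* **Regional perceptual loss** $L_{rp}$: with $R^{tis}_b$ the tissue mask of
  $B$ (brain minus both donors' tumor sites) and $R^{tum}_a$ the tumor mask
  of $A$,
  $$L_{rp} = \lambda_1\,\mathbb{E}\big[\phi_{3,4}(y \cdot R^{tis}_b) -
  \phi_{3,4}(x_b \cdot R^{tis}_b)\big]^2 + \lambda_2\,\mathbb{E}\big[\phi_{4,4}(y
  \cdot R^{tis}_b) - \phi_{4,4}(x_b \cdot R^{tis}_b)\big]^2 +
  \lambda_3\,\mathbb{E}\big[\phi_{4,4}(y \cdot R^{tum}_a) - \phi_{4,4}(x_a \cdot
  R^{tum}_a)\big]^2,$$
  where $\phi_{3,4}, \phi_{4,4}$ are deep feature maps (the `conv3_4` /
  `conv4_4` activations of a VGG-19-topology extractor) and
  $\lambda_1:\lambda_2:\lambda_3 = 1:100:100$. Masking happens **before**
  feature extraction, so the loss is invariant to anything the generator
  paints outside the two regions.
* **Regional L1 loss** $L_1 = \mathbb{E}\,\lVert y \cdot R^{tis}_b - x_b \cdot
  R^{tis}_b\rVert_1$, anchoring tissue color and texture to the background
  donor.
* **Local–global least-squares adversarial loss** $L_{adv} = L_g + L_l$. The
  global discriminator $D_g$ judges the concatenation of a full image with
  its one-hot label ($[x_b, s_b]$ real vs $[y, s_{ab}]$ fake); the local
  discriminator $D_l$ judges random $64\times 64$ single-image crops,
  sharpening fine texture. Both use the least-squares form, e.g.
  $L_g = \mathbb{E}[(D_g(x_b, s_b) - 1)^2] + \mathbb{E}[D_g(y, s_{ab})^2]$.

The total objective is $L = \lambda L_{rp} + \mu L_1 + \gamma L_{adv}$ with
$\lambda:\mu:\gamma = 1:1000:1000$. All expectations are implemented as
plain means over batch and all feature/pixel elements, which keeps every
term scale-stable when the slice size changes.

## Architecture

The generator is a residual encoder–decoder
(`CIR64F7-CIR128F3-CIR256F3-Res256×9-DCIR128F3-DCIR64F3-C1F7`): a 7×7
Conv–InstanceNorm–ReLU stem, two stride-2 downsampling stages, nine
256-channel residual blocks, two stride-2 transposed-conv upsampling stages
and a sigmoid head, so outputs live in $[0, 1]$ like the min-max-normalized
inputs. The global discriminator has seven 4×4 conv layers
(`CLR64F4-CILR128F4-CILR256F4-CILR512F4×3-C1F4`, LeakyReLU, no
normalization on the stem, patch-map output with no sigmoid); the local
discriminator is identical but one layer shorter, matching its smaller
input. The layer strings are parsed by `network_spec()` and round-trip
through `render_network_spec()`, so the architecture used is auditable
against its printed description.

Three structural choices were genuinely open and are resolved as follows:

* **Strides.** The layer grammar specifies filter counts and sizes but not
  strides. We adopt the patch-discriminator convention of the pix2pix family
  this architecture descends from: the first three discriminator convs are
  stride 2, the rest stride 1; in the generator only the two CIR stages
  after the stem and the two DCIR stages resample.
* **Local discriminator input.** $D_l$ sees image crops only, no label
  channels: the local adversarial term is written on images alone, and the
  local critic's job is realism of texture, not label correspondence. Crop
  locations for $y$ and $x_b$ are drawn independently for the same reason.
* **Generator-side adversarial term.** The least-squares objective is
  stated for the discriminators; the generator uses the standard pairing
  $\mathbb{E}[(D(\cdot)-1)^2]$ on its fake outputs.
* **Upsampling.** `DCIR` is read literally as transposed convolution, with
  `output_padding = 1` so a stride-2 transposed 3×3 conv exactly inverts the
  stride-2 downsampling dimensions.

`base_width_scale` multiplies every channel width: 1 is the full-scale
architecture; the test suite and the smoke experiments run at 1/8 width
(widths 8/16/32), which preserves every structural property while making
CPU training practical.

## The feature extractor is pluggable

$L_{rp}$ only needs a *fixed* deep feature map to define a perceptual
metric. `feature_extractor()` builds the VGG-19 convolutional topology
(blocks of 2, 2, 4, 4 convs with 2×2 max-pools) with He-initialized weights
from a fixed seed; no pretrained download is required, and the extractor is
a deterministic pure function. Inputs are replicated from one channel to
three and standardized with the usual ImageNet moments, so a pretrained
VGG-19 weight set could be substituted without interface changes. Features
are taken post-ReLU. Consequences to keep in mind: perceptual-loss *values*
and `fid_images()` scores computed with a random-weight extractor are
internally consistent (zero iff regions agree, monotone under corruption)
but not numerically comparable to published values that use pretrained
backbones. Tests that need a small extractor use a 2-block clone
(tags `conv1_2`/`conv2_2`) — the loss accepts any tag pair.

## Preprocessing and label conventions

* Intensity normalization is min-max per 2D slice,
  $I_N = (I - I_{\min})/(I_{\max} - I_{\min})$; constant slices are
  rejected. Per-slice (rather than per-volume) application matches a model
  that consumes slices independently.
* The slice window "30 to 110" of a 155-slice study is read as the 0-based
  half-open range $[30, 110)$ — 80 slices — consistent with the half-open
  convention used throughout the package.
* Raw challenge labels $\{0, 1, 2, 4\}$ are re-encoded to five classes
  adding an explicit brain-tissue class (0 outside, 1 tissue, 2 edema,
  3 core, 4 enhancing), because the compositor needs to distinguish brain
  background from image background and the raw files encode tissue only
  implicitly (skull-stripped volumes are zero outside the head). The brain
  mask is `image > 0` reduced to its largest connected component with holes
  filled. `decode_label()` inverts the encoding exactly.
* Intensity slices are resized bilinearly, labels by nearest neighbor (no
  new codes).

## Compositing policy

The tumor keeps its original pixel coordinates — no translation or
registration — and the background donor's own tumor is first relabelled to
tissue, so the pasted tumor wins all conflicts. Tumor pixels falling outside
$B$'s brain are dropped; a pair losing more than `max_dropped` (default 5%)
of its tumor is rejected as inadmissible and resampled, since a truncated
lesion would be anatomically implausible and a mislabelled lesion poisons
the augmentation. The threshold is a package policy, exposed as an argument;
tumor-free slices are excluded from the donor pool because an empty paste is
meaningless.

## Training

One model per modality. Adam with learning rate 2e-4 and betas (0.5, 0.999)
— the defaults of the CycleGAN/pix2pix family — with one discriminator
update (global, then local) followed by one generator update per step.
Discriminator updates reuse the generator forward pass from the start of the
step (generator weights are unchanged by them), and the generator update
backpropagates through the freshly updated discriminators. Batch size
defaults to 1 at full scale. Everything — initialization, pair sampling,
crops — draws from R's RNG seeded once from `gan_config(seed = )`, so a full
CPU run is bit-reproducible; checkpoints store the RNG state, making resumed
runs identical to uninterrupted ones.

Numerical details: instance normalization uses $\varepsilon = 10^{-5}$ and
no affine parameters; GAN conv weights are initialized $N(0, 0.02^2)$;
max-pool backward routes ties to the first matching position; Adam bias
correction is the standard $\sqrt{1-\beta_2^t}/(1-\beta_1^t)$ factor.

## The phantom generator

Real challenge data cannot ship with a package, so `generate_phantom_case()`
produces structurally faithful stand-ins: per-slice brain masks thresholded
from a sum of random Gaussian bumps (largest component, holes filled,
30–70% area in central slices), one ellipse-like tumor per case with two
interior rings giving nested edema ⊃ core ⊇ enhancing sub-regions, strictly
inside the brain; modality-dependent region contrasts (the t1ce channel
renders core ∪ enhancing brighter than edema); additive Gaussian noise with
sd 3% of the intensity range, clipped at zero, so slices are never
piecewise-constant; and arbitrary per-volume intensity scales so the
normalization path is exercised. Everything is deterministic per seed, and
cases round-trip exactly through the NIfTI writer/reader.

What the phantom does **not** emulate: anatomical structure (gyri,
ventricles, hemispheric asymmetry), 3D tumor growth, bias fields,
inter-scanner intensity distributions, or realistic lesion texture. Tests
passing on phantoms therefore demonstrate the *mechanics* — compositing,
masking, losses, optimization, determinism — not clinical image quality;
conclusions about real-data performance require training at full width on a
real cohort.

## Problem sizes used by the shipped experiments

The package's own verification runs are deliberately small so they complete
quickly on one CPU: the smoke experiment trains 200 steps on 4 phantom
patients at 64×64 and 1/8 width (seed 1, flair channel, batch 1, the 64×64
local crop coinciding with the slice), checking that all losses stay finite,
generator outputs stay in $[0, 1]$, and the median tissue L1 of the last 20
steps falls below that of the first 20. With the adversarial and L1 terms
weighted equally (1000:1000), per-step L1 is noisy — each step scores a
different random donor pair — so the median-over-20 comparison is the
stable summary we report. Unit tests run networks at 1/8 width on 48×48
slices (the smallest size the 7-layer global discriminator accepts) and
verify every analytic gradient against finite differences.

## Evaluation utilities

`dice_score()` implements the voxel-wise overlap
$2\sum p_{true} p_{pred} / (\sum p_{true} + \sum p_{pred} + \epsilon)$ with
$\epsilon = 10^{-6}$ by default ("a very small constant"; the exact value is
a package choice). `region_dice()` groups codes by the challenge convention
— whole $\{2,3,4\}$, core $\{3,4\}$ (core includes enhancing), enhancing
$\{4\}$ — and reports their mean. `frechet_distance()` computes
$\lVert\mu_r-\mu_f\rVert^2 + \mathrm{tr}(\Sigma_r + \Sigma_f -
2(\Sigma_r\Sigma_f)^{1/2})$ with the cross term evaluated as
$\mathrm{tr}((\Sigma_r^{1/2}\Sigma_f\Sigma_r^{1/2})^{1/2})$ through
symmetric eigendecompositions (negative eigenvalues clipped), which is exact
for the Gaussian Wasserstein-2 distance and numerically stable.

## Known limitations

* CPU-only: full-width 256×256 training is architecturally supported but
  impractically slow without an accelerator; the package's value at full
  scale is the reference implementation and the small-scale verification.
* The random-weight extractor makes perceptual/FID *numbers* incomparable
  across extractor seeds and to published scores.
* The compositor cannot invent unseen tumor shapes — diversity is bounded
  by the $n^2-n$ donor combinations.
* Tumor placement ignores anatomy beyond the brain mask: a lesion may land
  in an implausible (though in-brain) location.
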