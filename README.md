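# lesiongan

Conditional-GAN data augmentation for multi-modal brain-tumor MRI
segmentation, built on **label compositing**: the tumor region of one
patient's semantic label is pasted onto the brain background of another,
and a generator is trained to render the composite into a realistic
(image, label) pair. From *n* annotated patients the compositor can address
*n*² − *n* ordered donor pairs — 226 patients yield 50,850 virtual samples —
so a scarce labelled cohort becomes a combinatorially large pool of
segmentation training data.

## Who this is for

Researchers augmenting voxel-labelled MRI cohorts (BraTS-style layouts:
`<case>_<modality>.nii.gz` + `<case>_seg.nii.gz`, labels 0/1/2/4) and anyone
needing a dependency-light, fully deterministic CPU reference implementation
of regional-loss conditional image synthesis. A built-in phantom generator
emulates skull-stripped multi-modal slices with nested tumor sub-regions, so
the whole pipeline is testable without any download.

## The model

A residual encoder–decoder generator *G* (nine 256-channel residual blocks,
sigmoid head) maps a one-hot composite label s_ab concatenated with the
tumor donor's image x_a to a synthetic slice y. Supervision combines

- a **regional perceptual loss**
  L_rp = λ₁E[φ₃,₄(y·R_b^tis) − φ₃,₄(x_b·R_b^tis)]² + λ₂E[φ₄,₄(y·R_b^tis) −
  φ₄,₄(x_b·R_b^tis)]² + λ₃E[φ₄,₄(y·R_a^tum) − φ₄,₄(x_a·R_a^tum)]², with
  λ₁:λ₂:λ₃ = 1:100:100 and masking applied before feature extraction;
- a **regional L1 loss** L₁ = E‖y·R_b^tis − x_b·R_b^tis‖₁ anchoring tissue
  texture to the background donor; and
- a **local–global least-squares adversarial loss** L_adv = L_g + L_l: a
  7-layer patch discriminator on full (image ⊕ label) stacks plus a 6-layer
  discriminator on random 64×64 crops.

The total objective is L = λL_rp + μL₁ + γL_adv with λ:μ:γ = 1:1000:1000.
Evaluation utilities provide the region-grouped Dice score
(whole {2,3,4} / core {3,4} / enhancing {4}) and the Fréchet distance
between Gaussian fits to deep features.

## Worked example

```r
library(lesiongan)

# 4 deterministic phantom patients, one modality, 64x64 slices
ds  <- phantom_slice_dataset(4, seed = 1, shape = c(6, 64, 64), modality = "flair")
cfg <- gan_config(iterations = 200, image_size = 64, crop_size = 64,
                  base_width_scale = 1/8, seed = 1, modality = "flair",
                  extractor = feature_extractor(base_width_scale = 1/8, seed = 1))
fit <- fit_lesion_gan(ds, cfg)
summary(fit)
```

```
Lesion-synthesis GAN, modality flair: 200 steps, 180,809 generator parameters
  tissue L1 median: first 20 steps 0.0917 -> last 20 steps 0.09018
 step     l_rp       l_1       l_g       l_l     l_adv    total
  200 25.41976 0.1210389 0.2586103 0.2297214 0.4883317 634.7903
```

The per-step tissue L1 (mean absolute error between the generated and the
background donor's image on the tissue mask, in normalized intensity units)
falls from a median of 0.0917 over the first 20 steps to 0.0902 over the
last 20 — at this deliberately tiny scale (1/8-width networks, 4 phantom
patients) the generator is already learning the background anatomy while
the adversarial terms keep the patch discriminators engaged (`l_g`, `l_l`
near 0.25 means neither side dominates). Virtual pairs then come from:

```r
aug <- generate_augmented_dataset(fit, ds, k = 3, seed = 7, out_dir = "virtual")
aug$manifest[, c("tumor_donor", "background_donor", "modality")]
```

```
  tumor_donor background_donor modality
1      P004:2           P001:1    flair
2      P001:5           P004:3    flair
3      P003:1           P001:5    flair
```

Each output names its donors (`patient:slice`), and every emitted label file
round-trips to exactly the raw codes {0, 1, 2, 4}. `plot(fit)` draws the
loss trajectories; `predict(fit, composite, x_a)` renders a single
composite; `simulate(fit, nsim, seed, dataset)` returns in-memory pairs.

A command-line wrapper with `phantom` / `compose` / `train` / `generate` /
`evaluate` subcommands lives at `inst/cli/lesiongan.R`.

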