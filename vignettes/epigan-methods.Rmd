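---
title: "Methods: a 3D conditional GAN for EPI bias correction and brain extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3D conditional GAN for EPI bias correction and brain extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`epigan` treats coil-inhomogeneity correction plus brain extraction of 3D
EPI volumes as a single image-to-image translation problem. A conditional
GAN is trained on pairs (c, x): c is the raw, coil-biased full-head volume
and x the ideal output — the same anatomy with the multiplicative bias
removed and every non-brain voxel set exactly to zero. The generator G is a
3D U-Net; the discriminator D is a 3D PatchGAN that sees the pair
(condition, candidate) concatenated channel-wise at its input and emits a
patch of independent real/fake probabilities, one per receptive field.
Because the source volume fully determines the desired output, no noise
variable is fed to G; the only stochasticity in G is dropout.

The objective combines the conditional adversarial loss with a
strongly weighted L1 reconstruction term,

$$G^* = \arg\min_G \max_D \; \mathbb{E}_{c,x}[\log D(c,x)]
 + \mathbb{E}_c[\log(1 - D(c, G(c)))] + \lambda\,\mathbb{E}\,\lVert x - G(c)\rVert_1 ,$$

with $\lambda = 100$. Two implementation choices deserve note:

* The L1 norm is implemented as the per-voxel *mean* (the expectation
  form), so $\lambda$ keeps its calibration independently of grid size.
* The generator minimizes the non-saturating form
  $-\log D(c, G(c))$ rather than $+\log(1-D)$; this is the standard way to
  realize the min–max objective without vanishing gradients early in
  training. The logged curves still expose the two expectation terms of the
  adversarial loss separately, alongside the generator composite.

Underlying assumptions: the bias field is smooth, multiplicative and
strictly positive; the brain mask is a deterministic function of the
anatomy visible in c; and source and target are spatially aligned (motion
correction and registration are upstream concerns, outside this package).

## Architecture

The generator has `depth` encoder levels (4×4×4 convolution, stride 2,
batch normalization, leaky-rectifier slope 0.2) and `depth` mirrored
decoder levels (4×4×4 transposed convolution, stride 2, batch
normalization, rectifier), with skip concatenation from encoder level *i*
to decoder level *depth − i*, dropout (rate 0.5) on the first
`dropout_layers` decoder levels, and a tanh output so predictions live in
the same [−1, 1] range as the normalized inputs. Feature maps start at
`base_filters` and double per level, capped at 8× the base. Following the
original pix2pix design (which the architecture otherwise adopts
wholesale), normalization is omitted on the first encoder layer and on the
bottleneck: with batch size 1 the bottleneck's 1×1×1 spatial extent makes
per-channel statistics degenerate there. The discriminator stacks
`n_levels` stride-2 convolutions (batch-normalized except the first,
leaky-rectified) and a final stride-1 convolution to one sigmoid channel;
on a 64×64×64 padded input the default four levels give the 4×4×4 patch,
and on 64×64×16 a 4×4×1 patch.

All layers, their backward passes, and Adam are implemented in the package
(R, with C++ im2col/col2im kernels for the strided 3D convolutions); every
backward pass is checked against central finite differences in the test
suite. Weights are initialized from N(0, 0.02); Adam uses
$\beta_1 = 0.5$, $\beta_2 = 0.999$.

## Training, logging, and checkpoint selection

Per training sample per epoch the loop performs one discriminator update
(real pair labeled 1, fake pair labeled 0) and then one generator update
through the freshly updated discriminator, reusing the same generator
forward pass (and dropout mask) for both. Defaults follow the reference
setting: 200 epochs, batch size 1, learning rates 2×10⁻⁴ (G) and 1×10⁻⁶
(D) — a deliberately starved discriminator that keeps the adversarial game
from oscillating or collapsing. Every iteration appends one record with
the two discriminator terms and the generator composite; every epoch ends
with a checkpoint. Training is a pure function of the seed: data order,
initialization and dropout all derive from it, and two runs with the same
seed produce bit-identical logs.

Model selection evaluates every checkpoint on held-out pairs and picks the
highest mean MSSIM (ties broken toward the earlier epoch), MSSIM being the
index that tracks visual quality most closely; CAD and L2 are reported
alongside. The learning-rate grid-search helper probes candidate (lr_G,
lr_D) pairs for a few epochs and rejects a pair when the probe hits a
non-finite loss, when the per-epoch mean composite exceeds 10× its
first-epoch mean (divergence), when the final-epoch oscillation amplitude
exceeds 5× the first-epoch SD (the "seesaw" failure), or when the
discriminator wins outright (median D(c, G(c)) below 10⁻⁴, leaving no
usable adversarial gradient). The last rule exists because at desk scale an
over-strong discriminator saturates without any numerical explosion.

## The synthetic phantom world

Real training data of this kind (rodent EPI with manually curated
N4-corrected, brain-extracted targets) are not publicly deposited, so the
package generates its own. Each phantom is a smoothly perturbed ellipsoidal
brain (WM core at 0.8, GM rim at 1.0, two CSF pockets at 1.4 relative
units; the surface is modulated by a seeded low-frequency random field so
no head is a perfect quadric), wrapped in a scalp/muscle shell, with
partial-volume softening confined to the head support so the background
stays exactly zero. Modality enters through appearance, as in real data:
spin-echo heads have a bright shell (0.9 vs 0.45 in gradient-echo — scalp
and muscle retain far more signal at spin-echo contrast) and carry a water
reference phantom above the head. The reference object's intensity equals
the CSF value (1.4): both are free water, and on T2-weighted EPI free
water is the intensity ceiling, so a brighter value would be unphysical.

The coil model is the normalized on-axis field magnitude of a circular
loop, $s(d) = (1 + d^2/a^2)^{-3/2}$, floored at a minimum sensitivity
(default 0.1) and applied multiplicatively. `coil_for_spec()` sizes and
places the loop from the head itself — radius 0.9× and standoff 0.18× the
dorsal-ventral head extent — which reproduces the real mouse setup (a
10-mm loop resting ~1 mm above the scalp of a ~5.5-mm-deep head) and
scales geometrically for miniature test worlds. This close placement gives
the characteristic appearance of surface-coil EPI: bright cortex under the
loop and a strong several-fold intensity drop toward the ventral brain.
Noise is additive Gaussian on real-valued magnitude images (σ default
0.03 relative units), not Rician: the data these models consume are
real-valued reconstructions, and the additive choice keeps the noiseless
limit exact. Sources are clipped at zero; targets are noise-free.

`make_dataset()` jitters anatomy (±8% axes), tissue intensities (±10%),
coil geometry (radius ±10%, standoff −20/+30%, lateral position ±10% of
the brain axes) and derives per-pair and split seeds from the master seed
by stage-name hashing, so inserting a stage never shifts downstream
randomness. The held-out count is `max(1, round(n × test_fraction))`,
assigned randomly at the pair level.

What the phantoms deliberately do not model: EPI geometric distortion,
multiband slice leakage, motion, susceptibility dropout, inter-species
anatomy (GE and SE worlds share the same head geometry and differ only in
appearance), and any imperfection of the reference targets. Passing tests
therefore demonstrate that the network, losses and pipeline function and
learn as designed — not that the trained toy models would transfer to real
scanner data.

## Normalization and evaluation conventions

Each volume is normalized independently to [−1, 1] by its own minimum and
maximum ($\hat A = 2(A-m)/d$, $m$ = midrange, $d$ = range), with $(m, d)$
retained for exact inversion; a constant volume is a degenerate-input
error. Whether source and target should share one $(m, d)$ per pair is
genuinely open; per-volume normalization is implemented because the
normalization is stated per image with no pairing caveat. Inputs are
zero-padded symmetrically (upper side rounded up) to the next multiple of
$2^{\text{depth}}$ and cropped back after prediction; padding never
discards data. Metrics operate on the [0, 1] display scale
($0.5x + 0.5$), over whole volumes including background — the outlier
behavior of these similarity indices only makes sense when background
participates.

MSSIM uses a 7×7×7 window sliding at stride 1 with no padding, a unit-sum
circular-symmetric Gaussian weighting (SD 1.5 samples), population-style
weighted moments without Bessel correction, exponents
$\alpha=\beta=\gamma=1$ and constants $C_1=10^{-4}$, $C_2=9\times10^{-4}$,
$C_3=4.5\times10^{-4}$. The window size itself is not uniquely determined
by the stated parameters; 7³ is chosen because with stride 1 it reproduces
the published 58×10×58 window count on a (64, 16, 64) grid, and it remains
configurable. The Dice index binarizes both volumes at a strictly-greater
0.05 threshold (boundary values count as background; pre-binarized masks
pass through unchanged) and reports an explicit error when both masks are
empty. PSNR uses peak 1 on display-scale volumes; L2, MSE and PSNR are
interconvertible ($L2^2 = N\cdot\text{MSE}$), so L2 is the headline
distance.

## Numerical choices

* All computation is double precision (R's native numeric); NIfTI volumes
  are written as float32, and the I/O round trip is tested at float32
  precision. Double precision is strictly tighter than the float32 a GPU
  framework would use, and all comparisons are tolerance-tested.
* Discriminator probabilities are clamped to $[\varepsilon, 1-\varepsilon]$
  with $\varepsilon = 10^{-7}$ before logs, so every loss is finite for
  every input; gradients flow through the sigmoid analytically.
* Batch normalization uses batch statistics during training (batch size 1:
  statistics over the spatial voxels of each channel) and accumulated
  running statistics (momentum 0.1) at inference; variance is floored at 0
  before the square root; $\epsilon = 10^{-5}$.
* Ties in checkpoint selection resolve to the earliest epoch; `which.max`
  provides this deterministically.
* Degenerate inputs fail loudly: constant volumes at normalization,
  windows larger than the volume in MSSIM, empty masks in Dice, zero-norm
  arrays in CAD, non-finite voxels at the NIfTI boundary, non-divisible
  shapes at the network boundary (naming the offending axis).

## Desk-scale problem sizes

The full-scale configuration (6 levels, 64 base filters, 64³-padded
volumes, 200 epochs over hundreds of scans) is far beyond a CPU test
suite, so the shipped tests and the acceptance script run miniatures and
state them explicitly as this package's choices: 16³-voxel phantom worlds
with proportionally scaled heads and coils; depth-3 generators; 8–10
training and 2–4 held-out pairs. The single-modality smoke run trains 30
epochs with 32 base filters; the cross-modality comparison trains GE-only
and SE-only models for 200 epochs with 16 base filters. Capacity and epoch
budgets differ deliberately: with only 240 iterations available, extra
filters substitute for iterations, while the spin-echo task — whose shell
overlaps the brain in intensity and whose reference phantom owns the top
of the intensity range — genuinely needs an order of magnitude more
iterations than the gradient-echo task before its best checkpoint appears
near the final epoch. A deliberately small toy default of 8 filters was
considered and rejected for the acceptance runs: at that size the
spin-echo generator reliably falls into a stable local optimum (constant
background output deep in tanh saturation, an attractor created by the
many exactly-zero target voxels) and never recovers within desk-scale
iteration budgets.

## Known limitations

* The adversarial contribution at desk scale is modest: with the reference
  learning-rate imbalance the discriminator moves little over a few
  thousand iterations, so toy-scale learning is driven mainly by the L1
  term. The architecture and losses are nevertheless the full method, and
  the loss curves expose the adversarial terms for inspection.
* Pair-level random splitting can place near-identical jittered phantoms
  in train and test — the same leakage concern that pair-level splitting
  of repeated scans from one subject raises with real data.
* The phantom world's simplifications (previous section) bound what any
  green test here can claim about real EPI.
* Batch size is fixed at 1 by design; the batch-normalization behavior is
  tied to that setting.
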