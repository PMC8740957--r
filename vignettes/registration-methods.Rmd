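---
title: "Cross-scale weakly supervised deformable registration with siamreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale weakly supervised deformable registration with siamreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siamreg)
```

## The problem

Multi-sequence vessel MRI produces volume pairs that disagree in geometry
(tissue motion, patient repositioning) and in intensity statistics (different
pulse sequences render the same anatomy with inverted or unrelated
contrasts). Intensity-similarity registration is unreliable across such
modality gaps, while segmentations of the structure of interest — here the
vessel lumen — are comparatively easy to obtain and are modality-invariant.
`siamreg` therefore registers *weakly supervised*: the network that predicts
the dense displacement field is trained only to maximize the overlap of
anatomical labels, never to match intensities.

A second practical obstacle is that acquisitions from different scanners or
protocols come on grids of different sizes. Conventional CNN registration
requires pre-cropping both inputs to one shape, which both adds manual
preprocessing and bakes a single shape into the trained model. `siamreg`
accepts fixed and moving volumes of different extents directly.

## The model

The network is a Siamese 3D U-Net:

* **Two weight-shared encoders.** The fixed volume (with its label stacked
  as a second channel) and the moving volume run through *the same* encoder
  weights: a first 7×7×7 convolution for a wide receptive field, then per
  level two 3×3×3 convolutions and a 2×2×2 max-pool. Weight sharing
  guarantees both inputs are embedded under the same metric and halves the
  parameters to train. Activations are leaky ReLUs (slope 0.2): with narrow
  layers and no normalization, plain ReLUs let one aggressive early update
  silence an entire layer permanently (every channel negative everywhere,
  hence zero gradient); the leak makes that state recoverable.
* **A feature-level zero-padding module.** With inputs of different extents
  the two branches emit feature maps of different extents at every level.
  Before decoder fusion, every moving-branch feature map (bottleneck and
  each skip feature) is zero-padded to the extents of its fixed-branch
  counterpart — symmetrically when the extent difference is even, with the
  odd cell on the trailing edge, or on a single edge when configured. The
  padding deliberately sits *between* encoder and decoder: padding the raw
  inputs instead would distort the low-level features of the original
  image, and zero fill adds nothing where the anatomy of interest rarely
  sits (grid borders).
* **One decoder on the fixed grid.** Starting from the concatenated
  bottlenecks, each level nearest-neighbour up-samples, concatenates both
  branches' (padded) skip features, and applies two 3×3×3 convolutions. A
  final 3×3×3 convolution reduces to 3 channels: the displacement vector
  field u(x), in voxel units, on the fixed grid. The transform is
  T(x) = x + u(x), applied by backward mapping (the warped moving image
  samples the moving volume at x + u(x) trilinearly).
* **A Gaussian displacement head.** The raw 3-channel output is smoothed
  with a fixed isotropic Gaussian (σ = 1 voxel by default,
  `fieldSigma`). This is classical Gaussian field regularization in
  the demons tradition: the overlap loss carries information only near
  label boundaries, and the smoothing head extends boundary-driven
  displacement coherently into label interiors, where the additive
  smoothness penalty alone leaves the field under-determined. The operator
  is symmetric, so its backward pass is itself.

The final layer is zero-initialized so an untrained network predicts exactly
the identity transform; displacement regression from a near-identity start
is markedly more stable than from a random start.

## The loss

Let p be the warped (soft, trilinearly interpolated) moving label and g the
fixed label. The soft Dice loss is

$$L_{DSC}(p,g) = 1 - \frac{2\sum p\,g}{\sum p + \sum g + \varepsilon}.$$

Its gradient with respect to a single label entry has magnitude
$2g^2/(p+g)^2$: with sparse labels or poor initial overlap the denominator
is small and the gradient explodes, destabilizing training. The multi-scale
Gaussian-smoothed Dice (GDSC) loss counters this. A discrete kernel

$$k(x) \propto e^{-x^2/2\sigma^2},\quad x \in \{-3\sigma,\dots,3\sigma\},$$

normalized to unit sum, smooths both labels separably along each axis for
every σ in an ordered bank (default {0, 1, 2, 4, 8}; σ = 0 is the identity),
and the per-scale soft Dice overlaps are averaged:

$$L_{GDSC}(p,g) = 1 - \frac{1}{Z}\sum_{z\,\in\,\sigma}
  \frac{2\sum p_z g_z}{\sum p_z + \sum g_z + \varepsilon}.$$

Large kernels spread label mass over space, bounding the per-voxel gradient
and giving the optimizer long-range pull toward distant structures; the
σ = 0 term keeps fine detail in play. Two properties are worth knowing:

* With `sigmaSet = 0` the loss is exactly `dscLoss` (asserted to 1e-9 in
  the tests).
* For σ > 0 the per-scale overlap of *identical* smoothed soft labels is
  below 1 (the soft values multiply), so the GDSC value has a nonzero floor.
  The floor is constant with respect to the transform and therefore
  harmless to optimization; only gradients matter.

The total objective adds a smoothness penalty on the field,
$L = L_{GDSC} + \alpha\,L_{smooth}$ with α = 0.5 by default. Two variants
are implemented: `gradient` (default), the mean Frobenius norm of the
forward-difference Jacobian of u, and `bending`, the mean squared central
second difference, which leaves affine fields unpenalized. Both appear in
the literature under the same regularizer notation; the first-order form is
the default because it is the direct reading of a gradient-magnitude
penalty, and the bending form is kept for users who want affine-invariant
regularization.

Numerical choices: ε = 1e-6 stabilizes empty-label denominators (the bare
formula would divide by zero on an empty batch); σ values are non-negative
integers because the kernel support is indexed by integer voxel offsets;
smoothing applies to the *warped* moving label (warp, then smooth), since p
is defined as the label after the transform.

## Training

Adam minimizes the objective; defaults follow the reference regime
(learning rate 1e-4, 10,000 iterations, batch 2, checkpoint every 15
iterations, grouped 4-fold cross-validation). Because dense mixed-extent
minibatches cannot be stacked, cross-scale pairs are processed as
accumulated single-pair gradients up to the effective batch size. Pairs are
visited in shuffled epochs rather than drawn independently, so every pair
is seen equally often even in very short runs. Checkpoints carry optimizer
and RNG state, so training resumes bit-for-bit; when validation pairs are
supplied, the checkpoint with the best mean validation DSC is returned.

Three optimizer details matter far more here than in ordinary supervised
training, because the displacement head starts at exactly zero and the
overlap gradient lives only near label boundaries:

* **Adam ε = 1e-5** (not the textbook 1e-8). Gradients span many orders of
  magnitude across parameters; with a tiny ε, parameters whose gradient is
  pure noise still take full-size sign steps, burying the informative
  directions under a random walk.
* **Linear warm-up (50 iterations by default).** Before the second-moment
  estimates fill, Adam's steps are sign-like, and a sign-step in weight
  space — unlike a gradient step, whose image in field space goes through
  the positive semi-definite feature Gram — is not guaranteed to descend in
  field space. Unwarmed runs can lock into an oscillation around the
  identity transform and never take off; warming up while the moment
  statistics accumulate removes this failure mode.
* **Optional late step decay** (`lrDecayFactor`, applied after 2/3 of the
  iterations by default): once overlap is roughly recovered, a smaller step
  settles the field instead of letting it overshoot.

Two augmentations mirror common practice for small clinical cohorts:
offline left/right flipping, which doubles the training manifest, and small
random affine transforms applied identically to both members of a pair
during training. One interaction deserves emphasis for *short* schedules:
flip-doubling makes the expected gradient of the left-right displacement
component vanish across each mirrored pair of training examples (the
mirrored copy contributes the sign-flipped gradient), so with only a few
hundred optimizer steps the momentum estimate hovers near zero and the
field barely grows. With the full 10,000-iteration schedule the network has
time to fit both orientations individually; in the scaled-down experiments
below flipping is disabled for this reason, and the learning rate is raised
to 2e-3 with warm-up and a late step decay — a step size that lets Adam
traverse an O(1) weight scale within a 300-step budget (1e-4 is calibrated
to a 10,000-step schedule).

All convolutions run in single precision through an im2col + BLAS GEMM
kernel (the standard arithmetic for network training); everything outside
the network — losses, warping, metrics, I/O — is double precision.

## The synthetic benchmark

Clinical multi-sequence data cannot ship with a package, so `siamreg`
generates its own benchmark: a curved tube that bifurcates into two
branches (a Y-shaped lumen emulating a carotid artery), rasterized as a
binary lumen label and rendered in two modalities with *inverted*
foreground/background contrast plus independent Gaussian noise — exactly
the condition under which intensity losses fail and label-driven training
is needed. Landmarks are placed at the bifurcation and on the vessel wall
(standing in for plaque annotations).

Ground-truth deformations are elastic: independent Gaussian vectors on a
coarse control grid, trilinearly up-sampled, Gaussian-smoothed, and scaled
so the maximum displacement magnitude equals the configured amplitude. The
*fixed* member of a pair is produced by backward-sampling the fixed-modality
rendering (and label) through the field u, while the moving member keeps the
pristine geometry; the stored field is then *exactly* the field that aligns
the moving image onto the fixed grid, so warp(moving label, gtDvf) recovers
the fixed label by construction and network predictions are directly
comparable to u (TRE). Fixed-side landmark positions are obtained by
fixed-point inversion of u at the moving landmark positions. An optional
centered crop of the moving side reproduces the cross-scale regime.

Default parameters are chosen for realism at the default 64³ / 0.6 mm grid:
lumen radius 3–5 voxels (≈ 3.5–6 mm diameter, a common carotid calibre),
bifurcation at 55 % of the vessel axis, deformation amplitude 3 voxels
(≈ 1.8 mm, plausible inter-sequence tissue motion). The 48³ scaled-down
experiments use radius 2–3.5 voxels, scaling the vessel with the grid the
way a smaller field of view would. What the phantom does *not* emulate:
MR physics (bias fields, flow artifacts, anisotropic point-spread),
surrounding anatomy, or label noise — passing tests on phantoms
demonstrates that the machinery optimizes and generalizes across geometry
and deformation draws, not clinical-grade accuracy.

## Scaled-down experiments

The reference results were produced on clinical carotid data with
GPU-scale training (10,000 iterations at 112×64×64). The package's
self-checks run a deliberately small version of the same protocol on one
CPU: 12 phantom pairs at 48³ (6 patients × left/right), amplitude 3
voxels; a levels-2, base-8-channels network trained for 300 iterations
(batch 1, learning rate 2e-3 with 50-iteration warm-up and 0.3 step decay,
σ = {0,1,2,4}, α = 0.5); evaluation on 4
held-out pairs from a grouped split. The checks assert recovery behaviour —
post-registration lumen DSC exceeding the pre-registration value and
masked TRE below the identity-transform TRE — not the clinical-scale
numbers. `scripts/acceptance.R` re-runs this experiment end to end
(simulation → manifest I/O → training → evaluation) and writes the measured
quantities as JSON.

## Conventions and degenerate inputs

* Voxel indices are 0-based; crop boxes are half-open; world mm = origin +
  index × spacing. Landmarks live in world mm so geometry operations never
  invalidate them.
* Displacement fields are stored in voxel units on the fixed grid;
  conversion to mm happens only in metrics. Warping resolves origin offsets
  between grids through the shared world frame, so centred crops stay
  geometrically consistent.
* Images warp with border clamping (no dark rims); labels warp with zero
  fill (no anatomy outside the field of view) and stay soft for the loss,
  hard (nearest) for evaluation.
* Evaluation DSC of two empty masks is 1 (vacuous agreement). TRE averages
  over the lumen mask by default — background errors carry no anatomical
  meaning — with a whole-grid option.
* Landmark distance is directional: fixed landmarks are transported through
  the field into moving space and compared to moving landmarks.
* The fixed grid must be larger or equal per axis; a larger moving grid is
  an error rather than a silent crop. Extents must divide by 2^levels;
  violations name the offending axis before any training starts.

## Known limitations

* One decoder means one fixed/moving size *relationship* per trained model:
  arbitrary unseen size combinations work at inference only within the
  cross-scale envelope the padding module covers (moving ≤ fixed per axis).
* Quality hinges on label quality — the weakly supervised setting inherits
  any segmentation errors.
* No diffeomorphic guarantees: the smoothness penalty discourages but does
  not forbid folding; inverse fields are not computed.
* The CPU implementation targets the scaled-down regime; clinical-scale
  training (10,000 iterations at full resolution) is meant for accelerator
  ports of the same architecture.
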