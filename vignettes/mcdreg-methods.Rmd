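---
title: "Bayesian deformable registration with mcdreg: model, losses, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian deformable registration with mcdreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdreg)
```

## The registration model

`mcdreg` performs unsupervised deformable registration of 3D scalar
volumes. A fully convolutional network `g(S, T) = u` maps a stacked
source/target pair to a dense displacement field `u`: each voxel `p` of the
target grid is assigned a 3-vector `u(p)` in voxel units, and the
deformation map is `phi = Id + u`. The warped source `S o phi` is produced
by a spatial transformer — trilinear interpolation of `S` at `p + u(p)`
over the eight integer neighbours — which is differentiable in `u`, so the
whole pipeline trains end to end by gradient descent without any ground
truth deformations.

Training minimizes

```
L_total = (1 - CC(T, warp(S, u))) + alpha * R1(u) + beta * R2(u)
```

* **Image term.** `CC` is the *global squared* normalized
  cross-correlation: `(sum((t - tbar)(s - sbar)))^2 /
  (sum((t - tbar)^2) * sum((s - sbar)^2))` with volume-wide means. It lies
  in [0, 1], is invariant to affine intensity rescaling of either image,
  and equals 1 only when the images are affinely related, so `1 - CC` is a
  well-scaled dissimilarity. A locally windowed CC is a common alternative
  with sharper spatial gradients; the global form is the default here
  because it is the form the loss above is defined with, and it keeps the
  loss cheap at training time.
* **Smoothness `R1`.** Mean, over voxels and vector components, of the
  squared forward-difference gradients of `u` (`||Du||^2`). The mean
  (rather than sum) reduction keeps `alpha = 1` meaningful across volume
  sizes. `alpha` defaults to 1 and there is rarely a reason to change it.
* **Anti-folding `R2`.** `sum(max(0, -det))` over the Jacobian
  determinant map of `phi`. A deformation with `det < 0` somewhere folds
  space onto itself — physically impossible for tissue — and each folded
  voxel is penalized by its determinant magnitude while orientation-
  preserving voxels contribute exactly zero. The sum (not mean) reduction
  matches the count semantics of the folding metric reported at
  evaluation time. `beta` is swept over {0, 1e-5, 1e-4, 1e-3, 1e-2} in
  typical use; larger `beta` trades a little image fit for fewer folds.
  Because the reduction convention affects the scale of `beta`, absolute
  values are not transferable across implementations — only the trend
  (more `beta`, fewer folds) is.

The Jacobian determinant is computed as `det(I + grad(u))` with central
finite differences at interior voxels and one-sided differences at the
boundary; the same code path feeds both the training penalty and the
reported folding counts, so there is a single source of truth. `det = 0`
is treated as non-folding (strict inequality), and the warp itself applies
the predicted map directly to the source image (the forward map
convention, used consistently for images and labels).

## Network architecture

The network (`network_config()`, `build_bfcnm()`) is an encoder-decoder:

* an *inception-style first layer* — parallel 3D convolutions with kernel
  sizes 3, 5 and 7 (each emitting `base_channels` channels, concatenated) —
  captures structure at several spatial scales before any downsampling;
* an encoder of stride-2 convolutions (no pooling), doubling channels per
  level for `n_levels = 3` levels;
* a decoder whose stages are *Bayesian blocks*: transposed convolution,
  convolution, PReLU, group normalization, dropout. Three "add" skip
  connections join encoder and decoder features of equal resolution. The
  two deepest decoder stages carry the group-norm + dropout pair; the
  final full-resolution stage is a plain upsampling block;
* a last linear-activation convolution emitting the 3-channel field at
  input resolution, initialized with near-zero weights so an untrained
  network predicts an almost-identity deformation (standard practice for
  registration networks: it makes the initial loss the unregistered
  dissimilarity rather than noise).

PReLU (one learnable slope per channel, initialized at 0.25) follows every
convolution block. Group normalization pools all voxels of a contiguous
channel group (`G = 4` by default, checked for divisibility) to compute
mean and standard deviation `sqrt(var + eps)` with `eps = 1e-5`, then
applies a learned per-channel affine; unlike batch normalization it is
exact at batch size 1, which is how registration pairs are trained.
Intensities are expected on the 0-255 scale (`normalize_intensity()`) and
divided by 255 at the network input.

The exact channel widths of the original architecture are not fixed by its
description; the defaults here (`base_channels = 16`, doubling per level)
are the smallest layout consistent with the topology, and everything is
configurable.

There is no deep-learning framework dependency: convolutions, transposed
convolutions, PReLU, group normalization, dropout, backpropagation and
Adam are implemented in the package directly, with im2col patch gathering
and BLAS matrix multiplication doing the heavy lifting. At the desk scales
this package targets (8^3-32^3 volumes) a training iteration takes a
fraction of a second; the implementation is exact, so every layer is
verified against brute-force oracles and finite differences in the test
suite.

## Bayesian inference by Monte Carlo Dropout

Dropout (rate 0.5 in the Bayesian blocks) stays active at *training and
test* time. Training with dropout plus L2 weight decay on the convolution
kernels is the practical form of variational inference with a Bernoulli
approximate posterior over weights, so a trained network is a posterior
over registration functions rather than a point estimate. At test time,
`M` stochastic forward passes (`mc_sample()`, default `M = 48`) yield
displacement samples `y_1 ... y_M`; their voxelwise mean (`mc_mean()`) is
the field used for the actual registration, and the componentwise sample
standard deviation (`mc_std()`, `M - 1` denominator) is the per-voxel
epistemic uncertainty. Only model (epistemic) uncertainty is estimated —
the spread from what the network has not learned — not aleatoric image
noise.

The three component standard deviations are collapsed to a scalar per
voxel by the Euclidean norm (rotation-invariant; a mean-of-components
variant is available) and min-max normalized *across the entire evaluation
set* (`uncertainty_stats()`), so thresholds in [0, 1] are comparable
between volumes. Whether to normalize before thresholding is a genuine
choice; normalization is the default here because the threshold grid is
defined on [0, 1] and raw standard deviations have no natural scale.
Dropout masks are drawn per activation (standard volumetric dropout
semantics), inverted-scaled by `1/(1-rate)`, and seeded, so every sample
is reproducible from `(seed, i)`.

## Evaluation framework

With labeled regions available, accuracy is measured by per-region Dice
overlap of warped source labels against target labels (`dice_labels()`;
labels are warped nearest-neighbour through the *mean* MC field, never
interpolated). Deformation regularity is the count of nonbackground
voxels with negative Jacobian determinant (`folding_count()`); by default
"nonbackground" means target label > 0 when labels are supplied.

Uncertainty quality asks whether the model is uncertain exactly where it
is wrong. Each nonbackground voxel is *correct* if the warped source
label matches the target label (`correctness_map()`), and *uncertain* if
its normalized uncertainty strictly exceeds a threshold `T` (ties count
as certain, so `T = 1` flags nothing). Over the threshold grid
{0, 0.1, ..., 1} (`threshold_sweep()`):

* `NPV = TN / (TN + FN)` — among certain voxels, the fraction correct;
* `TPR = TP / (TP + FN)` — among incorrect voxels, the fraction flagged;
* `UA = (TP + TN) / total` — overall fraction of desirable cases.

TPR is non-increasing in `T` as a theorem of thresholding (raising the
bar can only shrink the uncertain set); the suite asserts it on arbitrary
inputs. Cells with zero denominators are reported as `NA` rather than 0,
to avoid fabricating values at extreme thresholds.

## Synthetic phantoms and what they do (not) show

`make_phantom()` builds labeled volumes: nested shells around the grid
centre, boundary-perturbed by a smooth random field, each with a distinct
mean intensity plus Gaussian noise, min-max normalized to 0-255.
`make_smooth_deformation()` draws Gaussian-smoothed random vector fields
rescaled to a target maximum amplitude and, by default, rejection-samples
until the field is fold-free (capped retries). `make_pair()` applies a
ground-truth field to a phantom to produce a misaligned source, so
parameter-recovery tests can compare predictions against the (inverted)
known deformation — information the unsupervised method itself never
sees. `insert_lesion()` overwrites a seeded sphere with a fixed intensity
to emulate an out-of-distribution abnormality.

Defaults: 32^3 grids, 5 regions (mirroring the five cortical regions
typically scored), noise s.d. 6/255, deformation amplitude 2.5 voxels at
smoothness 4 — smooth, modest, anatomically plausible misalignments. The
phantoms deliberately mimic the *evaluation structure* of brain data (a
handful of labeled regions, smooth deformations, intensity noise), not
its anatomy or MRI physics (no bias fields, no Rician noise, no MNI
geometry). Passing tests on phantoms therefore demonstrates that the
machinery — warping, losses, optimization, uncertainty calculus, metrics
— is correct and that the method behaves as designed at small scale; it
does not certify accuracy numbers on real brain MRI.

## Desk-scale study design

The full-scale study behind this method trains for ~29,000 iterations on
thousands of 144x180x144 brain pairs; that is not reproducible on a
single CPU. The package's own reproduction (`scripts/acceptance.R` and
the acceptance test file) is a scaled-down design, chosen once:

* 16^3 phantoms with **3** regions (at 16^3, five nested shells would be
  about one voxel thick — thinner than the structures Dice is meant to
  score; three shells keep regions 2+ voxels thick, comparable in
  relative thickness to the full-scale regions);
* ground-truth deformations of amplitude 5 voxels at smoothness 5: on a
  16-voxel grid the misalignment must be strong and coarse-scaled for a
  short training run to carry signal, so the study uses displacements
  around a third of the grid extent varying on a scale of about a third
  of the grid (the package-wide generator defaults, amplitude 2.5 at
  smoothness 4, describe milder misalignment appropriate for 32^3 use);
* 10 training pairs, 50 epochs (500 iterations) at learning rate 1e-4,
  `alpha = 1`, `beta = 1e-4`, dropout active, batch size 1, weight decay
  1e-5;
* the smallest practical network at `base_channels = 16` (about 870k
  parameters);
* evaluation on 6 held-out pairs through the Monte Carlo mean field with
  `M = 16` samples (the registration field the method actually
  prescribes), plus a lighter `beta` contrast {0, 1e-3} (base_channels 8,
  6 pairs, ~200 iterations) for the folding trend, and a lesioned-vs-clean
  uncertainty comparison for out-of-distribution detection. The lesion
  is a dark sphere (radius 4, intensity 0) centred in the tissue — a
  fluid-like anomaly maximally unlike the bright-core training
  distribution, and the comparison averages uncertainty over the
  nonbackground domain (the same domain the other metrics use). Both
  choices matter: a dark lesion overlapping the dark background is
  in-distribution and invisible, and bright lesions inside
  already-bright tissue raise uncertainty locally but the effect can
  vanish in a whole-volume mean — limitations worth knowing when using
  image-level uncertainty as an abnormality flag.

At this scale the network is only partially converged, so the expected
outcomes are directional: registered Dice above the unregistered
baseline, endpoint error below the zero-field baseline, folding counts
non-increasing in `beta`, and higher mean uncertainty on lesioned inputs
— the qualitative signatures of the full-scale results, not their
magnitudes.

## Numerical choices and edge cases

* Out-of-bounds warp samples are clamped to the volume boundary; clamped
  coordinates get zero gradient (a valid subgradient at the boundary).
* Nearest-neighbour label ties at exactly .5 round half up, for
  determinism.
* The trilinear warp is non-smooth at integer crossings; gradient checks
  use interior points and tolerate the measure-zero kinks.
* `mc_std()` requires `M >= 2`; uncertainty normalization errors out if
  the evaluation set has zero spread (`max == min`) instead of dividing
  by zero.
* Dice on two empty masks, constant-volume CC, and all-background
  correctness domains raise typed errors rather than returning NaN.
* Adam runs with the conventional moments (0.9, 0.999); weight decay
  applies to convolution kernels only, not biases, PReLU slopes or
  group-norm affines.
* All generators and stochastic passes are pure functions of their seeds;
  training with a fixed seed is bitwise reproducible.

## Known limitations

* Pure-R training is practical up to roughly 32^3 volumes; full-scale
  brain MRI needs a GPU framework.
* The predicted field is a raw displacement, not a diffeomorphism:
  folding is penalized, not excluded (no scaling-and-squaring
  integration, no inverse-consistency).
* Only epistemic uncertainty is estimated; an over-confident converged
  network can be wrong and certain.
* Global CC is insensitive to small localized misalignments; a windowed
  similarity would be needed for fine-grained registration quality.
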