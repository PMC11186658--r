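---
title: "Bucket-based augmentation policy search for 3D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bucket-based augmentation policy search for 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bucketaugment)
```

## The problem

Segmentation networks trained on CT volumes from one institution often
degrade sharply on scans from another scanner or protocol: intensity
calibration, contrast, noise level and voxel spacing all shift, while the
anatomy and the labelling rule stay the same (covariate shift). Data
augmentation is the cheapest defence, but which transforms, at which
strengths, and in which combination is dataset-dependent, and an exhaustive
search over stacks of parameterized volumetric transforms is infeasible —
with 10 transforms at 15 magnitudes each, a stack of 5 already spans
$(10 \times 15)^5$ configurations.

## The method

BucketAugment collapses that space into $N_b$ random *buckets*. A bucket is
an ordered stack of $N_{op}$ transforms, each drawn uniformly (with
replacement) from the ten-transform bank, with a magnitude bin drawn
uniformly from a 15-bin grid and then **frozen**. The search problem becomes
a small discrete one — which bucket helps the network generalize — and is
solved *inside* the ordinary training loop by a tabular Q-learning
controller:

* every $K$ epochs the model is validated;
* the reward is $+1$ if validation loss fell, $-1$ if it rose, $0$ if
  unchanged;
* the reward is added to the active bucket's Q score;
* on a negative reward the controller advances to the next bucket in cyclic
  order; otherwise the active bucket keeps augmenting every training sample.

The previous loss is initialized to a sentinel of 1000, so the first
validation always rewards the starting bucket, and it is replaced by the
observed loss after every validation. At the end of training the Q-table
ranks the buckets; the argmax (ties to the lowest index) is the discovered
policy, exportable as a small JSON document.

Two reference behaviours bracket the search: `augmentation_mode = "none"`
(no augmentation) and `"trivialaugment"`, which applies exactly one
uniformly drawn transform at a uniformly drawn strength per sample and needs
no search at all.

### The transform bank

| transform            | range      | operator                                              |
|----------------------|-----------|--------------------------------------------------------|
| identity             | —         | no-op (a genuine arm, since application probability is 1) |
| translation          | 0–10      | shift by *m* voxels, random axis and sign              |
| elastic deformation  | 50–150    | random displacement field, peak 0.02·*m* voxels        |
| zooming              | 1–2       | isotropic magnification about the centre, centre-crop  |
| rotation             | 0–0.52 rad| rotation about a random principal axis through centre  |
| intensity            | 0.1–1     | multiplicative scaling (1 neutral)                     |
| contrast             | 1–5       | gamma on \[0, 1\] (1 neutral)                          |
| sharpening           | 10–30     | unsharp mask, amount *m*/10, blur σ = 1                |
| smoothing            | 0.1–2     | Gaussian blur, σ = *m* voxels                          |
| gaussian noise       | 0.1–0.3   | additive zero-mean noise, sd = *m*                     |

Each range is divided into 15 evenly spaced magnitudes including both
endpoints (step = (max − min)/14). Spatial transforms warp image and label
through one shared inverse map — trilinear interpolation for the image,
nearest neighbour for the label — which is what guarantees that output label
values are always a subset of the input's. Intensity transforms touch the
image only. All outputs are clipped to \[0, 1\].

Where a named transform admits several reasonable operators (is "intensity"
multiplicative or additive? what smooths the elastic displacement field?),
this package fixes one conventional choice, documents it, and keeps it
configurable through range overrides rather than claiming it is the only
reading: intensity is multiplicative, contrast is gamma, sharpening is
unsharp masking, and the elastic field is per-voxel uniform noise smoothed
with a fixed σ = 8 voxel Gaussian, rescaled to unit peak and scaled by
0.02·*m* voxels. Every choice is neutral-tested where a neutral value exists
(zoom 1, rotation 0, translation 0, amplitude 0 are exact identities).

### Controller subtleties

Two readings of the update rule coexist in descriptions of this kind of
controller: one where an exactly unchanged loss leaves the Q-table alone
(reward 0), and one where any non-increase increments the score. The first
is this package's default; the second is available via
`init_controller(equal_loss = "increment")`. Exact loss ties are measure-zero
for continuous losses, so the distinction matters mostly for degenerate
mock runs.

Q updates are plain ±1 increments — no learning rate, no discount. The
Q-table is therefore exactly the running sum of rewards per bucket, which
the tests exploit as a conservation invariant: `sum(q)` must equal the sum
of all rewards in the history at all times, and the active bucket changes
if and only if the last reward was −1.

`run_mock_search()` exists to study convergence without a model: each round
the loss moves down with the active bucket's improvement probability and up
otherwise. The walk is multiplicative, `loss ← loss · exp(±step + ε)`, with
step 0.05 and ε ~ N(0, 0.01) on the log scale. An additive walk was
rejected because a strongly improving bucket drives it to a floor within a
few hundred rounds, where exactly-equal losses freeze the controller; the
multiplicative walk keeps losses strictly positive and strictly ordered for
any horizon. With improvement probabilities (0.3, 0.3, 0.9, 0.3) and 200
rounds, the best bucket is identified in effectively every replicate.

## The training harness

`train()` is model-agnostic: anything implementing the three-generic
contract — `fit_step()` (consume a batch, return updated state and loss),
`validate_loss()` (deterministic scalar loss on a held-out set),
`predict_labels()` (image array in, label array out) — can be trained. One
bucket is active per validation interval and is applied, with fresh
per-application randomness, to every training patch in that interval;
validation and test data are never augmented. Preprocessing follows CT
practice: per-sample min-max intensity normalization to \[0, 1\] and
non-overlapping cubic patching with zero padding (96³ patches at full scale;
16³ in the examples here). The loss is the unweighted sum of soft-Dice and
voxel-mean cross-entropy; evaluation is per-class mean Dice over volumes.
Sliding-window inference is deliberately not implemented — evaluation runs
per patch, which is sufficient for policy search and keeps the harness
small.

The built-in `toy_trainer()` is a deliberately minimal fixture: per-voxel
multinomial logistic regression on four features (bias, intensity, and
Gaussian-smoothed intensity at σ = 1 and 2), trained by full-batch gradient
descent (default learning rate 30, chosen once as the largest setting that
was stable for these per-voxel-mean gradients). It exists so the complete
pipeline runs and is testable on a laptop CPU in seconds; it is *not* a
stand-in for a segmentation network, and its absolute Dice numbers carry no
meaning beyond "the plumbing works and augmentation choices move the
numbers".

## The synthetic phantoms

`make_phantom()` builds an intensity-coded phantom: background 0.2, one or
more large ellipsoids at 0.6 (class 1, liver-like), paired small ellipsoids
at 0.85 (class 2, kidney-like), with organ centres and semi-axes jittered
±5% per volume. Appearance parameters — additive intensity offset, gamma,
additive Gaussian noise (default sd 0.05), voxel spacing — transform the
image only; the label grid is generated before any of them apply.
`make_domain_pair()` draws a source set and a target set whose appearance
parameters are shifted (the demo uses offset −0.15 and noise +0.10, a
plausible scanner/protocol gap after \[0, 1\] normalization), while the
geometry process is shared: covariate shift only, by construction.

What the phantoms do *not* emulate: real CT texture, partial-volume effects,
beam hardening, anatomical variability beyond ellipsoid jitter, or
inter-dataset labelling differences. Passing tests on phantoms therefore
demonstrate the correctness of the transforms, the controller, and the
harness plumbing — not that any particular policy transfers to real
abdominal CT. On real data the same code applies unchanged via
`read_volume()`/`write_volume()` (NIfTI), `remap_labels()` for merging
paired-organ ids, and a user-supplied trainer.

## Numerical choices and degenerate inputs

* Interpolation: trilinear for images, nearest for labels; out-of-field
  voxels fill with 0 / background.
* Gaussian smoothing uses a truncated (3σ) kernel with border
  renormalization, so every output voxel is a convex combination of inputs
  and the value range never expands.
* Neutral magnitudes short-circuit to the untouched input, making the
  identity properties bit-exact rather than within-tolerance.
* Constant volumes are rejected by `normalize_volume()` (zero dynamic
  range); NaN, infinite or negative validation losses are rejected by the
  controller; magnitudes outside a spec's declared range are rejected at
  application time, which catches hand-edited or corrupted bucket files.
* `dice_score(∅, ∅)` is defined as 1; a class absent from both prediction
  and truth contributes a soft-Dice of 1.
* All randomness flows through seeds: transforms and buckets accept a
  `seed` argument (implemented with `withr::with_seed`, so the global stream
  is left untouched), and a whole training run is reproducible — two runs of
  the demo pipeline with the same configuration produce byte-identical logs
  and Q-tables.

## Problem sizes used in examples and tests

The test suite and the demo pipeline use 32³ phantoms with 16³ patches,
8 source and 4 target volumes, 6 epochs with validation every 2, and search
spaces of up to 10 buckets × 5 operations — sizes chosen so a full run takes
seconds while still exercising every code path, including multi-patch
tiling and multi-validation controller traces. Mock-search convergence is
assessed over 100 independent 200-round replicates.

## A worked run

```{r demo, eval = FALSE}
res <- run_training(list(epochs = 6, seed = 1), out_dir = "run")
res$log                      # one row per validation: epoch, loss, reward, bucket
glance(res$controller)       # best bucket and total reward
attr(res, "target_dice")     # per-class Dice on the shifted target domain
autoplot(res$controller)     # Q-table bar chart
```

The same pipeline is exposed on the shell through the thin dispatcher in
`inst/cli/bucketaugment` (`demo-synthetic`, `train`, `apply-bucket`,
`inspect-qtable`).

## Known limitations

* The controller is purely reactive — no exploration bonus, no discounting,
  no skipping of low-scoring buckets later in training; with very noisy
  validation losses the ±1 reward is a high-variance signal and long runs
  are needed before the ranking stabilizes.
* One bucket serves all training samples in an interval; per-image adaptive
  policies are out of scope.
* Magnitudes are frozen at initialization: the search is over bucket
  membership, not over continuous magnitude refinement.
* Volumes are processed in index space; no world-coordinate resampling is
  performed, so datasets with very different spacings should be resampled
  upstream if that matters for the application.
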