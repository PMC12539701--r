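---
title: "Classifying bee pollen producers from macroscopic color images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bee pollen producers from macroscopic color images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific model

`pollentrace` treats a macroscopic pollen photograph as a *bag of colored
grains*. The scientific premise is floral constancy: a honeybee colony keeps
visiting the plant species it has adopted, so the species mixture — and
therefore the grain *color* mixture — of a producer's pollen is stable over
time and characteristic of the local flora. The classification target is the
producer; because every producer operates in exactly one municipality,
producer predictions induce municipality-of-origin predictions by a
many-to-one relabeling.

The pipeline assumes:

* images are acquired under standardized lighting on a near-uniform,
  non-reflective template, 8-bit RGB, at least 16×16 px (in practice
  hundreds of pixels across);
* the pollen region is *textured* relative to the background, so local
  gray-level entropy separates the two;
* grain shadows are *achromatic* (gray), so chroma — distance to the RGB
  cube diagonal — separates shadow from grain;
* color composition, not grain shape or texture, carries the producer
  signal.

## Pipeline stages and tunable parameters

### Segmentation

`segment_pollen()` computes the Shannon entropy (base 2) of quantized gray
levels in circular patches and thresholds the entropy map with Otsu's
method; the high-entropy class is pollen. Parameters:

* `radius` (pixels, default 5): patch radius. Smaller radii track grain
  boundaries more tightly but are noisier.
* `n_bins` (default 256): gray quantization of the local histogram, matching
  8-bit depth. Entropy is bounded by `log2(min(patch size, n_bins))`.

Numerical choices fixed by the package: gray conversion is the luminance row
`0.299 R + 0.587 G + 0.114 B` of the RGB→XYZ matrix (so segmentation and
the color model share one lightness definition); border patches are
truncated to in-bounds pixels rather than padded; Otsu operates on a
256-level quantization of the entropy range, ties broken toward the lowest
level, and the returned cut is the midpoint between the two classes'
adjacent levels; an input whose range is numerically zero (relative spread
below 1e−12) is a degenerate-input error rather than an arbitrary
threshold.

### Shadow removal

`remove_shadows()` computes, for every masked pixel, the Euclidean distance
`d(P) = ||U × P|| / ||U||` to the achromatic axis `U = (1,1,1)` and removes
masked pixels with `d` below one standard deviation (`stats::sd`, computed
over the masked pixels only, on [0,1]-scaled RGB) of those distances.

Two points here were genuinely open and are worth recording:

* **Direction of the rule.** Read literally, one could *keep* the
  near-achromatic pixels; but the stated purpose of the step is to discard
  gray shadow pixels, and only removing `d < σ` achieves that (a pure gray
  has `d = 0`). The package removes low-chroma pixels by default and exposes
  `rule = "keep_low"` for the literal reading.
* **Scope of σ.** σ over masked pixels (not the whole image) makes the rule
  adaptive to the sample's own chroma spread; this is the implemented
  choice.

If σ = 0 (all masked pixels identical in chroma) the mask is returned
unchanged; the refined mask is always a subset of its input.

### Color representations

`rgb_to_hsv()` computes hue as `atan2(√3 (G − B), 2R − G − B)` wrapped to
[0, 2π). The two-argument arctangent is deliberate: a single-argument
arctan of the same ratio is quadrant-ambiguous and would fold opposite hues
together. Saturation is `C/V` (0 for achromatic pixels, where hue is 0 by
convention); value is `max(R,G,B)`. Hue and saturation are invariant to
multiplying RGB by a constant in (0,1] — the illumination invariance that
motivates this space.

`rgb_to_xyz()` is the linear map with rows
(0.607, 0.174, 0.200 / 0.299, 0.587, 0.114 / 0, 0.066, 1.116).
`xyz_to_luv()` applies the two-branch lightness law on `y = Y/Y0`
(`116 y^{1/3} − 16` above 0.008856, `903.3 y` below; the branches agree to
~1e−3 at the cut) and the chroma offsets `u* = 13L(4X/D − u0)`,
`v* = 13L(vY/D − v0)` with `D = X + 15Y + 3Z` and white point
`u0 = 0.19793943`, `v0 = 0.46831096`, `Y0 = 1` (RGB white maps to `Y = 1`
under the matrix above, hence the normalization).

One inconsistency is resolved explicitly: the primary convention uses
`v' = 6Y/D`, but the white-point constant `v0` above is the CIE-1976 value
that corresponds to `v' = 9Y/D`. The package implements the `6Y/D` form as
its default and provides `v_prime = "cie1976"` as a switch; all tests of
self-consistency (white maps to zero chroma) use the CIE-1976 branch, where
the constants are mutually consistent. Black (`D = 0` or `L = 0`) maps to
`(0, 0, 0)`.

Four feature representations are supported: `hsv`, `luv` (3-D) and the
chroma-only projections `hs`, `uv` (2-D). Hue is fed to the quantizer as a
plain coordinate — its circularity is *not* unwrapped, a known artifact of
the `hsv`/`hs` representations (red hues near 0 and 2π quantize to
different codebook colors); `uv` does not suffer from this and is the
recommended default.

### Color codebook features

`fit_codebook()` learns `k` representative colors by mini-batch k-means:
k-means++ seeding, then mini-batches (default `batch_size = 4096`,
`n_iter = 100`) with per-center learning rates `1/n_j` (each center is the
running mean of the samples it has absorbed), then one full-batch Lloyd
polish step that recomputes every non-empty center as the exact mean of its
assignment. The polish makes degenerate cases exact (`k = 1` returns the
pixel mean; point-mass clusters are recovered exactly) and removes
mini-batch jitter. Centroids are stored in lexicographic order so the
codebook is independent of optimizer labeling; fitting is bit-for-bit
reproducible under a fixed seed.

`k` is constrained to 16–35 — the number of plant species observed per
sample in palynological analyses of this kind of material — with default 32.
When sweeping `k`, the codebook is refit per `k`.

Two design decisions:

* **Codebook scope.** Fitting the quantizer on *all* images leaks test
  pixels into the representation. The default is `train_only`; `scope =
  "all"` is available for comparison.
* **Relative frequencies.** Histograms are normalized to sum to 1 (not raw
  counts), so images with different pollen areas are comparable.

`pool_pixels()` caps pixels per image (default 2000) for tractability;
subsampling is seeded and deterministic.

### Classifier grid and selection

`default_grid()` spans polynomial-kernel SVMs (degrees 4–10, `C = 0.91`,
`coef0 = 1.3`, `gamma = 1`, features unscaled since histograms already live
in [0,1]), random forests (50/100/200 trees) and MLPs, crossed with the four
representations. The MLP backend is `nnet`, which supports a single hidden
layer; the grid therefore uses one layer of 32/64/128 units. This is a
deliberate narrowing: multi-layer perceptrons are reported as the weakest
family for this task, and a second layer would add cost without changing
the comparison's outcome.

Selection is by stratified 10-fold cross-validated weighted F1 (class sizes
as weights) on the training split. Folds deal each class's shuffled members
cyclically, so per-fold class counts differ by at most one from
proportionality; a class smaller than the fold count is an error. Exact
score ties go to the lower-complexity spec (SVM degree, forest size, hidden
units), then to the lexicographically smaller spec identity, making
selection order-independent. A fold whose training part is single-class is
scored 0 with a warning. Class imbalance is handled *only* via
stratification and weighted F1 — no resampling or class weights.

### Evaluation

`metrics()` fixes the zero-division conventions explicitly: a class never
predicted has precision 0; a class with no true samples has recall 0; F1 is
0 when precision and recall are both 0. Balanced accuracy is the plain mean
of per-class recalls over classes with support (no chance-level
adjustment). The municipality rollup maps both label vectors through the
producer→municipality function and recomputes metrics; because this is a
partition coarsening, rollup accuracy is never below producer accuracy.
`temporal_table()` scores each sampling visit independently.
`test_retest()` computes per-producer F1 separately on the two acquisition
rounds and returns their Pearson correlation r₁,₂; a constant F1 vector in
either round makes the correlation undefined and raises an error rather
than silently returning 0.

## The synthetic generator

`generate_dataset()` emulates the structure of a field campaign: by default
20 producers across 10 municipalities (two per municipality), 4 sampling
visits, 14 samples per visit, 4 images per sample — two acquisition rounds
of two images — for ≈4,480 images at full scale, split ~2:1 train:test per
producer with test images balanced between rounds. Tests and the
acceptance script use the scaled-down study the package validates at desk
scale: 10 producers × 4 visits × 3 samples × 4 images (480 images at
256×256), which keeps the full suite within tens of minutes on one CPU.

What it emulates, and how the knobs map to biology:

* **Shared flora, different proportions.** All producers draw grain colors
  from one global pool of `palette_size` (default 24, middle of the 16–35
  species range) base colors; a producer is its mixture-weight vector.
  `separation` (default 0.40) pulls each producer's weights from a common
  Dirichlet draw toward a producer-specific mode; `separation = 0` makes
  all producers identical, so any classifier must fall to chance.
* **Geographic structure.** Producers of one municipality blend a shared
  municipality mode into their own by an affinity that ramps evenly from 0
  to `municipality_affinity` (default 0.9) across municipalities. This
  reproduces two features of real material: misclassifications concentrate
  between closely located producers, and municipality-level accuracy
  exceeds producer-level accuracy. The defaults were calibrated once so the
  desk-scale study operates in the regime reported for real pollen imagery
  (~85–90% producer accuracy with imperfect, *persistently* difficult
  pairs); they are study conditions, not fitting targets.
* **Temporal drift.** `visit_drift` (default 0.03) applies a multiplicative
  log-normal perturbation to the weights per (producer, visit),
  representing seasonal shifts in the pollen spectrum; the perturbation
  depends only on producer and visit, not on the image, so images of one
  visit share one drifted spectrum.
* **Acquisition.** Grains are ellipses (semi-axes 4–9 px) with per-grain
  palette colors plus small per-pixel noise, covering `coverage` (0.35) of
  the frame, centers rejected on existing grains; the background is a flat
  gray (0.8) jittered per image by `illumination_jitter` (0.02); each grain
  casts a partial achromatic ring shadow darkened by `shadow_strength`
  (0.35). Shadows are exactly achromatic, which is what makes them
  removable by the one-σ chroma rule — and is also the main idealization.

What it does **not** emulate: photorealistic grain texture, optics (blur,
vignetting, sensor noise), color-calibration drift between devices,
non-elliptical or clumped grains, and backgrounds with texture. Passing the
package's tests therefore demonstrates internal correctness of every stage
and end-to-end recoverability of a planted producer signal under the stated
idealizations — not field performance on real photographs, which depends on
acquisition discipline the generator assumes away.

## Determinism

Every stochastic stage (palette and image synthesis, pixel subsampling,
k-means seeding and batching, fold shuffling, forest and MLP fitting)
derives its seed from a single run-level integer through a fixed folding
function, so identical configurations and seeds reproduce identical
datasets, codebooks, models and predictions bit for bit.

## Known limitations

* The entropy segmentation needs a textureless background; textured
  surfaces would require morphological post-processing that is deliberately
  out of scope.
* Hue circularity is unhandled in `hsv`/`hs` (see above).
* The classifier is closed-set: adding a producer requires retraining.
* Reliability r₁,₂ is undefined when a round's per-producer F1 is constant
  (e.g. a perfect classifier); the pipeline reports this as a warning and
  omits the coefficient rather than fabricating a value.
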