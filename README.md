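# pollentrace

Producer classification of corbicular bee pollen from macroscopic color
images.

## The problem

Bee pollen is traded as a premium food product, and buyers increasingly want
verifiable information about where it was produced. The standard ways of
establishing pollen origin — palynology (microscopic identification of the
plant species in a sample) and physicochemical profiling — need expert
analysts and laboratory equipment that most actors in the supply chain,
especially in developing regions, cannot access.

There is, however, a cheap signal: color. Honeybees exhibit floral
constancy — a colony keeps foraging the same plant species once adopted — so
the pellets a producer's hives collect show a stable *mixture of grain
colors* that reflects the local flora. A flat-lay photograph of a pollen
sample under controlled lighting therefore carries a producer-specific color
fingerprint. `pollentrace` implements a complete pipeline that turns such
photographs into producer (and hence municipality-of-origin) predictions,
for researchers and traceability practitioners working on image-based food
authentication.

## The method

For each image the pipeline:

1. **Segments the pollen region.** Grains are textured, the acquisition
   template is flat, so the Shannon entropy of gray levels in circular
   patches (radius 5 px) separates pollen from background; the entropy map
   is thresholded with Otsu's method. Residual grain *shadows* are then
   removed: a shadow pixel is near-achromatic, i.e. close to the gray
   diagonal of the RGB cube, so masked pixels whose distance to that axis
   `d(P) = ||U × P|| / ||U||` (with `U = (1,1,1)`) falls below one standard
   deviation of the masked-pixel distances are dropped.
2. **Re-expresses colors.** Pixels are transformed to HSV
   (hue via the quadrant-aware arctangent of
   `(√3(G−B), 2R−G−B)`) or to CIE L\*u\*v\* (via an RGB→XYZ matrix and the
   cube-root lightness law), and projected onto one of four
   representations: `hsv`, `luv`, `hs`, `uv`. The chroma-only `uv` pair is
   the strongest performer, being insensitive to residual lighting
   variation.
3. **Quantizes colors into a codebook.** Mini-batch k-means (k-means++
   seeding, per-center learning rates, final full-batch polish) learns `k`
   representative colors from training-image pixels; `k` is kept in 16–35,
   the range of plant species found per sample palynologically, with
   `k = 32` the default. Each image becomes the `k`-vector of relative
   frequencies of its pixels' nearest codebook colors.
4. **Classifies and evaluates.** A grid of multiclass classifiers
   (polynomial-kernel SVMs of degree 4–10, random forests up to 200 trees,
   single-hidden-layer perceptrons) × the four representations is scored by
   stratified 10-fold cross-validated weighted F1; the winner is refit and
   evaluated on the held-out test split: accuracy, balanced accuracy,
   macro/weighted precision, recall and F1, per-visit temporal tables, a
   municipality rollup (producers map many-to-one onto municipalities, so
   rollup accuracy is provably no lower), and test–retest reliability

   r₁,₂ = Σᵢ(fᵢ,₁−f̄₁)(fᵢ,₂−f̄₂) / √( Σᵢ(fᵢ,₁−f̄₁)² · Σᵢ(fᵢ,₂−f̄₂)² ),

   the Pearson correlation between per-producer F1 vectors computed on the
   two time-separated acquisition rounds of the test images.

Because field-collected pollen image datasets are not generally available,
the package ships a **synthetic generator** (`synth_config()`,
`generate_dataset()`) that emulates their structure — producers as mixture
weights over a shared regional color pool, visits as small spectrum drifts,
municipalities as groups of producers with correlated flora, grains with
achromatic partial shadows — together with ground-truth masks and palettes,
so every pipeline stage can be validated against a known answer.

## Worked example

```r
library(pollentrace)

cfg <- synth_config(n_producers = 5L, n_visits = 4L, samples_per_visit = 3L,
                    image_size = c(128L, 128L), seed = 5L)
man <- generate_dataset(cfg, "pollen_demo")      # 240 images + manifest

grid <- default_grid(representations = "uv", ks = 32L,
                     svm_degrees = c(4L, 6L), families = "svm_poly")
res <- run_pipeline(man, representation = "uv", k = 32L, grid = grid,
                    seed = 11L)

print(res$best_spec)
print(res$producer_metrics)
print(res$municipality_metrics)
print(res$temporal)
```

Output of this exact run:

```
svm_poly(C=0.91,coef0=1.3,degree=6)/uv/k32
accuracy 0.9500 | balanced 0.9500 | macro P/R/F1 0.9499/0.9500/0.9496 | weighted F1 0.9496
accuracy 0.9625 | balanced 0.9688 | macro P/R/F1 0.9690/0.9688/0.9687 | weighted F1 0.9625
  visit balanced_accuracy weighted_recall weighted_precision weighted_f1
1     1              0.95            0.95               0.96   0.9492063
2     2              0.90            0.90               0.90   0.9000000
3     3              1.00            1.00               1.00   1.0000000
4     4              0.95            0.95               0.96   0.9492063
```

The first block is the model selected by cross-validation (a degree-6
polynomial SVM on the u\*v\* codebook histograms). The second line says 95%
of the 80 held-out test images were assigned to the right producer; the
third that rolling predictions up to municipalities raises accuracy to
96.25% (within-municipality confusions cancel out). The per-visit table
shows the classifier holds up across the four seasonal sampling visits.

A command-line front end for the same steps is installed with the package
(`inst/scripts/pollentrace`): `pollentrace generate|segment|train|evaluate|reliability`.

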