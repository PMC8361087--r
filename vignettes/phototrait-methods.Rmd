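---
title: "Predicting plant functional traits from photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant functional traits from photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modelling idea

Plant functional traits — leaf area (LA), growth height (GH), specific leaf
area (SLA), leaf nitrogen concentration (LNC), seed mass (SM) and stem
specific density (SSD) — summarise the main axes of plant form and function
but are laborious to measure. Trait databases hold species-level
measurements; citizen-science platforms hold hundreds of millions of
geolocated plant photographs with species identifications. `phototrait`
implements a weakly supervised bridge between the two: every photograph of a
species inherits that species' trait distribution as its (noisy) regression
target, and a convolutional network is trained to predict the trait from the
pixels, optionally fused with the climate of the photograph's location.

The supervision is *weak* in a precise sense: the label attached to an image
is not a measurement of the photographed individual but the mean (and
standard deviation) of its species' measurements. The package's design
choices all flow from managing the consequences of that weakness.

## Pipeline stages

1. **Trait ingest.** Trait records in standardized units are filtered with a
   pooled z-score rule (`removeTraitOutliers`, default `zMax = 4`), then
   aggregated per species into mean, sample SD and record count
   (`computeSpeciesStats`). The threshold is read as a standardized
   deviation, not an absolute difference: an absolute rule would be
   unit-dependent and meaningless across six traits with different units.
   The sample (n−1) SD is used, the convention of trait databases; a species
   with a single record has SD 0 and therefore no plasticity distribution.
   A recomputed z-score filter is not idempotent as a mathematical identity
   — removing a gross outlier shrinks the pooled SD and can newly expose
   borderline records — but for gross outliers over a compact bulk (the
   regime the rule targets) a second pass removes nothing, and the test
   suite pins that behaviour.

2. **Occurrence ingest.** Records lose eligibility for missing or
   out-of-bounds coordinates or a reported coordinate uncertainty above
   100 km (boundary inclusive; *unknown* uncertainty is kept, because
   occurrence exports routinely omit the field and dropping them would
   silently discard most data). Bioclim predictors BIO1, BIO4, BIO7, BIO12,
   BIO15 and the derived annual precipitation range BIO13 − BIO14 are
   extracted at each photo location by nearest-cell lookup (no
   interpolation; at 10-arc-minute-class resolutions the containing cell is
   the natural reading of "extract"). Points that hit no-data (ocean) cells
   are dropped. Rasters are exchanged as ESRI ASCII grids — a plain-text
   georeferenced WGS84 raster format the package reads and writes itself.

3. **Dataset building.** Species present in both sources are linked by
   exact name match after trimming and case folding (no synonym
   resolution). Each species is a sampling stratum capped at
   `maxPerSpecies` photographs (the study design used 8, 2, 3, 3, 1, 5 for
   LA, GH, SLA, LNC, SM, SSD) so the model cannot profit from memorising
   species-specific trait values. Targets are log10-transformed (trait
   distributions are strongly right-skewed), trimmed at 3 SD, and the data
   are split test-first (10% by default, or an explicit `nTest` to
   reproduce published dataset summaries whose printed test counts are not
   exactly 10%), then 4:1 into training and validation with the validation
   share rounded *down* — `validation = floor(remainder/5)` reproduces all
   six published train/validation count pairs exactly. The trim runs once
   per trait dataset, before splitting, so trimming cannot depend on the
   split. Min–max normalisation (targets and each bioclim variable
   separately) uses training-partition extrema only; validation and test
   values may fall slightly outside [0, 1] and are deliberately not clipped
   at this stage — clipping would hide the leakage-freedom property the
   tests assert.

4. **Plasticity target augmentation.** When a species has a trait SD, each
   *presentation* of a training image redraws its target from
   Normal(μ, σ) truncated to [μ−σ, μ+σ] in original units, then
   log10-transforms, normalises and clips to [0, 1]. Sampling in original
   units is chosen because μ and σ are computed there; a config switch is
   not offered because the log-scale alternative changes the meaning of σ.
   The sampler is the exact inverse-CDF construction
   `qnorm(runif(n, pnorm(lo), pnorm(hi)))`, so truncation is exact rather
   than rejection-based. The symmetric truncation preserves the mean, which
   the tests verify by Monte Carlo against 3 standard errors. A fresh draw
   per presentation (rather than one frozen draw per record) parallels
   image augmentation, which is also redrawn per presentation. If σ = 0 for
   every record in a batch the deterministic targets are returned without
   consuming randomness, so a zero-SD dataset makes plasticity training
   bit-identical to baseline training under one seed — a property the
   acceptance suite asserts.

5. **Regression model.** The regressor follows the published head design:
   image-only — global average pooling, dense 512 (relu), dense 1 (linear);
   mixed — image branch ending in 4 linear units, climate branch 64-32-4
   (last linear), fused regressor 8-8-4-1 (last linear, others relu).
   Training uses MSE, batch size 20, RMSprop at learning rate 0.001 with
   per-step inverse-time decay 0.0001 (`lr/(1 + decay·step)`, the
   convention of the framework generation the recipe stems from; ρ = 0.9,
   ε = 1e−7). Early stopping monitors validation MAE (computed on
   un-augmented images and mean targets) with a patience of 5 epochs and
   best-epoch weight restoration; the published criterion ("no further
   improvement, diverging from training error") is qualitative, and
   patience-with-restore is its standard operationalisation.

   The desk-scale backbone `tiny_test_cnn` is three strided 3×3
   convolutions (8, 16, 32 channels) with global average pooling —
   deliberately small so the full pipeline trains in seconds on a CPU. The
   named large backbones (Inception-ResNet-v2, Xception, MobileNetV2 at
   half width) are accepted as configuration values but require externally
   supplied pretrained weights; constructing them here errors informatively.

6. **Image handling.** Images are center-cropped to a square ("removing the
   spare margins"), bilinearly resized (EBImage) and scaled to [0, 1].
   Augmentation applies independent 50% horizontal/vertical flips and
   scales contrast, saturation and brightness by independent factors
   uniform on [0.9, 1.1], then clips to [0, 1]. The photographic
   definitions used: brightness multiplies all channels; contrast scales
   deviations about the image mean; saturation scales chroma about the
   per-pixel luma (0.299 R + 0.587 G + 0.114 B). The operations are named,
   not formula-defined, in the source recipe; these are the common
   photographic forms and they are pinned by tests (identity configuration,
   involution of flips, clipping).

7. **Evaluation.** MAE; NMAE = 100·MAE/range(test targets) (comparable
   across traits; computed on the normalised scale the models train on,
   with original-unit metrics available by denormalising predictions);
   R² = squared Pearson correlation of predictions vs targets, i.e. the
   explained variance of the linear fit — not agreement with the 1:1 line.
   Constant predictions carry no linear signal and report R² = 0; constant
   targets make NMAE undefined and error. Ensembles average member
   predictions element-wise; the suite asserts the Jensen inequality
   (ensemble MSE ≤ mean member MSE) rather than the false claim that an
   ensemble beats every member. k-fold cross-validation re-randomises the
   full split per fold and pools prediction-target pairs (N = k × N_test).
   Robustness across annotation categories (growth form, image quality,
   image-target distance) uses per-category MAE, category shares, and a
   nonparametric rank test on absolute errors (Wilcoxon for two groups,
   Kruskal–Wallis for more) at α = 0.05; the original analysis does not
   name its test, so no attempt is made to match exact p-values.

8. **Trait mapping.** Normalised predictions are inverted to original units
   (10^denormalise), deduplicated against training/validation records, and
   interpolated by inverse-distance weighting evaluated at the centers of a
   0°30′ WGS84 grid: weights d^−2 over *all* points (no k-nearest cutoff;
   neither power nor neighbourhood is stated in the source, so both are
   configurable and the defaults are declared, not claimed to match),
   great-circle haversine distances on a 6371 km sphere (planar distance is
   wrong at high latitude), an exact-hit rule (a cell center coinciding
   with observations takes their mean), a 100 km buffer mask around
   observations to limit extrapolation, and an optional land mask. The
   quantile-range map is the .9 − .1 quantile difference per cell (linear
   interpolation between order statistics, quantile type 7), computed from
   the raw point values per cell by default or from an s×s subgrid of IDW
   evaluations (`mode = "idw"`) — the source wording is ambiguous between
   the two, so both ship. Latitudinal profiles are unweighted band means of
   unmasked cells. Grid-to-grid comparison resamples bilinearly onto the
   reference geometry and reports Pearson r with its two-sided p over
   jointly unmasked cells. LA and SM maps are displayed log10-transformed;
   `displayTransform` returns a transformed copy and never alters stored
   values.

## The synthetic corpus: what it emulates and what it does not

`generateCorpus` fabricates every input the pipeline consumes, making the
method's working hypothesis — that traits are inferable from visible
features such as organ size and colour intensity — literally true so that it
can be tested. Per image of species *s* at location *x*:

trait = c₀ + c_area·a + c_green·g + c_clim·z(x) + u_s + ε,

where *a* is the ellipse ("leaf") area fraction of the image, *g* the green
intensity of the foreground, *z* the min–max-scaled annual mean temperature
at *x*, u_s ~ N(0, cSpecies) a species effect independent of all features
(for negative controls), and ε the observation noise. Species have range
centers on a toy rectangular landmass with smooth climate gradients, and
their images scatter around those centers, so species mean traits carry a
recoverable climate signal. Trait-table records are drawn
Normal(mean_s, sdFrac·mean_s), making the tabulated per-species statistics
consistent with the latent means up to sampling error.

Default study conditions (chosen once): 100 species × 3–7 images (~500
images), 5 trait records per species, sdFrac 0.1, σ_noise 0.5, 64 px
images, c₀ = 2, c_area = 30, c_green = 8. Three named presets
(`benchmarkSpec`): *informative* (the defaults), *climate* (c_area = 20,
c_green = 0, c_clim = 6.8 — the variances of the image and climate terms
are then approximately equal, giving climate fusion headroom), and
*negative* (all feature coefficients 0, cSpecies = 2, c₀ = 20 — species
means vary but nothing visible predicts them). Problem sizes (500 images,
64 px, ≤ 10 epochs, the tiny backbone) are the package's desk-scale study
conditions; they make the full loop run in about a minute per model.

What the generator does **not** emulate — and hence what green tests do not
show about real data: photographic heterogeneity (occlusion, backgrounds,
multiple species per frame), observation bias of citizen scientists toward
striking species, taxonomy errors, spatially autocorrelated sampling
effort, or any real covariance structure between traits. Passing the
end-to-end checks demonstrates that the machinery recovers signal that is
present and rejects signal that is absent; it says nothing about the
magnitude of performance on real photographs.

## Numerical choices and degenerate inputs

* **Initialisation.** Convolutions and wide dense layers use He-normal
  weights. Narrow relu layers (≤ 64 units: the climate branch and the
  8-8-4 fusion stack) start *all alive*: weight sd 0.4/√fan_in with bias
  0.5, so every unit's initial preactivation sits near +0.5. With He
  variance, a 4-unit relu layer's preactivation means spread ±1.4 around
  the bias and the layer frequently loses all four units during the first
  RMSprop steps — RMSprop's variance-normalised updates move parameters a
  near-constant ~lr per step regardless of gradient size — which silences
  every upstream gradient and freezes the model at a constant prediction.
  The all-alive start makes that failure mode rare without touching the
  architecture, optimiser or learning rate; because it can still occur
  under unlucky seeds, the trainer additionally detects a collapsed run —
  end-of-epoch validation predictions exactly constant, meaning every relu
  path is dead and no gradient can revive it — and restarts from a fresh
  initialisation under a seed derived from the config seed and the restart
  count (at most 5 restarts; dead runs are discarded, so the returned
  model reflects at most `maxEpochs` epochs of training from its final
  initialisation, and the whole procedure remains deterministic in the
  config seed). The final output bias starts at 0.5, the center of the
  normalised target range.
* **Determinism.** A model's build and training are deterministic in its
  config seed under single-threaded BLAS: initialisation, minibatch order,
  augmentation and plasticity draws all derive from it. Library code runs
  under a scoped RNG (`withSeed`) and restores the caller's RNG state.
* **Degenerate guards.** Zero pooled SD retains all records in outlier
  filtering and trimming; a single-record species has SD 0 and bypasses
  the plasticity draw; μ − σ ≤ 0 floors the truncation interval just above
  0 with a warning (keeping log10 defined); zero target range rejects
  normalisation (and NMAE); constant predictions report R² 0; IDW ties at
  a cell center are averaged; the exact-hit tolerance is 10⁻⁶ km.
* **Quantiles** use R's default type 7 (linear interpolation between order
  statistics), declared so test oracles match exactly.

## Known limitations

* The tiny backbone is not a stand-in for full-scale architectures; results
  on the synthetic corpus do not transfer to 512 px real-image training,
  which additionally needs pretrained weights supplied externally.
* IDW with all-point support is O(cells × points); the chunked
  implementation is fine for the package's grids but a k-nearest variant
  would be needed for hundreds of thousands of points at 0.5°.
* Species linkage is exact-name only; real TRY/GBIF joins benefit from a
  taxonomic backbone, which is deliberately out of scope.
* Grid-to-grid Pearson comparison ignores spatial autocorrelation; its
  p-values are optimistic and should be read as descriptive.
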