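---
title: "Trait calibration from leaf spectral libraries and transfer by extra-weighted spiking"
author: "specspike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait calibration from leaf spectral libraries and transfer by extra-weighted spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specspike)
```

## The modeling problem

A leaf VIS--NIR--SWIR spectrum is a reflectance fraction measured at
every nanometre from 350 to 2500 nm (2151 points). Many leaf traits
leave signatures in this range: chlorophyll absorbs strongly in the blue
and red, water at about 970, 1450 and 1940 nm, protein-bound nitrogen in
the 1550--1750 nm amide region, and leaf thickness (LMA) modulates the
optical path length broadly across the NIR. Other macronutrients (K, Ca,
Mg) exist largely as free ions with no direct absorption feature and are
only indirectly predictable through their association with
carbon-bearing compounds.

`specspike` models each of nine traits (N, P, K, Mg, Ca, S in % dry
matter; LWC in %; CHL in µmol m⁻²; LMA in g m⁻²) separately from the
spectrum, supports building and persisting those calibrations from a
*spectral library* of reference samples, and quantifies what happens
when the calibration is applied to an *external* dataset — a different
species, year or environment — including the repair strategy of
extra-weighted spiking.

## Preprocessing

Replicate scans of one leaf are averaged pointwise
(`average_replicate_scans()`; the reference protocol takes nine scans
per leaf). Before modeling, spectra are binned into contiguous 10 nm
windows (`window_average()`), reducing 2151 points to 216 bands: 215
full 10-point windows plus one trailing single-point window at 2500 nm.
Two choices here were genuinely open and are ours:

* windows are anchored at the first wavelength (350 nm), and
* the trailing partial window is **kept**, averaged over the points it
  contains, rather than dropped — this preserves the SWIR edge. Both a
  drop policy and a different anchor are one code change away in
  `window_average_matrix()`.

Reflectance is stored as a fraction in `[0, 1]`. Files whose values look
like percent (maximum above 1.5) are rejected with a hint instead of
being rescaled silently, because automatic rescaling hides unit bugs.
Missing trait measurements are empty CSV fields (`NA` accepted on read)
and propagate as `NA`, never as zero.

## The two regression engines

**PLS1.** Partial least-squares regression with a single response:
predictors are mean-centered (never variance-scaled — all bands share
reflectance units), the response is centered, and latent variables are
extracted by deflating the cross-product vector against an orthonormal
basis of X-loadings. For one response this SIMPLS-style sequence is
algebraically identical to NIPALS PLS1 but never rewrites the predictor
matrix, so one fit with A components costs two matrix--vector products
per component and yields the coefficient vectors of *all* models with
1..A components (they are nested). Cross-validation over the 1--30
latent-variable grid therefore needs exactly one fit per fold. Each
trait is modeled separately (PLS1 rather than a joint PLS2) because
external sets can lack traits entirely — camelina-style sets have no CHL
or LMA — which would break a joint response matrix.

Numerical edge cases: a response with (weighted) zero variance is an
error; if the centered predictors run out of rank before the requested
number of components, extraction stops and the remaining nested
coefficient columns repeat the last extractable model, so predictions
are well-defined for every grid point.

**MLP.** The neural-network comparator is a single hidden layer of relu
units (sizes 5/10/15/20) with an L2 penalty (0.005/0.01/0.03) on the
weights, trained on standardized inputs and response by L-BFGS-B with
analytic gradients from a seeded random initialization, stopping on
vanishing loss change or 2000 iterations. A scalar "hidden layer size"
grid implies one hidden layer, which is how the comparator is built;
training is exactly reproducible at a fixed seed. The optimizer, the
standardization and the stopping rule are implementation decisions, not
claims about any reference workflow.

## Hyperparameter selection

`calibrate()` drops samples missing the target trait, assigns 10
random folds (sizes differing by at most one; plain random, not
stratified — a species-stratified option would be easy to add, but the
default mirrors the simplest protocol), pools the out-of-fold
predictions across all folds and computes one RMSE_CV and R²_CV per
grid point. The chosen point minimizes RMSE_CV; points within one part
in 10⁸ of the minimum are treated as ties and the smallest model wins
(fewest latent variables; smallest hidden size, then smallest penalty).
That tolerance matters only in degenerate cases — on noiseless rank-d
data every model with at least d components reaches machine-level
RMSE_CV and the rule returns d — and is far below any real
between-model difference. Grid points infeasible for some fold (more
latent variables than training samples minus one) get `NA` and are
never chosen. The final model is refit on the whole calibration set at
the chosen point.

The fold seed is shared across traits for a given calibration seed, so
two traits with the same retained samples get identical folds.

## Transfer schemes and extra-weighted spiking

`draw_spike()` selects `n_spike` external samples (20 by default)
uniformly at random; the remainder of the external set is the test set
and is *never* used in calibration (asserted programmatically on every
run). Three schemes are compared:

1. `library_only` — calibrate on the library, predict the test set;
2. `spike_only` — calibrate on the spike samples alone;
3. `spiked_library` — calibrate on the library plus the spike samples
   replicated `r = round(n_library / n_spike)` times.

The replication equalizes the statistical weight of the two groups: with
a 2460-sample library and 20 spikes, `r = 123` and the augmented set has
exactly twice the library's samples. Replicated rows are physical copies
(ids suffixed `.rep<k>`), which is the definition of the procedure; for
weight-aware fitters `spike_weights()` provides the equivalent
case-weight formulation, and a test asserts the two give identical PLSR
coefficients. Rounding to the nearest integer defines the factor for
non-divisible sizes. Each scheme re-tunes its hyperparameters on its own
calibration set (pass a one-row grid to pin them instead); whether a
reference analysis would re-tune or reuse the library model's complexity
is unknowable from outside, and re-tuning is the cleaner default.

`spike_size_sweep()` investigates the cost/benefit of the spike size:
one pool (50 samples by default) is drawn once and held aside; for each
size in {10, 20, 30, 40, 50} a random subset of the pool spikes the
library and performance is measured on the external samples outside the
pool, so all sizes are scored on the same evaluation samples.

## Evaluation

R² is the coefficient of determination `1 − SSE/SST` about the observed
mean — *not* squared correlation — and is reported unclipped, so a model
worse than the test-set mean goes negative (common under domain shift).
Bias is `mean(predicted − observed)`; RPD is the sample SD (n−1) of the
observations divided by the RMSE. Bias and RPD formulas are the standard
chemometric definitions, stated here because they are a convention
choice. `pca_project()` gives the mean-centered PC projection used to
visualize library↔external shift with per-group 95% ellipses.

## The synthetic-data generator

Because measured libraries of this kind are distributed on request
rather than deposited, the package ships a generator whose output has
the statistical structure the analysis assumes. It is explicitly *not* a
radiative-transfer model; it emulates exactly the features the pipeline
is sensitive to:

* **Archetypes.** Each species has a smooth baseline reflectance curve
  (VIS floor, green bump, red edge at ~715 nm, NIR plateau, mild SWIR
  decline) with species-specific plateau and green-bump heights.
* **Trait coupling.** Each trait removes reflectance through Gaussian
  absorption bands at chemically motivated centers (see
  `default_bands()`); the rendered spectrum is
  `clip(baseline + shift − Σ sens·trait·gauss + noise, 0, 1)`.
* **Traits.** Drawn from a truncated multivariate normal (rejection
  sampling) with species-specific means/SDs and a correlation structure
  dominated by the N–chlorophyll association (r = 0.75). All means, SDs
  and correlations are assumptions chosen to be field-plausible — no
  per-species covariances are published for the reference material —
  and are configuration, not constants.
* **Spectral decoupling.** A per-trait fraction of the trait SD is not
  expressed in the spectrum (assay error plus non-optical biology): the
  spectrum is rendered from a perturbed trait value while the reported
  trait stays exact. This caps attainable R² at `1 − frac²` and is what
  makes 20-sample calibrations genuinely weaker than library-scale
  ones. Defaults place the per-trait ceilings at a realistic scale
  (CHL ≈ 0.92, N ≈ 0.84, LWC ≈ 0.44; see
  `default_spectral_decoupling()`). Setting the fractions to zero gives
  the exactly recoverable regime used by the rank-recovery tests.
* **Domain shift.** External species get an additive smooth baseline
  offset plus a multiplicative perturbation of band sensitivities, both
  scaled per species (library species 0, external maize/sorghum 0.5,
  soybean 1.0, camelina 1.6 — the most distinct group) and globally by
  `shift_magnitude`. Zero magnitude with identical archetypes makes
  library and external draws statistically indistinguishable, which a
  test verifies via t-tests on PC1 scores.
* **Per-scan noise.** i.i.d. Gaussian reflectance noise, SD 0.005 by
  default; spectra are generated already scan-averaged (replicate-scan
  simulation is available by rendering with larger noise and averaging).

What passing tests on this generator do **not** show: robustness to
instrument drift, scattering nonlinearity, water-band saturation or any
feature of real leaf optics beyond linear band superposition. The
generator validates the *pipeline logic* (leakage-free schemes, correct
weighting, selection behavior, metric identities, qualitative transfer
behavior), not biology.

## Reproducibility and problem sizes

Every random step is seeded, and composite runs derive stage seeds from
one root seed by hashing stage names (`derive_seed()`), so a rerun of a
single stage reproduces its state inside a full run; pipeline outputs
carry the configuration hash in a header comment. Identical
configurations reproduce studies byte-for-byte.

The test-suite and acceptance-script studies are scaled-down versions of
the full layout — libraries of 220--300 samples on the raw or a thinned
grid, external sets of 60--126, PLSR grids to 10 latent variables,
5--20 Monte-Carlo seeds per property — sizes chosen to exercise every
code path at comfortable runtimes while keeping the Monte-Carlo
properties stable. The full-scale composition (2460 library + 445
external samples; 123× replication) is generated and checked
structurally. The MLP's reference 4×3 grid under 10-fold CV is exercised
at small sample sizes, where its training cost is negligible.

## Known limitations

* The generator's linearity means PLSR is nearly always the stronger
  engine on synthetic data; the MLP comparator earns its keep only on
  real, nonlinear data.
* Spike selection is uniform random; Kennard–Stone or stratified
  selection (natural extensions) are not implemented, but
  `draw_spike()` is the single pluggable point.
* Instrument-level preprocessing (white/dark referencing, splice
  correction) is out of scope; inputs are assumed to be calibrated
  reflectance fractions.
* `rpd()` errors on perfect predictions (RMSE = 0) rather than
  returning infinity; callers should report that case separately.
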