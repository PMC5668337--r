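---
title: "Species fingerprinting from REIMS burn spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species fingerprinting from REIMS burn spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reimsid)
```

## The measurement and the modelling problem

Rapid evaporative ionisation mass spectrometry (REIMS) identifies tissue
from the aerosol released when an electrosurgical knife cuts into it. Each
cut ("burn") of 3–5 s produces a transient block of high-intensity scans;
a sample is typically cut 8–12 times, and scans are acquired continuously
over m/z 200–1200 at 0.5 s per scan with a leucine-enkephalin lockmass
(m/z 554.2615) infused throughout. In negative mode the informative signal
over m/z 600–950 is dominated by intact phospholipids (PE and PS classes)
and fatty-acid species, and the *relative shape* of that lipid profile is
characteristic of a species. `reimsid` implements the complete modelling
chain for this measurement: a synthetic generator of REIMS-like scan
streams, preprocessing to fingerprint vectors, a PCA-LDA classifier with
an outlier rule, streaming per-burn recognition, OPLS-DA marker mining,
and ion-mass annotation arithmetic.

## Preprocessing model

A raw run is reduced to fingerprints in a fixed order:

1. **Burn gating.** Scans whose total ion count (TIC) exceeds `1e8`
   counts are burn scans; maximal consecutive intervals above the gate
   are burns. Everything below the gate is background and never reaches a
   classifier.
2. **Averaging.** The gated scans — all burns pooled for a per-sample
   fingerprint, or one burn at a time for streaming recognition — are
   averaged pointwise into one spectrum.
3. **Lockmass correction.** The intensity-weighted centroid *c* of the
   signal within ±0.5 Da of 554.2615 rescales the whole m/z axis by
   554.2615/*c*. With a single infused reference only a one-point
   multiplicative recalibration is identifiable; higher-order corrections
   are deliberately out of scope. If no lockmass signal is present the
   fingerprint is produced uncorrected, with a warning and a flag.
4. **Binning.** Bin centres run 600.0, 600.5, …, 950.0 inclusive — 701
   bins; a point belongs to `[centre − 0.25, centre + 0.25)`, so edge
   points are assigned deterministically.
5. **Intensity floor.** Bins whose *summed raw* intensity is below `2e6`
   counts are zeroed. The floor is applied per bin, before
   normalisation; applying it per point or per spectrum would interact
   differently with peak width, and the per-bin reading matches the
   floor's placement among the binning parameters.
6. **TIC normalisation.** The vector is divided by its sum; an all-zero
   vector is an error (the sample yields no usable signal).

The chain is deterministic: identical runs give bit-identical matrices.

## The PCA-LDA classifier and the 5σ rule

Fingerprint matrices have many more bins (701) than samples per class, so
linear discriminant analysis is preceded by mean-centred PCA
(`n_pca = 25` by default; 80 is a reasonable choice for large multi-class
studies, and the argument is exposed). LDA solves the generalized
eigenproblem of between- versus within-class scatter on the PCA scores,
with the pooled within-class scatter ridge-regularized by
`1e-6 · trace/dim` — rarely active after PCA, but it keeps the problem
well-posed. A *k*-class model admits at most *k* − 1 discriminant axes;
a request for more is an error rather than silently truncated. (For a
two-class catch-method model this means a single axis, whatever axis
count a score plot is drawn with.)

Each class *k* gets a centroid and per-axis standard deviations in
discriminant space. A query with discriminant coordinates *z* has
standardized distance

$$d_k = \sqrt{\tfrac{1}{A}\sum_{a=1}^{A}\left(\frac{z_a - c_{ka}}{s_{ka}}\right)^2},$$

a diagonal Mahalanobis-style distance in σ units, divided by the axis
count so thresholds are comparable across models with different `A`. The
query is assigned to the nearest class if \(\min_k d_k \le \sigma_{max}\)
(default 5) and is an **outlier** otherwise. The aggregated Euclidean
form was chosen over a per-axis maximum: it is the natural multivariate
generalization of "within 5 standard deviations" and is rotation-stable
within the discriminant space. Ties in the argmin resolve by class list
order; raising `sigma_max` can only turn outliers into assignments,
never the reverse.

Validation uses stratified leave-20%-out cross-validation: five seeded
folds, each class dealt cyclically across folds so every training split
contains every class, and every sample is held out exactly once.
Stratification is a deliberate choice where a plain random 20% split
could orphan a small class. Correct-classification rates are reported as
`100 · correct/total`, rounded to two decimals.

## Streaming recognition

`stream_recognize()` consumes scans in acquisition order. A burn opens at
the first scan above the gate and closes at the first scan below it (or
at end of stream; minimum length one scan). On closure the burn runs
through the same average–lockmass–bin–floor–normalise chain and is
classified immediately. Streaming and offline per-burn processing of the
same run agree *bit-exactly* — internally the model projects queries one
row at a time precisely so that batch and single-burn code paths cannot
diverge in floating point.

A sample-level verdict takes the label (including "outlier") with the
largest share of burns; a tied vote resolves to "outlier", since an
ambiguous sample should not be certified as any species. The
whole-sample average-spectrum classification is reported alongside
(`recognize_run()`), because a single averaged spectrum is the quantity a
confirmatory, non-real-time validation classifies, and it resolves
burn-split samples.

## OPLS-DA, validation statistics and marker selection

Fingerprints are mean-centred and Pareto-scaled (divided by the square
root of the standard deviation); zero-variance bins are dropped and
recorded. Class membership is a one-column-per-class dummy matrix. The
fit removes `n_orthogonal` components of X-variation uncorrelated with
class membership (orthogonal weights built from the deflated loading
minus its projection onto the span of the Y-predictive weights), then
fits `n_predictive` components by NIPALS PLS2 on the filtered matrix.
Predictive and orthogonal score blocks are orthogonal by construction,
and with `n_orthogonal = 0` the model *is* plain PLS2 — the test suite
pins both properties, the latter against an SVD-based PLS oracle.

- **R²Y(cum)** is the fraction of dummy-Y variance explained;
  **R²X(cum)** counts both blocks.
- **Q²(cum)** comes from stratified 7-fold cross-validation (a common
  software convention for this model family), refitting the model *and
  its scaling* per fold: `Q2 = 1 − PRESS/TSS`.
- **Permutation testing** refits the full pipeline under random
  relabellings and reports the exceedance proportion
  `#(Q2_perm ≥ Q2_obs)/n_perm` (default 100 permutations). The
  exceedance form was preferred over a regression-intercept summary
  because it is directly interpretable as an empirical p-value.

S-plots are defined for a single predictive direction, so per-species
marker mining uses one-vs-rest two-class models (`oplsda_ovr()`). For
each retained bin, `p` is the covariance and `p_corr` the Pearson
correlation with the first predictive score, oriented so positive means
enriched in the focal class; both are computed on the Pareto-scaled
matrix, the same representation the model saw. VIP is computed over
predictive components only (the orthogonal block describes what the
model *removed*), and satisfies `mean(VIP²) = 1` exactly. Markers are
bins jointly passing `VIP > 1`, `|p| > 0.03` and `|p_corr| > 0.5`,
ranked by `|p_corr|`.

## What the synthetic generator emulates — and what it does not

No public spectra accompany the workflow this package implements, so the
generator is a first-class, tested component that encodes the study
conditions:

- five white-fish classes (cod, coley, haddock, pollock, whiting)
  sharing ~30 common phospholipid-like base ions with class-specific
  weights, plus the species-enriched marker ions at m/z 788.5 (cod),
  817.5 (coley), 810.5 (haddock), 629.5/655.5/667.5 (pollock) and 790.5
  (whiting); a haddock catch-method contrast (trawl enriched at 764.5,
  line at 819.5); and two out-of-model species (seabass, seabream) whose
  base-ion weights are perturbed strongly enough that a trained
  five-class model rejects every sample as an outlier;
- 8–12 burns per sample of 6–10 scans (3–5 s at 0.5 s/scan), baseline
  blocks between burns, burn TIC ~5e8 ≫ the 1e8 gate ≫ baseline TIC
  ~2e6;
- a continuum m/z grid at 0.02 Da so that 0.5 Da binning genuinely
  aggregates sub-bin points; Gaussian peaks (σ = 0.05 Da) whose grid sum
  equals the ion intensity, so binning conserves intensity exactly;
- per-burn lognormal intensity jitter (CV 0.25), sparse additive
  chemical noise per scan, and a per-run mass-axis scale error
  (SD 15 ppm) that the lockmass correction must undo.

Within-class variance and absolute intensity scales are not published
for this assay beyond the two thresholds (2e6, 1e8); the generator's
defaults respect those thresholds and otherwise use values a
practitioner would call realistic for QTof lipid profiles. They were
fixed once, before any benchmark was run, and are exposed in
configuration objects rather than buried.

The generator does **not** model aerosol transport, isotope fine
structure, detector saturation, inter-batch drift or real biological
covariance between lipids. Passing tests therefore demonstrate that the
*algorithms* are correct and that recovery holds under the stated noise
model — not that any particular accuracy will be achieved on real fish,
whose class overlap is unknowable without the original spectra.
`simulate_fingerprints()` additionally shortcuts the continuum stage for
statistically heavy experiments (permutation tests, repeated CV),
emulating the *distribution* of preprocessed fingerprints; tests that
exercise gating, lockmass and streaming always use full raw streams.

## Worked example

A compact version of the full workflow (sizes kept small so the vignette
is cheap to rebuild; the test suite and `scripts/acceptance.R` use 40
training and 10 validation samples per class):

```{r workflow, eval = FALSE}
profiles <- default_species_profiles()
fish <- profiles[c("cod", "coley", "haddock", "pollock", "whiting")]
design <- dataset_design(fish, setNames(rep(20L, 5), names(fish)), seed = 1L)
train <- simulate_features(design)          # raw streams -> fingerprints

model <- reims_pcalda(train$x, train$labels, n_pca = 25, n_lda = 4)
pcalda_cv(train$x, train$labels, n_pca = 25, seed = 1)

run <- simulate_run(profiles$coley, seed = 99)   # one live sample
recognize_run(run, model)                        # per-burn calls + verdict

ovr <- oplsda_ovr(train$x, train$labels, "pollock",
                  n_predictive = 1, n_orthogonal = 3)
select_markers(splot(ovr), vip(ovr))             # recovers 629.5/655.5/667.5

match_bin(655.47)                                # DHA dimer annotation
```

## Numerical choices and degenerate inputs

- Per-class dispersions are floored at `1e-12` so a degenerate class
  (identical members) still yields finite, huge distances rather than
  division by zero.
- NIPALS iterations converge to a squared relative score change of
  `1e-26`, tight enough that the fit agrees with a direct-SVD PLS oracle
  to 1e-8.
- `classification_rate()` rejects `total = 0`; `tic_normalize()` rejects
  all-zero vectors; singleton classes are rejected wherever a dispersion
  or scatter would be undefined; burn detection returns an empty table
  (not an error) when nothing passes the gate.
- Seeds: every stochastic routine takes an explicit seed or draws from
  the caller's stream inside `with_seed()`, which restores the caller's
  RNG state; equal designs (including the seed) give byte-identical
  datasets.

## Known limitations

- The 5σ rule uses a *diagonal* per-class dispersion in discriminant
  space; strongly correlated within-class structure would call for full
  covariance, at the price of many more parameters per class.
- OPLS-DA here targets model validation and S-plot/VIP mining; it does
  not attempt numeric compatibility with any commercial implementation,
  and the R²/Q² of the original fish study are not reproducible without
  the original spectra.
- Annotation is mass arithmetic against a small editable candidate
  table: no spectral-library search, no acyl-chain isomer resolution —
  without chromatographic separation, isobaric lipids remain putative
  mixtures by design.
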