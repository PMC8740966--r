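---
title: "Chemometric discrimination of plant taxa from ATR-FTIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric discrimination of plant taxa from ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirtaxa)
```

## The problem

Closely related plant taxa — species, varieties and their hybrids, such as
the interbreeding members of the Japanese Knotweed complex — are often
morphologically indistinguishable, yet correct identification drives
management decisions (herbicide timing, biocontrol sourcing, legal
attribution of infestations). ATR-FTIR spectroscopy measures the infrared
absorbance of intact leaf material over 4000–400 cm⁻¹ and captures a
metabolic fingerprint of the sample surface. The biological information
concentrates in the *fingerprint region*, 1800–900 cm⁻¹, where lipids,
proteins, carbohydrates and nucleic acids absorb. `ftirtaxa` implements
the standard chemometric pipeline for turning such spectra into taxon
assignments, candidate biomarkers, and dendrograms of between-taxon
similarity — together with a synthetic spectrum generator that provides
ground truth for validating every stage.

## The preprocessing model

A measured absorbance spectrum is modelled as

$$ x(\nu) \;=\; g \,\big( s(\nu) + b(\nu) + \varepsilon(\nu) \big), $$

where $s$ is the biochemical signal (a sum of absorption bands), $b$ a
smooth baseline drift, $\varepsilon$ additive noise, and $g$ a
multiplicative gain induced by variable sample thickness and crystal
contact. The chain `preprocess()` applies, in fixed order:

1. **Fingerprint cut** (`cut_region()`, inclusive bounds, defaults
   1800–900 cm⁻¹). On a 4 cm⁻¹ grid this keeps 226 points.
2. **Savitzky–Golay second differentiation** (`sg_derivative()`):
   a local least-squares polynomial fit whose second derivative sharpens
   overlapping bands and annihilates constant and linear baseline
   components.
3. **Vector normalisation** (`vector_normalize()`): division of each
   spectrum by its Euclidean norm, removing the gain $g$.

The composition is exactly invariant to $g$: the suite checks
`preprocess(g·x) == preprocess(x)` to 1e-10. Mean-centring is *not* part
of `preprocess()`; it belongs to model fitting, where the centring means
must come from training data only (`mean_center()` shifts an external
test set by the *training* means — the suite tests this leakage guard).

### Numerical choices

* **SG window and order.** No community convention fixes these; the
  defaults are a 9-point window with a quadratic polynomial, a common
  chemometrics choice. Both are explicit `preprocess_config()` fields and
  are recorded in every run report; results that depend on them state the
  configuration.
* **Derivative scale.** The derivative is taken with respect to the point
  index, not physical cm⁻¹. On a uniform grid this differs only by a
  constant factor, which vector normalisation removes; tests assert the
  invariance rather than the scale.
* **Edge policy.** The first and last half-window points are computed by
  fitting the polynomial on the one-sided first/last `window` points and
  evaluating its derivative there. No reflection padding: nothing is
  fabricated at the region edges.
* **Baseline correction.** For band-*intensity* comparisons (not for
  classification) `rubberband_baseline()` subtracts the lower convex hull
  of each spectrum — the standard rubber-band algorithm, chosen because
  band height above the local background is what tracks concentration in
  raw absorbance spectra.

## Classification

Three models operate on preprocessed fingerprint vectors:

* **PCA** (`fit_pca()`): SVD-based, with loadings, scores, explained
  variance and the centring means retained so external data are always
  projected with training-set statistics.
* **PCA-LDA** (`fit_pca_lda()`): linear discriminant analysis on the
  first `n_pcs = 10` principal-component scores. The truncation
  regularises the within-class scatter, which is singular in the raw
  226-point space. Ten PCs is the conventional choice for fingerprint
  data.
* **RBF-SVM** (`tune_train_svm()`): one binary C-SVC per unordered class
  pair (an SMO solver implemented in C++), combined by one-vs-one
  majority voting. The input representation is the full preprocessed
  spectrum, not PC scores (configurable); a kernel machine does its own
  effective dimensionality control and published pipelines apply SVM
  directly to preprocessed spectra. Hyper-parameters are chosen by grid
  search over cost × gamma — powers of ten from 1e-3 to 1e3 by default —
  scored by **venetian-blinds cross-validation** with 10 data splits:
  the sample at position *i* joins fold *(i − 1) mod 10 + 1*, interleaving
  samples like blind slats. Score ties go to the smaller cost, then the
  smaller gamma. Because fold composition depends on sample order, the
  ordering convention (acquisition order of the training set) is part of
  the documented contract.

Validation uses a stratified random 70/30 train/test split
(`split_train_test()`): the training size is exactly
`floor(0.7 n)` — 1106 of 1580 — with per-class quotas reconciled to that
total by largest-remainder rounding. Quality parameters
(`evaluate_classifier()`) are one-vs-rest per class: accuracy
$(TP+TN)/n$, sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, each in
percent, macro-averaged without weighting. This reading of per-class
"accuracy" reproduces the characteristic pattern (macro sensitivity ≤
macro accuracy ≤ 100) of published quality-parameter tables.

## Biomarker extraction

Class differences are characterised through PCA loadings
(`pick_loading_peaks()`): candidate peaks are local extrema of the
loading's *absolute value* — second-derivative preprocessing inverts band
signs, so both lobes carry information — accepted greedily in decreasing
magnitude while suppressing any candidate within 20 cm⁻¹ of an accepted
peak. Which class carries more of a compound is decided by the sign of
the raw class-mean difference at the peak (`peak_directions()`), not the
loading sign. Peaks are annotated against a packaged, user-editable
lookup of characterised wavenumbers (glucomannan 1033.84, xyloglucan
945.119, pectin 1442.75 cm⁻¹, …) within a 4 cm⁻¹ tolerance — one grid
step. Two follow-up statistics quantify a candidate band:
`band_intensity_ratio()` (ratio of rubber-band-corrected class-mean peak
heights; tracks concentration) and `peak_shift()` (signed argmax
difference of vector-normalised class means; indicates structural
change, quantised to the 4 cm⁻¹ grid). Which loading vector feeds the
peak-pick is configurable (PC1 of the two-class PCA by default, any PC
or the PCA-LDA discriminant loadings via `pca_lda_loadings()`), and the
choice is recorded in run reports.

## Hierarchical clustering

`hca()` implements Ward's minimum-variance agglomeration on Euclidean
distances via the Lance–Williams recurrence. Two conventions matter and
are fixed here:

* **Height scale.** Merge heights are reported on the Euclidean-distance
  scale — two singletons merge at their inter-point distance (the
  `ward.D2` convention; toolboxes differ by constant factors).
* **Tie-breaking.** Equal-cost merges pick the lexicographically
  smallest label pair, making trees deterministic and independent of row
  order.

Two input modes reproduce the methodological contrast between
environment- and genetics-dominated linkage:

* **Fingerprint mode**: average spectra by type → SG second derivative →
  vector normalise → HCA. Whatever effect carries the most spectral
  energy dominates — on herbarium material that is often the growth
  environment.
* **Loadings mode**: SG + normalise per spectrum → select the absorbance
  values at the wavenumbers highlighted by PCA loadings → average by
  type → HCA. Restricting the input to discriminative wavenumbers
  suppresses broadband environmental variance and favours the taxon
  signal.

Trees export as ultrametric Newick (`to_newick()`): the branch to a
child merged at height $h_c$ under a parent at $h$ has length
$(h - h_c)/2$, so the cophenetic distance between two leaves equals
their merge height exactly. An `as.hclust()` bridge supports base-R
dendrogram plotting.

## The synthetic data generator

`simulate_spectrum_set()` stands in for the herbarium acquisition. Each
spectrum is a sum of Gaussian bands (class-specific plus shared) with
four effect layers matching the study design it emulates:

| Parameter | Default | Emulates |
|---|---|---|
| grid | 4000–400 cm⁻¹, 4 cm⁻¹ | instrument data spacing |
| replicates per surface | 10 | "ten spectra per leaf surface" |
| surfaces | upper/lower | adaxial/abaxial chemistry (gain 1.4 on ⅓ of bands) |
| locations | 3 | geographic origin (band-centre shifts, sd 3 cm⁻¹) |
| noise sd | 0.01 AU | detector noise (band amplitudes 0.3–1 AU → SNR ≫ 10) |
| baseline | quadratic, 0.05 AU | baseline drift |
| thickness gain | log-normal, σ = 0.15 | contact/thickness scaling |
| concentration jitter | log-normal, σ = 0.02 per sample×band | leaf-to-leaf biology |

Band shape is Gaussian (not Lorentzian/Voigt): no tested contract
depends on line shape. Class-level contrasts live in the library band
amplitudes, so planted effects are exact in expectation — the per-sample
concentration jitter averages out. At study scale (16 classes × 5
samples × 2 surfaces × 10 replicates = 1600 spectra; an optional
per-class count table reproduces unequal sampling, e.g. 79 samples =
1580 spectra) the generator matches the scale of the herbarium campaign
it emulates.

Three presets encode specific claims:

* `simulate_study_scale()` — separable 16-class world for
  parameter-recovery checks (the suite requires ≥ 95% SVM test accuracy
  over three seeds with disjoint class bands).
* `make_two_variety_scenario()` — two varieties identical except a
  glucomannan-like band at 1034 cm⁻¹ with a planted amplitude ratio
  (default two-fold); the pipeline must recover the ratio within 5% and
  place the discriminant loading peak within one grid step of 1034 cm⁻¹.
  Note 1033.84 lies exactly between the 1032 and 1036 grid points, so
  "the nearest grid point" is a 2 cm⁻¹ tie.
* `make_env_vs_taxon_scenario()` — all classes share strong common
  bands; a "greenhouse" environment multiplies half of them by 1.8,
  while weak taxon bands (amplitude 0.3 vs 1.0) carry the genetic
  signal. The environment effect was deliberately made *multiplicative
  on shared bands* rather than an additive disjoint band set: an additive
  design interacts with vector normalisation (classes with extra strong
  bands have their taxon features shrunk, which can fold environment
  structure back into the taxon-selected subspace), whereas multiplicative
  modulation of shared chemistry is both closer to how growth conditions
  act and keeps the two effects separable. With these amplitudes,
  fingerprint-mode HCA groups by environment and loadings-mode HCA
  (restricted to taxon band wavenumbers) groups by taxon — the
  methodological contrast at the level where it is literally testable.

The tests' "weak-signal" three-class world (class-specific amplitudes
scaled to ~0.03–0.1 AU under noise sd 0.05) instantiates the regime in
which a full-space RBF-SVM outperforms LDA in a 10-PC truncation: the
discriminative variance is real but small, so it falls partly outside
the leading principal components. Those amplitudes were chosen once,
when the scenario was designed, to place the problem between the trivial
and impossible extremes.

What a green test does *not* establish: the generator contains no water
vapour or CO₂ lines, no ATR penetration-depth wavelength dependence, no
Mie scattering, no correlated (pink) noise, and its class structure is
far cleaner than real herbarium biochemistry. Green synthetic tests
validate the *machinery* — preprocessing algebra, solver correctness,
metric arithmetic, tree construction — not field performance.

## Degenerate inputs and edge policies

* Zero-norm spectra are rejected by name before normalisation.
* Constant loadings yield an empty peak table; flat windows make
  `peak_shift()` error rather than return an arbitrary argmax.
* A class absent from the test set has undefined sensitivity: it is
  excluded from macro averages with a warning, not silently imputed.
* Stratified splitting refuses singleton classes and suggests
  non-stratified mode.
* Rank-deficient PCA requests truncate with a warning.
* SVM voting ties go to the alphabetically earliest class; CV score ties
  to the smaller cost, then smaller gamma.

## Known limitations

* The RBF-SVM solver is a plain two-variable SMO; it is exact (validated
  against an independent QP solve) but not optimised for training sets
  far beyond this study's scale (~10³ spectra).
* Binary OPUS files are not parsed; only exported two-column text.
* The published headline numbers (99.04% test accuracy, etc.) can only
  be reproduced against the study's raw-data workbook, which is not
  redistributable with this package; `reproduce_study()` runs the
  documented pipeline when given that workbook locally, and the
  corresponding acceptance test reports its absence rather than skipping.
* No probability calibration, ROC analysis, or bootstrap support values
  on dendrograms.
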