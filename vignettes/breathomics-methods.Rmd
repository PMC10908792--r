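---
title: "Non-volatile breathomics: models, parameters and design choices"
author: "breathomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-volatile breathomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathomics)
```

## The analysis problem

Non-volatile organic compounds (nVOCs) in exhaled breath can be collected on
a filter device and profiled by direct-infusion FT-ICR mass spectrometry:
no chromatography, two electrospray polarities, and two acquisition methods
covering 65–300 m/z ("ultra-small") and 95–1500 m/z ("small"), overlapping
between 95 and 300 m/z. Every acquisition yields a centroided peak list.
The analytical questions are (i) which molecular formulas are present
(annotation), (ii) how to obtain one comparable intensity per metabolite per
subject (normalization, mode/method merging, replicate consensus), and
(iii) which metabolites separate phenotype groups (a three-method
significance consensus), plus a chemical-class summary of the detected
metabolome.

This package implements that full chain, together with a synthetic cohort
generator whose ground truth (planted effects, dilution factors, batch
factors) makes every stage testable.

## Annotation model

A molecular formula's neutral monoisotopic mass is the sum of
principal-isotope masses (bundled IUPAC table). Ions are formed by
(de)protonation as the base ESI ionisation plus the adducts Na⁺ and K⁺ in
positive mode and Cl⁻ in negative mode; all ions are singly charged, which
is the right regime for direct-infusion small-molecule work below 1500 m/z.
The ±H mass deltas use the proton mass; Na/K/Cl deltas account for the
electron mass, which matters below roughly 550 m/z at sub-ppm accuracy.

A feature is annotated when `|ppm error| < 1` against a reference record's
adduct m/z. When an observed isotope pattern is available, the assignment
must additionally pass an isotopic fine-structure check: the theoretical
pattern is simulated by multinomial expansion over natural isotope
abundances, merged at the instrument's resolving power (default 488,000,
the value at m/z 400), and compared by a score defined as 1000 × the
weighted RMS relative deviation of matched peak abundances (weights
proportional to the square root of the theoretical abundance; theoretical
peaks with no observed match count as 100% deviation). A perfect fit scores
0; assignments at or above 300 are rejected. The score is an operational
analogue of vendor fine-structure metrics, whose formulas are not public:
the threshold is meaningful on our scale (a uniform 10% abundance error
scores 100; a pattern missing all isotopologues scores well above 300), but
scores are not numerically comparable to vendor values. Square-root
weighting was chosen because weighting by raw abundance lets the base peak
dominate: a spectrum missing every isotopologue would then score ≈240 and
slip under the rejection threshold, which contradicts the intended use of
the check.

Recalibration against a local calibrant list fits a linear m/z correction
(offset + slope) by least squares over calibrants matched within a 5 ppm
coarse window, falling back to a constant relative offset when only one
calibrant matches. Ties between reference records with identical formula
are all kept as hits; downstream stages take the first-listed record, which
mirrors how annotation front-ends resolve such ties.

## Preprocessing chain

The stage order is fixed and logged: recalibrate → build per-mode/method
feature tables (m/z binning at the ppm tolerance, intensity-weighted
centroids) → annotate → PQN → batch correction → stack the two acquisition
methods → merge ionisation modes → deduplicate → replicate consensus →
prevalence filters → (statistics branch) impute → median normalize →
log/Pareto.

**PQN.** The reference spectrum is the feature-wise median over the pooled
QC injections (falling back to the overall median when no QCs exist); each
sample is divided by the median of its value/reference quotients over
shared non-zero features. This removes the per-sample dilution caused by
variable exhaled micro-droplet yield. On synthetic cohorts the estimated
factors track the stored dilution truth with r > 0.95; with several
preparation batches the estimated factor is the product of dilution and
batch shift, which is exactly what a global multiplicative correction
should absorb.

**Batch correction.** Per batch, the ratio of the batch's QC median
intensity to the global QC median is divided out; batches without a QC
injection fall back to the batch sample median with a warning. Because PQN
already removes per-sample scale, this step is a safety net for residual
batch-level shifts.

**Mode merging.** For a formula detected in both polarities, the mode with
more detections across all samples wins; ties break by total intensity
(e.g. 91 positive vs 81 negative detections keeps positive). Formulas seen
in one mode pass through. Deduplication then keeps, per formula, the row
with the highest total intensity — this collapses the 95–300 m/z overlap
between the two acquisition methods and residual multi-adduct rows.

**Replicate consensus.** A metabolite counts for a subject only when
detected in at least 2 of the 3 breath replicates; the subject-level value
is the mean of the *detected* replicate intensities (zeros are never
averaged in), otherwise the subject is "not detected" (0).

**Prevalence filters.** Features must be detected in at least
`ceiling(fraction × n_subjects)` subjects: 5% at table assembly and 15%
before statistics, as two separately configured steps. Subject-level
counting (after replicate consensus) was chosen because the filter follows
replicate reduction in the workflow; acquisition-level counting remains
available by applying the filter to a pre-consensus table.

**Statistics preparation.** Missing values are imputed at 1/5 of the
detection limit (10⁶ counts → 2 × 10⁵), samples are median-normalized, and
features are log₁₀-transformed and Pareto-scaled (centred, divided by the
square root of the standard deviation; constant features are left centred
at 0 rather than dividing by zero). The logarithm base is configurable;
base 10 is the default.

## The three-method consensus

* **Volcano:** per feature, a Welch two-sample t-test on the
  log/Pareto-scaled values with Benjamini–Hochberg adjustment, plus a raw
  intensity fold change. The default significance pair is adjusted
  p < 0.1 and |log₂FC| ≥ 1; both thresholds are configuration values
  (p < 0.001 and an FC-only criterion are both in documented use). Fold
  change orientation (second-listed group over first) is always recorded,
  because the direction convention is otherwise ambiguous.
* **PLS-DA:** NIPALS partial least squares against the centred class
  indicator, default 5 components. R2Y is the cumulative explained
  Y-variance; Q2Y comes from stratified 10-fold cross-validation (one
  repetition, seeded). VIP scores follow
  `VIP_j = sqrt(p · Σ_a SSY_a w²_aj / Σ_a SSY_a)`, so mean(VIP²) = 1;
  features with VIP > 1.5 form the PLS-DA significant set.
* **Random forest:** 500 trees by default (capped at 1000), with the
  number of predictors per split equal to the rounded square root of the
  feature count (e.g. 2656 features → 52). The out-of-bag error is the
  internal validation estimate; the per-feature unscaled mean decrease in
  accuracy (OOB permutation importance) with threshold 0.00016 forms the
  third significant set. Seeds are mandatory: the OOB error is only
  reproducible in regime, not to the digit, across seeds.

The three sets are partitioned into the seven Venn regions; the ranked
triple intersection is the consensus list of the most robust markers. For
multi-group phenotypes (diet, alcohol, activity), a one-way ANOVA with
Tukey HSD pairwise comparisons at adjusted p < 0.1 replaces the volcano.

## Chemical-class coverage

Each detected feature contributes the main class of its top-ranked
annotation — one class per feature, because counting every candidate class
of an ambiguous formula would overstate coverage. Per class, coverage is
100 × detected / potential, where potential is the class size in the
reference list; classes holding less than 2% of total detected hits are
dropped from the summary (boundary inclusive). Coverage numbers are
relative to whatever reference list is supplied and are not comparable
across lists.

## The synthetic cohort generator

The generator emulates the statistical structure of the study, not the
physics of the instrument. Defaults are the study conditions: 101 subjects
(50 female, 16 of them using oral contraceptives; 68/28/5
flexitarian/vegetarian/vegan; 92 coffee drinkers; 10 smokers; 53/28/20
regular/occasional/no alcohol; 56/34/11 activity; 45 supplements; 15
allergies), 3 breath replicates per subject, both polarities and both
acquisition windows, pooled-QC injections at the start, after every 12
analytical samples, and at the end of each sequence.

Per metabolite and subject, the expected intensity is
`10^base × ∏ planted fold effects × dilution × batch factor × mode
efficiency`, with multiplicative log-normal noise (log₁₀ sd 0.1 per
acquisition, 0.05 for QCs). Multiplicative noise was chosen because the
downstream chain log-transforms intensities. A peak appears only if it
exceeds the detection limit (10⁶ counts) and a per-metabolite detection
probability draw succeeds; observed m/z carries a per-acquisition
systematic offset (sd 0.5 ppm — what recalibration removes) plus per-peak
jitter (sd 0.3 ppm, so a 1 ppm annotation gate keeps ≈ 99.9% of true
matches). Principal isotopologues (relative abundance ≥ 1%) are emitted, so
feature tables contain realistic M+1 satellite features. Per-replicate
dilution (log₁₀ sd 0.15) models variable micro-droplet yield and is stored
in the truth manifest for PQN recovery tests. Batch factors (2 batches,
log₁₀ sd 0.15) are preparation-side multiplicative constants shared by all
features — the kind of shift global normalization can remove. The default
panel size is 200 metabolites with 30 gender markers (fold 2–4, echoing
the largest reported gender fold change of 2.89), 10 oral-contraceptive
markers (fold 1.5–2.5) and 6 alcohol-abstinence markers (fold 2–3);
inter-replicate variance is not reported for the real cohort, so these
noise defaults were chosen once for testability and are not revisited.

What the generator does **not** emulate: raw transients or peak shapes,
within-run instrument drift, correlated metabolite panels (effects are
independent across metabolites), chemical background, or contaminant
series. Passing tests therefore demonstrate that the pipeline's logic
recovers known structure under realistic noise — not that it would resolve
every pathology of real spectra.

## Numerical choices and degenerate inputs

* Binning: consecutive sorted peaks closer than the ppm tolerance join one
  feature; a sample contributing several peaks to one bin keeps the
  maximum.
* Pareto scaling of a constant feature yields a centred zero row.
* PQN errors when a sample shares no non-zero feature with the reference
  and warns below 10 shared features; batch correction warns and falls
  back to sample medians for QC-free batches.
* Isotope-pattern convolution prunes terms three orders of magnitude below
  the abundance floor (default 10⁻⁴ relative) and merges peaks within the
  resolution-implied FWHM by abundance-weighted centroid.
* The two-group Tukey comparison reduces exactly to the pooled-variance
  t-test, which the suite verifies.
* `mtry` rounding is nearest-integer (√2656 = 51.54 → 52).

## Known limitations

* Observed fold changes are mildly attenuated (5–20%) when a substantial
  fraction of features shift in one group: PQN and median normalization
  both absorb part of a one-sided signal into the per-sample scale. This
  is a property of the normalization design itself, and the reason the
  marker-recovery checks gate on the FDR-adjusted p-value rather than the
  fold-change flag; markers planted exactly at fold 2 can land just under
  the doubled-effect line after normalization.
* 1/5-LOD imputation creates heavy outliers on the log scale for features
  missing in only a few subjects, inflating within-group variance and
  occasionally masking a genuine effect — visible in the synthetic cohort
  as markers with strong planted folds and unremarkable p-values.
* The fine-structure score gates annotations only when observed patterns
  are supplied; table-level centroid annotation uses the mass gate alone.
* Unannotated features are keyed by m/z within mode and method, so the
  same unknown detected by both methods in the overlap window survives
  deduplication twice.

## Problem sizes used in the checks

The simulation-based checks run on cohorts of 10–101 subjects with panels
of 60–200 metabolites (roughly 1300 acquisitions and 10⁶ peaks at the full
design), sizes at which every property of interest — dilution recovery,
merge correctness, marker recall, classifier regime — is already stable;
the acceptance script reports each quantity together with the size it was
computed at.
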