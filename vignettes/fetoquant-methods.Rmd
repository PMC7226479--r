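---
title: "Methods: absolute quantification and marker panels for diabetic fetopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute quantification and marker panels for diabetic fetopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetoquant)
```

## The problem

Diabetic fetopathy (DF) is a fetal complication of maternal hyperglycemia in
gestational (GDM) or type 2 (T2DM) diabetes. A quantitative plasma-proteomics
workflow for assessing candidate DF markers has four computational stages,
all implemented here:

1. **Calibration** against a spiked dilution standard: a UPS-2-style mixture
   of 48 defined proteins spanning 0.5–50,000 fmol (10.6 µg total) is spiked
   1:10 into a non-human background, run in six technical replicates, and
   used to fit a standard curve relating normalized MS1 intensity to
   absolute concentration.
2. **Quantification**: each plasma protein's *normalized total intensity* —
   the summed MS1 intensity of its proteotypic (single-protein) peptides as
   a fraction of the sample's total proteotypic intensity — is interpolated
   on the curve and converted to a mass concentration via the protein's
   molecular mass (`conc_ng_ml = conc_fmol_ul × mw_da / 1000`). NSAF
   (spectral counts over length, normalized to sum to one) is computed
   separately and used only for abundance ranking.
3. **Group statistics**: Kruskal–Wallis across the five cohort groups,
   pairwise Mann–Whitney contrasts, Fisher's exact tests for categorical
   tables, Spearman/Kendall rank-correlation bias checks, fold changes, and
   a generic Fisher overrepresentation test with Bonferroni correction.
4. **ROC panel**: per-marker and integrative multi-marker ROC analysis with
   a stratified percentile bootstrap CI, a Youden operating point and
   leave-one-marker-out elimination.

Because the underlying raw mass-spectrometry data are not publicly
available, the package ships a first-class synthetic-data generator that
emulates the study's cohort and intensity structure, so the entire pipeline
is exercised and tested end to end without downloads.

## The calibration model

The intensity response is modelled as a power law, `I = g·C^s`, which is
linear in log–log space. The fit is ordinary least squares of
log10(normalized intensity) on log10(concentration). Regression in log
space is the only reading under which a "linear" standard curve over five
orders of magnitude, and the reported jump in r² after excluding the
low-amount range, are coherent; no weighted or robust variants are offered.

Calibration points are gated before fitting:

* **Replicate CV gate** — the replicate "standard deviation of intensities"
  thresholds are interpreted as *relative* SD (CV = SD/mean): an absolute SD
  across a five-decade intensity range would be meaningless. Defaults:
  CV ≤ 20% everywhere, and ≤ 10% at the 500 fmol/µL top point
  (`cv_max`, `cv_max_top`).
* **Detection gate** — a point needs at least two detected replicates,
  otherwise it is marked `undetected` (a CV cannot be formed from one
  observation).
* **Prohibited margin** — points whose on-column amount
  (concentration × injected volume) falls in the half-open band
  `[0.5, 42)` fmol are rejected. The boundary is half-open so that a
  measured range beginning exactly at 42 fmol is retained. The same band
  flags predictions (`unreliable_margin`) at quantification time.

"Rational point selection" is operationalized as exactly these gates — no
manual exclusions. The injected volume used to map fmol/µL to on-column
fmol is not stated in the study design beyond the 2 µL injection of the
prepared sample, so `injection_ul = 2` is the default and is configurable.
Each standard protein contributes one calibration point (its replicate
mean); pooling proteins within an amount tier would discard the per-protein
response variation the CV gates exist to detect.

Prediction inverts the fitted line, `C = 10^((log10 I − a)/b)`, and flags
values outside the span of selected calibration concentrations as
`extrapolated`. With the default layout the selected points span
0.005–500 fmol/µL, and the `[0.5, 42)` fmol margin removes the two interior
tiers whose on-column amounts (1 and 10 fmol) fall inside it.

## What the generator emulates

`df_group_specs()` encodes the study conditions: groups G01 (GDM, healthy
newborns, n = 43), G02 (GDM + DF, n = 37), G03 (T2DM, n = 34), G04
(T2DM + DF, n = 29) and G05 (uncomplicated pregnancy, n = 36) — 179
subjects — with each marker's published group mean ± SD (CRP in µg/mL,
CEACAM1/CNDP1 in ng/mL, immunoglobulin subclasses in mg/mL; all stored
internally in ng/mL). Subject concentrations are drawn from zero-truncated
normals: the study reports means and SDs without a distributional claim,
and truncation only prevents physically impossible negative concentrations
(for every configured marker the mean sits ≥ 1.5 SD above zero, so the
truncation bias is negligible). The published SDs are treated as the total
between-subject spread; no variance decomposition into technical and
biological components is attempted because none is reported
(`biological_cv` defaults to 0 and adds extra per-subject noise only when
explicitly requested).

Technical noise is multiplicative lognormal with unit mean and configurable
CV (`replicate_cv`, default 0.10 — the value used for the recovery
benchmarks), so noise does not bias the intensity scale. Detection dropout
is logistic in log10 on-column amount with a 50% midpoint at 0.005 fmol and
steepness 4: detection is essentially complete above ~0.05 fmol, while the
lowest standard tier (0.01 fmol on-column) loses occasional replicates,
which exercises the `undetected` pathway without destabilizing the curve.

`forward_model_intensities()` is defined as the inverse of quantification:
each subject–marker target normalized intensity is read off the generating
curve at the true concentration, split across that marker's synthetic
proteotypic peptides, and a bulk background protein absorbs the remaining
intensity so that per-sample TIC normalization returns the targets. With
all noise at zero, quantify ∘ forward-model is the identity inside the
calibration validity range — a property the test suite asserts to 1e-9.

One structural consequence is worth stating plainly: TIC-normalized
intensities are fractions and cannot exceed 1, but the standards curve
extrapolated to mg/mL-scale immunoglobulin concentrations (≥ 2 decades
above the 500 fmol/µL top point) predicts normalized intensities far above
1. No intensity table can represent such samples, so the forward model
raises an error at that compositional ceiling, and the default pipeline
quantifies the three sub-mg/mL markers (CRP, CEACAM1, CNDP1) through the
MS channel while carrying IgG4 and IgA2 into the statistics and panel as a
directly measured channel. This mirrors the physical reality that intensity
fractions are only transferable between samples of commensurate total
signal; published mg/mL immunoglobulin values cannot arise from in-range
interpolation of a fmol/µL-scale curve.

What the generator does **not** emulate: raw spectra, retention time,
charge states, peptide-spectrum-match error or FDR filtering (the pipeline
starts from identified peptide intensities), protein inference, or
correlated marker–marker biology beyond the group structure. Passing tests
therefore demonstrate that the *procedures* are correct and recover their
generating parameters under the assumed noise model — not that the markers
would perform identically on new clinical data.

## Statistical choices

* Continuous marker contrasts use Mann–Whitney/Kruskal–Wallis. The study
  describes Fisher's exact tests on measured concentrations without saying
  how continuous values were dichotomized; here Fisher's exact is reserved
  for detection/categorical tables, with `dichotomize_at_median()` provided
  for fidelity experiments.
* The per-marker group tables report raw p-values (no multiplicity
  correction across markers), matching the reporting convention;
  Bonferroni is applied exactly where stated — the overrepresentation test.
* Kruskal–Wallis uses the universal chi-square approximation; an exact
  permutation p (full enumeration over group assignments) is available for
  N ≤ 10.
* Mann–Whitney is exact when the smaller sample has ≤ 8 observations and
  there are no ties, otherwise normal approximation with tie and
  continuity correction.
* The frequency filter retains a protein for a group iff it is detected in
  at least the threshold fraction of that group's samples (`≥`, so 1/2
  passes a 0.5 threshold); the default threshold of 1.0 reflects the
  requirement of frequency 1.0 motivated by the small group sizes.

## The panel combiner

The integrative score is a ridge-stabilized logistic regression on
z-scored markers (penalty 1e-6 on slopes only). The study does not name its
combination rule; logistic scoring is the standard integrative-ROC
construction, is monotone-equivalent to LDA under binormality, and the tiny
ridge yields a finite converged solution even under complete separation —
which the synthetic cohort, with its widely separated group means,
routinely produces. Marker direction is learned from the data; no signs are
hard-coded. The positive class defaults to the DF groups (G02 ∪ G04)
against all others; whether the uncomplicated-pregnancy group belongs in
the negative set is genuinely ambiguous in the study's phrasing, so it is a
configuration switch (`negative_groups`), included by default.

Confidence intervals use a stratified percentile bootstrap (resampling
within class, 2,000 resamples by default, seeded). AUC is computed by pair
counting with ties at ½, which equals trapezoidal integration of the
empirical ROC exactly — asserted to 1e-12 in the tests. The Youden
operating point scans midpoints between consecutive distinct scores and
resolves ties toward the lower threshold. "Specificity/selectivity" at the
operating point are reported as specificity and sensitivity respectively.

The simulated five-marker panel reaches an apparent AUC near 1.0 —
substantially above the 0.893 reported on the real cohort. This is
expected, not a success metric: the binormal separation implied by the
published group means (e.g. CEACAM1 at 113 ± 16 vs 516 ± 72 ng/mL) is far
wider than real per-patient data can have been, so the test suite treats
the published AUC only as a sanity floor that the simulation must exceed.

## Numerical conventions and degenerate inputs

* Identical seeds give identical outputs; every stage derives its own
  sub-seed from the master seed, so adding draws to one stage never
  perturbs another. Callers' RNG state is left untouched.
* Lognormal noise uses `meanlog = −σ²/2` so noise factors have unit mean;
  CV = 0 returns exactly 1.
* A zero normalized intensity yields an `undetected` flag and no
  concentration — missing means absent, never imputed; undetected samples
  move a marker's detection frequency instead of its group mean.
* Degenerate guards: all-equal observations give H = 0, p = 1; a zero
  denominator fold change, a zero-variance calibration abscissa, an all-zero
  spectral-count vector, and a zero-slope curve inversion are errors, not
  NaNs. JSON output serializes NaN as null with a warning.
* Duplicate peptide rows (fragmented exports) are summed with a warning;
  readers reject invalid rows with the offending row number.

## Problem sizes in the test suite

The suite simulates at the study's group sizes wherever a published value
is recovered (179 subjects; 48 standards × 6 replicates). Property suites
use sizes chosen for statistical resolution at interactive runtimes: 2,000
null simulations for the Kruskal–Wallis size check (binomial SE ≈ 0.5% at
α = 0.05), 500 replications × 500 resamples for bootstrap coverage, and
full enumeration oracles on instances with N ≤ 12 where enumeration is
exact rather than approximate.

## Known limitations

* TIC normalization assumes commensurate total signal between standards
  and samples; the forward model enforces this by construction, real data
  would not.
* One calibration point per standard protein assumes equal response
  factors across proteins; per-protein response calibration is out of
  scope.
* Apparent (resubstitution) AUC only — no cross-validation machinery, by
  design, matching the reported analysis.
* Protein masses ignore PTMs and glycosylation; masses come from the
  registry (or can be computed from FASTA-derived sequences upstream).
* Annotation-based enrichment takes flat term → protein maps; no GO graph
  traversal or semantic reduction.
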