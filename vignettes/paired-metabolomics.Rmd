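---
title: "Methods: paired untargeted LC-MS biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired untargeted LC-MS biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairomics)
```

This vignette documents the statistical model behind `pairomics`, the
choices made where the methodology is genuinely open, and what the
synthetic-data generator does and does not emulate.

## The setting

An untargeted LC-MS serum study acquires, per ionization mode, a table of
molecular features — (m/z, retention time) pairs with one intensity per
injection. The design here is paired: each subject is sampled at an early
and a late timepoint, and the analysis asks which features discriminate
the two within subject. The injection sequence carries its own structure:
several leading conditioning QCs (excluded from all statistics), a pooled
QC re-injected every few samples (the handle on analytical variability),
and a spiked internal standard in every injection (the handle on
injection-to-injection response).

## Quality control

**ISTD evaluation and normalization.** `istd_report()` fits ordinary least
squares of ISTD area against injection order; the slope, its standard
error, the slope t-test p-value and the within-sequence CV% make up the
control chart. `normalize_istd()` multiplies each sample by
`median(ISTD area) / ISTD area`. The reference is the *median* rather than
the mean or a designated injection: with a handful of injections one bad
ISTD spike should not move the reference. The operation is idempotent and
exactly removes a multiplicative per-injection response factor; it cannot
correct feature-specific (non-proportional) drift.

**QC CV filter.** `qc_cv_filter()` computes, per feature, the CV% of the
pooled-QC injections (sample standard deviation, n − 1 denominator) and
removes features with CV ≥ the threshold (default 30%). The comparison is
deliberately `>=`, so a feature at exactly 30% is removed. Conditioning
QCs never enter the computation. Missing QC values are a separate failure
mode: a feature observed in half the QC injections or fewer is removed as
unquantifiable rather than given a CV from too few points; otherwise the
CV uses observed values only. The filter is invariant to sample order and
to any global rescaling of the table, and retained/removed always
partition the input.

## Paired volcano selection

`volcano_select()` combines an effect-size rule with a paired test:

* FC = mean(late) / mean(early) over biological samples (ratio of means,
  linear scale — the convention that matches how fold-change thresholds
  are quoted; the mean of per-subject ratios is a different estimator and
  is not used);
* a two-sided paired t-test on log10 intensities, pairing each subject's
  two samples. Testing on the log scale makes the test agree in scale with
  the multiplicative FC threshold and makes p-values invariant to
  rescaling any single subject's pair.

A feature is selected when p < 0.05 **and** FC ≥ 2 or FC ≤ 0.5 (both
volcano arms). No multiple-testing correction is applied: the selection
feeds a multivariate model whose own validation (permutation, CV-ANOVA)
is the error control; raw p < 0.05 here is a deliberate,
faithful-to-practice screening rule, not an inference.

Degenerate inputs: missing intensities are imputed per feature as half the
minimum observed positive intensity (the usual below-detection-limit
proxy) before testing; features still containing non-positive values are
excluded with a warning. Zero-variance paired differences get p = 0 when
the common difference is nonzero and p = 1 otherwise, flagged
`degenerate`.

## OPLS-DA

`fit_oplsda()` autoscales variables (mean 0, unit variance — the
convention of the chemometrics software this workflow mirrors; the data
are already log10 scale when they come from the pipeline) and codes the
two classes −1/+1. Orthogonal components are extracted by the Trygg–Wold
deflation: on the current matrix, w ∝ Xᵀy normalized, t = Xw, p = Xᵀt/tᵀt,
w⊥ ∝ p − (wᵀp)w, and X is deflated by the orthogonal component t⊥p⊥ᵀ;
after `n_ortho` rounds a single predictive component is fit. By
construction every orthogonal score has zero correlation with y, and with
`n_ortho = 0` the model *is* one-component PLS1-DA (the test suite checks
both to machine precision, the latter also against an independent PLS
implementation).

Component count: a binary response supports one predictive component.
`n_ortho = "auto"` starts at zero and accepts one more orthogonal
component while cross-validated Q2Y improves by more than 0.01, capped at
5 — a parsimony rule; fitting orthogonal components that do not improve
prediction only flatters R2Y.

**Validation.** `oplsda_cv()` uses stratified k-fold cross-validation
(default 7 folds, seeded assignment); scaling, orthogonal filtering and
the predictive component are all re-estimated inside each training fold,
so held-out samples leak nothing (verified against an independently coded
oracle in the tests). Q2Y = 1 − PRESS/SS. `cv_anova()` converts the same
PRESS into an F-test with d1 = A (total components, predictive +
orthogonal) and d2 = N − A − 1; the published CV-ANOVA formulation leaves
the degrees of freedom partly heuristic, and this is the committed
reading, with SS − PRESS floored at zero. `oplsda_permutation()` refits
model and cross-validation under random label permutations with identical
settings; p(Q2) uses the add-one estimator (1 + #{Q2perm ≥ Q2obs})/(n+1),
which cannot be zero and counts an identity permutation honestly; the
familiar permutation plot is summarised by the least-squares intercepts of
R2/Q2 against |cor(yperm, y)| including the observed point at 1.

**VIP and selection.** With one predictive component,
VIPⱼ = √(p·wⱼ²/Σw²), so Σ VIP² equals the variable count exactly.
Confidence intervals come from a jackknife over the leave-one-fold-out
training subsets (mean ± t₀.₉₇₅,K₋₁ × jackknife SE). `select_vip()` keeps
variables ranked in the top 30 (ties broken by variable id for
determinism) whose CI lower bound is strictly positive — a large VIP with
an interval reaching zero is an unstable importance estimate and is
discarded. Reading the stability criterion as the jackknife CI of the VIP
score is a committed interpretation; VIP is nonnegative, so "interval not
including 0" can only sensibly refer to the uncertainty interval.

**Joint modelling of both modes.** The pipeline concatenates the
(separately ISTD-normalized, QC-filtered) positive- and negative-mode
features into one matrix before the volcano and OPLS-DA, so a single VIP
ranking mixes both modes — matching how mixed-mode selected-variable
tables are reported. Per-mode models would be the alternative reading;
they are available by passing one table and `NULL` for the other.

## Annotation

`annotate_features()` performs accurate-mass annotation only (MSI level
3): for each feature, library compound and polarity-compatible adduct it
computes the theoretical ion m/z from the *monoisotopic* neutral mass
(most-abundant-isotope atomic masses; electron mass included in the charge
deltas, e.g. +1.00727646 Da for [M+H]+) and records a hit when |ppm| ≤ 20.
Published "theoretical m/z" columns often print average molecular weights;
a TOF observes the monoisotopic line, so matching must be monoisotopic —
the bundled library therefore carries formulas, and masses are computed,
not copied. The default registry ([M+H]+, [M+Na]+, [M+H−H2O]+, [M−H]−,
[M+HCOO]−, [M−H−H2O]−) is the minimal single-charge set that reconciles
the bundled worked examples; 20 ppm accommodates the largest deviation
seen there (~11 ppm) on a Q-TOF while keeping the identification counts
exact. All candidate hits are retained with the best |ppm| flagged;
`distinct_compounds()` counts identifications from best hits by default,
since one feature is one ion species. One bundled variable (705.4863, a
phosphatidic acid candidate) is reconciled by no standard single-charge
adduct of its printed formula and stays unannotated by design.

## The synthetic generator

`simulate_study()` emulates the study design, with defaults pinned to the
emulated study where it states them: 6 paired subjects, 4045 positive- and
9712 negative-mode features, at least 5 conditioning QCs, a pooled QC
every 6 biological injections. Where the study is silent the defaults are
modelling choices held fixed: baseline log10 abundance uniform on [4, 7]
(typical peak-area magnitudes), a per-subject normal random effect of SD
0.15 log10 units shared across the subject's two timepoints (serum
metabolome between-subject spread), planted effects on the log scale with
|log2 FC| uniform on [1, 3] and random sign for 1% of features, and
per-feature analytical CVs drawn log-normal with median 10% and
sdlog = log(3)/qnorm(0.85) ≈ 1.06 — the unique log-normal meeting both
stated calibration points (median 10%, 15% of features at CV ≥ 30%, so
the QC filter has work to do). Analytical noise is multiplicative
log-normal at the feature's CV; pooled-QC injections are the per-feature
mean of the biological samples plus fresh noise (physical pooling);
conditioning QCs are copies of the first pooled draw; the ISTD channel has
true area 1e5 plus a configurable linear drift per injection.

What it does *not* emulate: chromatographic peak shape, isotope envelopes,
correlated features (adducts/fragments of one metabolite), missingness
mechanisms, retention-time drift, or batch effects beyond linear ISTD
drift. Passing tests on this generator therefore demonstrate the
correctness and statistical behaviour of the workflow under its own
assumptions — not performance on real serum data, where correlated
features and structured missingness make selection harder.

## Problem sizes and numerical choices

The test suite exercises a small preset (200–300 features per mode, 6
subjects) for speed, a large-QC preset (150 subjects, pooled QC every
sample) where sharp CV estimates are needed to check the filter against
planted values, null designs (20 samples × 50 variables, 20 replicates)
for Q2 and permutation-uniformity behaviour, and one full-size run
(4045 + 9712 features, 1000 permutations) asserting end-to-end
reproducibility under a fixed seed. Key tolerances: PLS1 equivalence and
CV-oracle agreement at 1e-10–1e-12; Σ VIP² at 1e-6; orthogonality at
1e-8; mass arithmetic at 1e-6 Da with fixture masses cross-checked against
an independent atomic-mass tabulation at 1e-4 Da.

Fold assignment, permutations and the generator all draw from seeded
local RNG streams, so every result is bit-reproducible given a seed, and
model fitting does not perturb the caller's RNG state.

## Limitations

The OPLS-DA is binary (paired two-timepoint) only; multi-class designs,
O2-PLS and S-plots are out of scope. Q2 on a 6-pair design has high
variance — permutation p-values, not Q2 magnitude, are the primary
evidence. CV-ANOVA degrees of freedom follow the committed heuristic
above. Annotation is accurate-mass only and deliberately reports *all*
plausible compounds per feature; upgrading an annotation to an
identification requires MS/MS or standards, which the workflow represents
only as a pass-through verification flag.
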