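---
title: "Pre-endoscopic risk scores for upper-GI bleeding: models, scoring rules, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-endoscopic risk scores for upper-GI bleeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugibscores)
```

## The problem

A substantial minority of patients admitted with upper gastrointestinal
bleeding never undergo endoscopy — they refuse, are too unstable, suffer
alcohol withdrawal, or die first. Their in-hospital mortality is far higher
than in endoscopically confirmed variceal or non-variceal bleeding, yet only
*pre-endoscopic* risk scores — those computable from clinical signs and
admission labs alone — can stratify them. This package implements thirteen
such scores, the three liver-failure scores relevant to the cirrhotic
subgroup, and the evaluation machinery (AUC, cutoffs, odds ratios) needed to
compare them on any cohort in the documented CSV dialect.

## Scoring rules and the conventions behind them

Every calculator is a pure function of the patient row, returns its
per-component point breakdown (`pts_*` columns always sum to `value`), and
flags the row unusable when any required input is missing — a
complete-case-per-score policy, so each score is evaluated on exactly the
patients for whom it is computable, and the reported `n_usable` varies by
score just as it does in retrospective chart data.

Several conventions deserve explicit statement because published score
tables are terse:

* **Bin boundaries.** All printed integer ranges are read half-open on the
  right. For the GBS urea bins this resolves the overlap between "48–60"
  and "60–149" as [48, 60) and [60, 150), consistent with the original SI
  definition (6.5–8, 8–10, 10–25 mmol/L) scaled to mg/dL. Likewise the
  INBS creatinine bands place 150 µmol/L in the 1-point bin.
* **GBS hemoglobin rows.** The "men ≥ 10" / "women ≥ 10" rows are read as
  10 ≤ Hb < 12 — the complement of the neighbouring rows, which is the
  original GBS definition.
* **T-score hemoglobin gap.** The published grades (≤8 → 1, 9–10 → 2,
  >10 → 3) leave (8, 9) unassigned; we close it as ≤8 → 1, (8, 10] → 2,
  >10 → 3, preserving every printed anchor while covering the line.
* **Rockall comorbidity** is non-additive: the worst applicable tier is
  taken (cardiac failure / coronary ischemia → 2; renal or liver failure or
  disseminated malignancy → 3).
* **Baylor severity**: acute dominates chronic when both could apply.
* **AIM65** uses sBP < 90 and albumin < 3.0 g/dL exactly as tabulated here
  (the original publication's sBP ≤ 90 is *not* used).
* **BUN is always derived from urea** (× 28.01/60.06), never accepted as a
  separate column, so the 22.4 mg/dL BUN threshold and the 48 mg/dL urea
  bin edge of the GBS cannot disagree. SI thresholds (INBS) are applied
  after conversion from the canonical internal units: urea and creatinine
  mg/dL, albumin g/dL, bilirubin mg/dL.
* **Charlson index** uses the original 1987 weights without age adjustment
  (age already enters most bleeding scores directly); clinical shorthand
  codes alias to their Charlson counterparts and are de-duplicated, so
  `cardiac_failure` + `congestive_heart_failure` counts once.
* **Modified CPT.** The creatinine augmentation of Child–Pugh is not
  standardised; the package adds 0/1/2 points at thresholds 1.3 and
  2.0 mg/dL (configurable). This rule is a package choice, made explicit
  here because several augmentation variants circulate.
* **MELD** uses the UNOS clamps (each lab floored at 1.0, creatinine capped
  at 4.0); both are arguments for sensitivity analysis.

## Evaluation

The AUC is the midrank Mann–Whitney estimator — exactly the probability a
random death outranks a random survivor with ties counted ½ — computed from
ranks in `O(n log n)` and verified in the test suite against a quadratic
concordant-pair oracle on every random instance up to n = 50. Confidence
intervals use the DeLong structural-components variance (deterministic,
standard); a stratified bootstrap utility (`roc_auc_ci_boot`) exists as a
cross-check and agrees within 0.02 at n = 200 in the tests. ROC thresholds
are the distinct observed score values plus a sentinel, rule "score ≥
threshold ⇒ predicted death"; for the T-score, the only lower-is-worse
score, values are internally negated and cutoffs reported back on the
original scale. Youden ties are broken toward the most sensitive threshold
— for a triage score the cheaper error is over-calling risk.

Odds ratios use the Woolf logit interval and Wald z on the log-OR; this
pair reproduces every printed contingency result in
`reproduce_printed_contingency_analyses()` to four decimals, which is why
it was chosen over competing interval constructions. A zero cell triggers
the Haldane–Anscombe +0.5 correction, applied only when needed and flagged
in the output. Chi-square, Fisher and Mann–Whitney tests delegate to base
R (`chisq.test`, `fisher.test`, `wilcox.test`). Swets bands assign
boundary AUCs upward (exactly 0.7 is "moderately accurate").

## The synthetic cohort generator

`generate_cohort()` emulates the admissions structure of a large UGIB
population: a three-group etiology mix (66.3% non-variceal, 21.2%
variceal, 8.1% no endoscopy, renormalised), group-specific covariate
anchors (e.g. the no-endoscopy group: Hb 8.39 g/dL, urea 90.7 mg/dL,
creatinine 1.56 mg/dL, albumin 2.82 g/dL, INR 1.77; cirrhosis prevalence
35.9%), and group mortality targets 7.4% / 21.9% / 37.9%.

The mechanism is a single latent severity $S \sim N(0,1)$ per patient.
Labs are log-normal (positivity by construction) with 25% coefficient of
variation and log-scale severity loadings; vitals are normal with additive
loadings; binary and ordinal fields (syncope, mental status, hematemesis
type, general condition, ASA class, ascites, encephalopathy) use logistic
links tilted by $S$. Death is $\mathrm{Bernoulli}(\mathrm{logit}^{-1}
(\alpha_g + \beta S))$, with each group intercept $\alpha_g$ solved by
root-finding so the *expected* group mortality equals its target under the
standard-normal severity distribution — so realized mortality matches the
targets up to binomial noise at any $\beta$.

A single factor is deliberately the simplest mechanism that makes all
thirteen scores informative at once; `calibrate_auc_band()` rescales only
$\beta$ (never the covariate structure) by bisection until a named score's
AUC on a large generated cohort enters a target band, so the *relative*
ordering of score AUCs emerges from the loadings rather than being forced
per score. Under the defaults that ordering reproduces the qualitative
published pattern: INBS/MAP strongest, GBS family and Iino intermediate,
Rockall/Baylor weak, and the Charlson index weakest — its only severity
link is the mild prevalence tilt on comorbidity draws, mirroring its low
published discrimination.

Values the cohort description does not print were fixed once at clinically
plausible levels: sBP anchors 112/108/105 mmHg and heart-rate anchors
92/96/97 bpm across the three groups (bleeding cohorts run mildly
hypotensive and tachycardic, worst in the sickest group), bilirubin
1.0/2.5/1.8 mg/dL (highest in the variceal/cirrhotic group), age SD 15 y
truncated to 16–99, and per-field missingness of 3–8% on albumin, INR,
bilirubin, general condition and ASA class to emulate retrospective chart
gaps and exercise the complete-case machinery.

What the generator does *not* emulate: admission timing, transfusion and
rebleeding dynamics, correlated multimorbidity clusters, and any
patient-level feature of the original cohort. Passing tests on synthetic
cohorts therefore demonstrate correctness of the calculators and the
evaluation machinery and qualitative fidelity of the AUC ordering — not
numerical agreement with any real cohort's AUC point values, which require
patient-level data.

## Numerical choices and degenerate inputs

* AUC is undefined for single-class outcomes; the pipeline raises an
  explicit error rather than returning 0.5.
* DeLong variance is 0 under perfect separation; the interval degenerates
  to a point, which is reported as-is.
* `n_score`, `modified_n_score` and `iino_score` refuse non-positive
  creatinine (the BUN/creatinine ratio and eGFR are undefined there);
  validation also rejects non-positive vitals/labs at ingest.
* Bisection tolerances: group-intercept calibration solves to 1e-9;
  AUC-band calibration stops as soon as the achieved AUC enters the band
  (at most 25 iterations over a β multiplier in [0.05, 8]) and errors with
  the achievable range if the band cannot be reached.
* Problem sizes: the shipped tests use cohorts of 150–12 000 patients and
  20 000 for the calibrated-generator checks; the acceptance script uses
  20 000. At these sizes the binomial SE on a group mortality rate is
  below 0.012 and the AUC SE in the no-endoscopy stratum about 0.014.

## Known limitations

* The endoscopic components of Rockall and Baylor are intentionally absent:
  the target population has no endoscopy. The full scores cannot be
  computed from this record schema.
* The modified-CPT augmentation rule is a documented package default, not a
  published standard.
* Mean-score tables of real cohorts are only checked directionally on
  synthetic data (no-endoscopy mean GBS exceeds non-variceal), because mean
  levels depend on dispersion parameters the generator fixes by convention.
* MELD-Na and newer MELD revisions, multivariable models, calibration
  curves and net-reclassification metrics are out of scope.
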