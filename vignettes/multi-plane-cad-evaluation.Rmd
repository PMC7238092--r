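---
title: "Multi-plane CAD fusion and reader-study evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-plane CAD fusion and reader-study evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadriplanes)
```

## The problem

Breast-ultrasound CAD modules score each stored imaging plane of a lesion
independently and return a dichotomous call, "possibly benign" or
"possibly malignant", per plane. Reading two orthogonal planes and calling
the lesion positive if *either* plane is positive (the cross-planes rule)
is highly sensitive but weakly specific: one noisy plane suffices for a
positive. Acquiring two additional oblique planes at 45° and requiring at
least 2 of the 4 planes to be positive (the quadri-planes rule) trades a
little sensitivity for substantially better specificity. This package
implements those fusion rules, the BI-RADS category adjustment through
which readers fold the CAD verdict into their own assessment, and the full
paired-comparison statistics of a two-reader study design, together with a
calibrated simulator so the whole pipeline is testable without patient
data.

## Decision model

Readers rate lesions on the ordinal BI-RADS scale restricted to
{3, 4A, 4B, 4C, 5} (internally ranks 0–4). A malignant-sign count maps to
a category as 0 → 3, 1 → 4A, 2 → 4B, 3 → 4C, and ≥ 4 → 5; the published
assignment enumerates 0–3 and "more than 4", so a count of exactly 4 is
assigned to category 5 as the only order-preserving completion. Every 2×2
analysis dichotomizes at the 4A/4B boundary: 4B, 4C and 5 are positive for
cancer.

A fusion rule is "positive if at least *k* of *n* planes are called
malignant": cross-planes uses *k* = 1 of 2, quadri-planes *k* = 2 of 4.
In the combined reading mode the reader's category moves one level up if
the fused verdict is positive, one level down if *every* plane is benign,
and — under the quadri rule with exactly one malignant plane — stays
unchanged: the upgrade and downgrade branches are defined only for those
two situations, and leaving the intermediate case untouched is the
conservative completion. The scale saturates at both ends (3 never
downgrades, 5 never upgrades), so the adjusted rank never differs from the
input rank by more than one level, and the adjustment is monotone in the
plane calls. Plane order never matters; only the count of malignant calls
does.

## Statistical toolkit

**Metric panel.** Sensitivity, specificity, PPV, NPV and accuracy are kept
as exact ratios; the percent strings round half-away-from-zero to one
decimal (the convention of clinical tables; base `round()`'s half-even
rule would print 87.45 as 87.4). A metric with a zero denominator is
returned as `NA` and flagged rather than failing the whole panel.

**McNemar.** Paired modes are compared on the discordant counts *b*, *c*.
The exact test is the two-sided binomial tail at p = ½ over *b* + *c*
discordants; the asymptotic test is the continuity-corrected chi-square
(|b − c| − 1)²/(b + c) on 1 df. `mode = "auto"` uses the exact test below
25 discordant pairs — the usual small-sample guidance — and the
chi-square above. In `evaluate_modes()` McNemar is applied to sensitivity
(paired on malignant lesions), specificity (benign lesions) and accuracy
(all lesions, paired on correct/incorrect). PPV and NPV are *not* given
McNemar tests: their denominators (test-positive and test-negative sets)
differ between the modes being compared, so there is no per-lesion pairing
for a McNemar test to act on.

**Cohen's kappa.** κ = (p₀ − pₑ)/(1 − pₑ) with marginal-product chance
agreement, banded as poor ≤ 0.2, fair 0.21–0.4, moderate 0.41–0.6, good
0.61–0.8, perfect 0.81–1. The exact value is always carried alongside the
2-decimal rounding.

**ROC over ordinal scores.** The empirical ROC of an ordinal score (BI-RADS
rank, or the 0–4 malignant-plane count) has one operating point per
achievable threshold "score ≥ v". Its trapezoidal area equals the
tie-corrected pairwise statistic (concordant positive–negative pairs plus
half the ties, over n₊ · n₋), which the tests verify by exhaustive
enumeration. The AUC standard error uses the Hanley–McNeil formula
(Q₁ = A/(2 − A), Q₂ = 2A²/(1 + A)); two correlated AUCs are compared with
z = (A₁ − A₂)/√(SE₁² + SE₂² − 2 r SE₁ SE₂). The pairing correlation *r*
is rarely reported with published ROC analyses, so
`estimate_paired_auc_correlation()` estimates it as the average of the
within-class Spearman correlations of the two score vectors, clipped to
[0, 1] (a negative rating correlation is treated as zero for variance
purposes, which can only widen the test). Callers may override *r*. On
simulated cohorts this analytic SE agrees with a lesion-level bootstrap
within about 10%.

**Youden cutoff.** J = max(sens + spec − 1) is searched over interior
thresholds only, and the cutoff is reported as the midpoint between the
two adjacent achievable score values — hence half-integer cutoffs such as
1.5 or 2.5 on the plane-count scale. Ties in J are broken toward the
higher-sensitivity (lower) cutoff, the usual screening preference.

**Two proportions.** Decision-change proportions are compared by the
chi-square test without continuity correction, switching to Fisher's exact
conditional test when any expected cell count is 5 or less. All p-values
in the package are two-sided; 0.05 is the conventional significance
threshold.

## Synthetic cohorts

`simulate_cohort()` draws, per lesion:

1. pathology ~ Bernoulli(prevalence), default 0.391;
2. a latent severity S = Z + d·1[malignant], Z ~ N(0,1), with severity
   shift d = 2.4 by default;
3. four plane calls by thresholding an equicorrelated Gaussian vector
   √ρ·W + √(1−ρ)·εⱼ at the class-conditional quantile, so the per-plane
   marginal positive rate is *exactly* `plane_sens` (malignant) or
   `plane_fpr` (benign) at any correlation ρ — the reason this
   construction was chosen over, say, beta-binomial mixing. The shared
   factor W mixes the lesion's severity (weight `cad_reader_dependence`,
   default 0.5) with an independent component, giving CAD calls and
   reader scores the positive dependence that makes combined-mode gains
   non-trivial;
4. per reader, an observed score S + σᵣ·ε thresholded at four increasing
   category boundaries (an ordinal probit), so reader skill is the single
   noise parameter σᵣ.

**Calibration.** Under the latent model the fused k-of-4 positive rate at
per-plane rate p and correlation ρ is the binomial tail at ρ = 0 and an
integral over the shared factor otherwise (`fused_positive_rate()`).
`calibrate_to_fused_targets()` inverts this monotone map by bisection to
residual < 1e−9. The default configuration calibrates the plane rates *at
its own ρ* so that the fused 2-of-4 verdict attains sensitivity 87.5% and
specificity 81.4% regardless of the correlation default; at ρ = 0.3 this
gives per-plane rates of about 0.727 (malignant) and 0.181 (benign).
Reader profiles come from the closed form of the ordinal probit: with
observed-scale SD s = √(1 + σ²), a target (sens, spec) pair at severity
shift d requires s = d/(Φ⁻¹(spec) + Φ⁻¹(sens)) and a 4B boundary at
s·Φ⁻¹(spec). The defaults place the novice at (60.0%, 84.9%) and the
experienced reader at (76.0%, 93.0%); d = 2.4 is the smallest round shift
at which the experienced profile is attainable with non-negative noise.
The remaining category boundaries sit at −1, +0.9 and +1.8 observed-scale
SDs around the 4B boundary; they shape the category histogram but not any
dichotomized metric. The inter-plane correlation default ρ = 0.3 is a
placeholder at a plausible magnitude — no published estimate of this
quantity exists — and is a config knob, as is the CAD–reader dependence.

**What the simulator does and does not emulate.** It reproduces class
prevalence, class-conditional per-plane call rates, exchangeable
inter-plane dependence, stochastically ordered reader categories and
CAD–reader coupling. It does not model lesion-size or histology
covariates, plane-specific quality differences (planes are exchangeable),
reader drift or training effects, or departures from the latent-Gaussian
dependence shape. Passing distributional tests on these cohorts therefore
validates the *pipeline machinery*, not any claim about real reading
behaviour beyond the calibrated marginals.

## Numerical and design choices

- Percent rounding: half away from zero, 1 decimal; exact ratios retained.
- Saturating one-level category adjustment; neutral branch for a single
  malignant plane under the quadri rule.
- Exact McNemar below 25 discordants; the (|b−c|−1)² continuity correction
  is applied verbatim, so at b = c it differs slightly from
  implementations that cap the correction at |b − c| (auto mode would
  select the exact test there anyway).
- Fisher fallback when any expected cell ≤ 5.
- Youden ties break toward higher sensitivity; cutoffs are midpoints of
  achievable score values.
- The rating-correlation estimate for the AUC z-test is clipped to [0, 1];
  degenerate (constant-score) classes drop out with a warning, and r = 0
  is used when both classes are degenerate.
- All simulation randomness flows from one seed through a private RNG
  stream that restores the caller's RNG state.
- Reports are byte-deterministic: no timestamps enter the JSON/CSV output.

The test suite sizes its simulations at 5,000 lesions for
distributional checks (goodness of fit of plane counts, fused-rate
agreement with the binomial tail within 3 Monte-Carlo standard errors,
parameter recovery within 3 binomial standard errors), 20,000–50,000 where
variance ordering or marginal calibration is asserted, and 400 lesions
with 500 bootstrap resamples for the analytic-vs-bootstrap paired-AUC
comparison — large enough for the stated tolerances, small enough to keep
the default run fast.

## Known limitations

- The package evaluates the *mechanical* combined mode: the category is
  always adjusted exactly by the fusion verdict. Readers who selectively
  override CAD are outside the model.
- Multi-reader variance-component analyses (Obuchowski–Rockette, DBM) and
  confidence intervals for proportions are out of scope; comparisons are
  pairwise.
- The Hanley–McNeil SE is an approximation derived under a bi-exponential
  rating model; with heavy ties (few ordinal levels) it can deviate from
  resampling SEs by several percent, which is why the correlation input
  and the z-test are exposed separately and cross-checked against a
  bootstrap in the tests.
- Weighted kappa (for the full ordinal scale) is not implemented;
  agreement is assessed on the dichotomized verdicts.
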