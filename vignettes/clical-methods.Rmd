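---
title: "Methods: the CLICAL score, its synthetic validation cohort, and the survival-forest check"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CLICAL score, its synthetic validation cohort, and the survival-forest check}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clical)
```

## 1. The scoring model

CLICAL aggregates seven baseline clinical variables of a metastatic
melanoma patient starting ICI monotherapy into a single prognostic
score.  Each variable contributes an integer weight; weight 1 always
marks the unfavorable (high-risk) category:

| variable | weight 1 (unfavorable) | weight 2 | weight 3 |
|---|---|---|---|
| age group | younger (< 65 y) | older (≥ 65 y) | — |
| BRAF V600E | mutated | wild type | — |
| prior targeted therapy | yes | no | — |
| LDH (× local reference upper limit) | very high (> 2×) | high (1–2×) | normal (≤ 1×) |
| NLR | abnormal (outside [1, 4]) | normal | — |
| eosinophils | elevated | normal | — |
| CNS metastases | yes | no | — |

The score is the weight sum divided by 7; the achievable levels are
exactly {k/7 : k = 7..15}, verified by exhaustive enumeration of all
2^6 × 3 = 192 category profiles.  Internally the package works on the
integer weight sum and renders the rational score to three decimals only
at I/O, so 11/7 prints as 1.571.

Two modelling points deserve emphasis:

* **The seventh variable.**  The published prose names six variables,
  but every printed score level is a multiple of 1/7 with maximum
  15/7, which forces seven variables of which exactly one is
  trichotomous.  CNS metastases — the one remaining baseline clinical
  variable, and a declared forest feature — completes the arithmetic and
  is included as the seventh binary variable (yes = 1 / no = 2).  The
  weight scheme is a plain serializable object
  (`default_weight_scheme()`), so users disagreeing with this
  reconstruction can supply their own.
* **The age direction.**  The published weight list assigns weight 1 to
  *younger* patients.  That is clinically counterintuitive for most
  cancers, but the package follows the text as written; the scheme is
  configurable.

Signatures merge adjacent score levels with similar survival: sums 7–9 →
I, 10 → II, 11 → III, 12–13 → IV, 14–15 → V.  The minimum sum 7 was
unobserved in the source cohort; it is assigned to Signature I, which
dominates it.  Complete cases only: `complete_case_filter()` drops any
record with an unknown scoring variable, reporting per-variable counts.

Boundary conventions (both configurable): LDH ratio exactly 1 is
*normal* and exactly 2 is *high* (the source text and its tables disagree
on openness of these intervals; the package exposes `boundary =
"lower"/"upper"`); the NLR normal range is the closed interval [1, 4],
with low (< 1) and high (> 4) both mapping to *abnormal*.  The
eosinophil threshold is never defined in the source; the reader accepts a
pre-categorized column (a percentage cutoff, default 5%, is an
implementation convention only).  The age cutoff defaults to 65 years
(the dichotomy the published counts were built on); 60 is supported for
the forest features.

## 2. The synthetic cohort: a stated world

No patient records are distributed, so every downstream stage is
exercised on a seeded synthetic cohort.  The generator encodes, once,
the published cohort description:

* **Marginals** (fractions of n = 578): older 0.55, BRAF-mutated 0.43,
  CNS metastases 0.28, LDH very-high/high/normal 0.14/0.20/0.66,
  eosinophils elevated 0.09, NLR abnormal 0.45, prior treatment
  naive/immunotherapy/target/target+immunotherapy/cytostatic
  0.34/0.25/0.18/0.10/0.13, ICI agent anti-CTLA-4/nivolumab/pembrolizumab
  0.51/0.26/0.23, male 0.55.
* **Structure**: prior targeted therapy presupposes a BRAF mutation.
  BRAF is drawn first; mutated patients receive prior targeted therapy
  with probability 161/234 (the published pre-target count among
  mutated); all others draw from the non-target groups renormalized.
  Other covariates are independent.  This independence deliberately does
  **not** reproduce the published score-level distribution (real
  covariates are correlated); no test or target promises it.
* **Survival**: a two-piece exponential per signature with knot at 32
  months — rate H32/32 before the knot (H32 = 3.42, 2.41, 1.70, 1.08,
  0.48 for signatures I..V, the published 32-month cumulative hazards)
  and rate c·H32/32 after it.  The plateau factor c is calibrated by
  bisection on [0, 5] (tolerance 1e-6) so that the signature mixture
  survival at 70 months equals 20%; the solution is c ≈ 0.191.  A pure
  exponential (c = 1) would give ≈ 7% at 70 months and a frozen hazard
  (c = 0) ≈ 26%, so the knot model is the simplest form matching both
  printed anchors.  The source also quotes 23% at 70 months in its
  discussion section; the Results value (20%) is the calibration target
  and the alternative is one config field away.  The whole-cohort median
  OS of 10 months quoted there is *not* a target: the two-piece model
  with the published hazards implies a later median, a known model-form
  limitation.
* **Censoring**: administrative, uniform on [14, 84] months,
  approximating staggered accrual over 2012–2018 with last follow-up
  near 84 months.
* **Response**: CR/PR/SD/PD at 0.055/0.128/0.178/0.638 (renormalized),
  with a centered log-odds tilt (default 0.4) making higher signatures
  richer in responders while approximately preserving the marginal;
  tilt 0 preserves it exactly.
* **Missingness**: MCAR per variable at the published denominators
  (BRAF 30/578, CNS 6/578, LDH 43/578, eosinophils 35/578, NLR 27/578).
  BRAF masking is restricted to patients without prior targeted therapy
  (the untested patients were all non-target) with the conditional rate
  inflated so the expected masked count is still 30; a consequence is
  that the mutated fraction *among tested* patients is ≈ 44% rather
  than 43%.  Under independent MCAR the expected complete-case yield is
  0.777 × n ≈ 449 of 578 — lower than the published 503, whose
  missingness was positively correlated across variables; the tests
  assert the independent-missingness expectation.

Because survival depends on covariates only through the signature, the
generator supports two modes: `signature_source = "covariates"` (default;
survival follows each record's scored signature — used by the end-to-end
pipeline) and `"proportions"` (signatures drawn from the published
signature mix — the mode in which the 20%-at-70-months calibration is
recovered by Kaplan–Meier, since the covariate-derived mix is more
favorable than the published one).  Everything is a deterministic
function of the config and seed; identical config + seed gives a
byte-identical CSV.

What a green generator test establishes: marginal frequencies, the
structural constraint, hazard levels by signature, the censoring
pattern, and calibration of the 70-month anchor.  What it does not:
covariate correlations, non-proportional or non-piecewise hazards,
informative censoring, or the published score-level counts.

## 3. Native survival estimators

Kaplan–Meier (product limit, Greenwood variance, log-log 95% CIs),
Nelson–Aalen (variance Σ d/n², log-transformed CIs), the Mantel–Cox
log-rank test for k ≥ 2 groups (hypergeometric covariance,
χ² = (O−E)ᵀV⁻¹(O−E) with a pseudo-inverse fallback for degenerate V),
Cox proportional hazards with the Efron tie correction (Newton–Raphson
with step-halving, max 50 iterations, tolerance 1e-9 on the coefficient
change, ridge 1e-8 on singular information, coefficients capped at |15|
with a warning under monotone likelihood), Wald 95% CIs matching the
forest-plot presentation, and Harrell's concordance with ties counted
1/2.  Tied event and censoring times at the same instant follow the
standard convention that events precede censorings.  The
proportional-hazards diagnostic adds covariate × log(t) interactions
evaluated inside the risk sets (no data expansion) and reports their
Wald p-values.

These are implemented natively — the `survival` package appears only in
the test suite as an independent oracle on small fixtures, alongside
hand-computed values (S(8) = 1/3 and H(8) = 5/6 on the three-subject
fixture; log-rank χ² = (2 − 5/6)²/(1/4 + 2/9) ≈ 2.88 on the
four-subject fixture) and brute-force enumerations (Efron partial
likelihood over explicit risk sets, exhaustive concordance pairs).

## 4. The survival random forest

No survival-forest package is available in the target environment, so
the forest is implemented in compiled code following the conventions of
the C-backed forest packages: bootstrap with replacement per tree,
log-rank splitting (the split maximizing the standardized two-sample
log-rank statistic among `mtry` randomly drawn features), terminal-node
Nelson–Aalen cumulative hazards stored as exact sparse step functions,
and ensemble prediction as the across-tree mean hazard with survival
exp(−H).  Categorical features enter as ordered integer codes
(unfavorable low), so axis-parallel threshold splits span the clinically
ordered partitions of these ≤ 5-level factors.  `nodesize` is the
minimum bootstrap-case count of a child node.  Out-of-bag machinery is
first class: each record's OOB hazard is averaged only over trees whose
bootstrap sample excluded it, OOB mortality is the hazard summed over
the event-time grid, and the OOB error is 1 − Harrell's C of that
mortality — the convention of the package family the published analysis
used, which never defines its "OOB error" explicitly.  All randomness
flows through R's RNG, so `set.seed` gives bit-reproducible forests.

Tuning follows the published protocol: for each ntree in
{50, 100, 200, 500, 1000}, search mtry (from 2) and nodesize, pick the
smallest OOB error, break ties toward fewer trees then smaller nodesize.
The published tuned parameters (ntree = 1000, mtry = 2, nodesize = 10 on
the 80% training split; ntree = 500, mtry = 2, nodesize = 6 on the full
data) are reachable grid points; `fit_srf()` defaults to the latter.
Prior treatment enters the forest as the full 5-level variable by
default, with the dichotomized pre-target encoding available.  Missing
data policy mirrors the score: complete cases only.

Risk grouping by predicted 60-month survival probability: the published
fixed thresholds (< 0.2 high, ≥ 0.41 low) for the three-group mode; for
the five-signature mode the thresholds behind the published five groups
are unrecoverable, so the predicted-probability distribution is cut at
the CLICAL signature proportions (cumulative 9.1 / 23.2 / 45.3 / 93.6%),
making forest signatures size-matched to score signatures.  When groups
formed this way are tested against survival of the *same* records, the
probabilities must be the OOB ones (`oob_survival_prob()`); in-sample
ensemble predictions are optimistically biased and inflate the log-rank
statistic — the package exposes both and the tests verify the null
behavior of the OOB route on uninformative features.

## 5. Evaluation

Time-dependent ROC at horizon τ uses the cumulative-cases /
dynamic-controls definition: cases had the event by τ, controls are
event-free at τ, subjects censored before τ drop out, and the remainder
are reweighted by the Kaplan–Meier estimate of the censoring
distribution (1/G(T−) for cases, 1/G(τ) for controls).  The AUC is the
weighted two-sample rank statistic and equals the trapezoidal area under
the returned curve to 1e-9.  The 60-month ROC is attempted and allowed
to fail with a structured error when cases or controls run out — the
published analysis hit exactly this at five years.  The Brier score at τ
is the IPCW-weighted squared error against event-free status, with the
marginal KM prediction as null reference.

## 6. Numerical and design choices

* Exact rational score arithmetic; 3-decimal rendering at I/O only.
* Bisection (not Newton) for plateau calibration: monotone, bracketed,
  tolerance 1e-6; verified against `uniroot` in the tests.
* Log-rank covariance uses the pseudo-inverse when a group's risk set
  degenerates.
* Forest leaf hazards are exact step functions, so horizon evaluation
  involves no grid interpolation error.
* The tuned-versus-untuned acceptance property runs on a documented
  scaled-down tuning grid (ntree {50, 200}, mtry 2, nodesize {6, 15} — a
  subset of the published grid) to fit the test-time budget; the full
  grid remains the API default.
* Pipeline manifests exclude wall-clock fields so identical seeds yield
  byte-identical artifacts.

## 7. Known limitations

* Covariate independence means the synthetic score-level distribution is
  more favorable than the published one; consequently the default-world
  Cox validation AUC at 36 months averages ≈ 0.67 over seeds (range
  0.50–0.80 with ~90-patient validation splits) rather than uniformly
  exceeding the published real-data 80.3 — the published AUCs are
  real-data quantities, covered only by directional checks.
* The two-piece exponential is a reporting-anchor model, not a fitted
  hazard shape; medians and interim survival between the 32- and
  70-month anchors are not calibrated.
* The published "95% accuracy" headline has no defined metric, horizon
  or denominator and is implemented nowhere.
* External-cohort scoring assumes the same LDH reference handling as the
  derivation cohort.
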