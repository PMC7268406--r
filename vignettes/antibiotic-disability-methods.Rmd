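---
title: "Methods: comparative cohort analysis of antibiotic-associated disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cohort analysis of antibiotic-associated disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fqad` implements a new-user, active-comparator cohort analysis of
antibiotic-associated disability in administrative claims: the composite
outcome is a confirmed adverse event (AE) in at least two of six system
organ class (SOC) categories together with an incident short-term
disability claim shortly after an antibiotic dispensing. The target arm is
oral fluoroquinolones (FQ); the comparator is azithromycin for sinusitis
and bronchitis and sulfamethoxazole/trimethoprim for urinary tract
infection (jointly AZ/ST). This vignette documents the models, windows,
parameters and design decisions; the README shows a worked run.

## Study design

**Cohort entry.** A person enters a cohort on the first dispensing of a
study antibiotic occurring 0–30 days (inclusive, day-0 counts) after an
outpatient diagnosis of uncomplicated sinusitis, bronchitis, or urinary
tract infection, with the arm–indication pairing enforced (FQ for any of
the three; azithromycin never for UTI; sulfamethoxazole/trimethoprim only
for UTI). Entry requires 183 days of continuous pre-index observation and
120 days of disability-insured observation afterwards. "6 months", "3
months" and "1 year" are fixed globally at 183, 92 and 365 days — the
windows are only ever specified in days or months, so one convention is
applied everywhere and tested at its boundaries.

**Exclusions.** General exclusions in the 183-day lookback: a list of
chronic conditions (fibromyalgia, rheumatoid arthritis, lupus, complicated
diabetes, Lyme disease, multiple sclerosis, renal or hepatic impairment,
HIV, joint replacement, organ transplant), long-term oral steroid use,
chemotherapy, and any prior disability claim. Long-term steroid use is
operationalized as *cumulative* days supplied ≥ 30 within the lookback;
the wording "30 days or longer" does not say whether the supply must be
continuous, and the cumulative reading is the conservative one for a
claims proxy. Indication-specific exclusions apply in a 92-day lookback
(e.g. hospitalization for pneumonia before a bronchitis index,
pyelonephritis before a UTI index), with hospitalization rules restricted
to inpatient diagnoses. Each removal is attributed to its first matching
rule in the attrition table.

**Mutual exclusivity.** An FQ entry with any AZ/ST dispensing in the
183-day lookback is removed, and vice versa; episodes in which both an FQ
and the comparator were dispensed (other-arm dispensing between the
indication date and 7 days after index) never form an index event. The
7-day co-dispensing tail is a design choice: "but not both" names no
window, so a short, configurable episode window is used. Same-day ties
between qualifying dispensings are broken by the lexicographically lowest
drug code, making cohort construction deterministic.

## Outcome phenotype

An **incident AE** is an AE-mapped diagnosis code first seen 1–30 days
after index with no occurrence of the same code in the 183-day lookback
(ending on the index day). Incidence is assessed at diagnosis-code level —
"the same diagnosis" must recur — not at SOC level. A **confirmed AE**
has the same code again 30–90 days after onset (primary analysis) or
30–60 days (sensitivity analysis), endpoints inclusive, with the onset day
as day 0 of the confirmation clock. The required ≥ 30-day persistence of
the AE is operationalized entirely by this confirmation gap; claims carry
no duration field. Distinct-SOC counting uses six collapsed categories:
ear/labyrinth and eye codes both count once as *sensory* (six categories
spanning seven MedDRA SOCs).

**Disability** is an incident short-term disability claim starting inside
the time-at-risk window (120 days primary, 90 days sensitivity), not
flagged as the continuation of a pre-index claim, in a person with no
claim overlapping the 183-day lookback. "Temporal proximity" between the
claim and the AEs is implemented as co-occurrence inside the time-at-risk
window with no ordering constraint relative to the AE confirmations — only
the window itself is defined by the design. The two analysis variants form
a linked pair: onsets end at day 30, so confirmation by day onset+90
(resp. +60) always falls inside the 120-day (resp. 90-day) window, and
sensitivity cases are provably a subset of primary cases (a tested
invariant). Whether the two SOCs' confirmations must overlap in time is
left unconstrained; that choice is surfaced here rather than hidden.

## Propensity model, trimming, matching

Baseline covariates are strictly pre-index: five-year age bands, sex, and
indicator flags for every diagnosis and drug code in the 30-, 183- and
365-day windows ending the day before index. The propensity score is the
L1-penalized (lasso / Laplace-prior) logistic probability of the FQ arm,
with the penalty selected by 10-fold cross-validated likelihood at
convergence tolerance `2e-7` and seeded fold assignment. The fit is
delegated to `glmnet`; the original large-scale implementation
parameterizes the Laplace prior by a starting variance on a
cross-validated grid, which corresponds to searching `glmnet`'s lambda
path, so the selected-penalty semantics are preserved. Constant columns
are dropped and logged; separation is handled by the penalty.

Entries with scores strictly below the 5th or above the 95th
linear-interpolation percentile of the *pooled* score distribution are
trimmed (boundary values retained — the rule is "less than" / "greater
than"). Matching is 1:1 nearest-first greedy with a caliper of 0.25 times
the sample SD (n−1) of the pooled post-trim scores, on the probability
scale by default (the caliper is defined on "the propensity score
distribution", not its logit; a logit-scale option exists). Greedy order:
all feasible cross-arm pairs by increasing |Δscore|, ties broken by
(target id, comparator id). For large cohorts an equivalent
pooled-sort/heap formulation is used — the globally nearest cross-arm pair
is always adjacent in the pooled score order — giving the same
nearest-first result in O(n log n); with exactly tied scores the two
formulations may pair different, equally-distant partners (both
deterministic, identical pair counts and distances). Balance is reported
as standardized mean differences, `(m1 - m2) / sqrt((v1 + v2)/2)` with
Bernoulli variances for binary covariates, and preference scores
`logit(F) = logit(S) − logit(P)` for treated fraction `P`.

Matching is propensity-only by default; exact matching within indication
is not imposed (the design describes a single pooled score), though the
indication mix is reported so imbalance is visible.

## Estimation and calibration

With 1:1 matched binary outcomes the conditional-logistic odds ratio has
the closed form `n10/n01` over discordant pairs, with
`SE(log OR) = sqrt(1/n10 + 1/n01)`; concordant pairs are ancillary. The
closed form is used directly and verified against numeric maximization of
the conditional likelihood in the tests — an iterative fitter would add
nothing but noise. Crude ORs/RRs on the matched cohorts use standard Wald
machinery with Haldane–Anscombe 0.5 correction on zero cells (flagged).
Published marginals reproduce the printed point estimates; the printed
matched CI itself is not reconstructible from marginals because pair-level
discordance was never published, so CI machinery is validated by
simulation coverage instead.

Each of the 45 negative-control outcomes — conditions assumed causally
unrelated to either arm — is analysed with the same matched pairs and
time-at-risk as the study outcome, but as a plain first-occurrence binary
outcome with a clean 183-day window (controls are single conditions; the
two-SOC composite logic does not apply to them). The systematic-error
distribution Normal(μ, σ) is fitted by maximum likelihood, each control
contributing `Normal(θ̂_i; μ, sqrt(σ² + τ̂_i²))`, via bounded quasi-Newton
on (μ, log σ) with multi-start at σ ∈ {0.01, 0.1, 0.5}, plus an exact
evaluation of the σ = 0 boundary (inverse-variance weighted mean). The
calibrated p-value is the two-sided tail of the estimate under
Normal(μ, sqrt(σ² + SE²)); with μ = 0, σ = 0 it reduces to the nominal
p-value, and with σ > 0 it is uniformly more conservative. The null is
symmetric normal; asymmetric variants are out of scope. The power
calculation uses the odds transform of the baseline proportion and a
one-sided α = 0.05 normal approximation — the only convention under which
the published inputs (119,653 per arm, prevalence 0.002, OR 1.25) give
≥ 80% power; a two-sided option exists.

## The synthetic claims generator

The source data are licensed commercial claims with no public accession,
so the package ships a generator whose defaults emulate the published
cohort's structure, and every pipeline stage is exercised on it. What it
emulates:

* observation periods with ~730-day mean dwell (exponential), 2007–2015,
  working-age entrants (index ages 18–65), 93% disability-insured;
* indication episodes at annual rates 0.20 / 0.16 / 0.14 (sinusitis /
  bronchitis / UTI), treated with a study antibiotic within 0–7 days with
  probability 0.85; arm choice confounded by three baseline
  characteristics (dysuria, hematuria, chronic pain) that shift both the
  treatment log-odds and the outcome log-odds and are visible as
  pre-index diagnosis codes; per-indication FQ log-odds (−0.21, −0.42,
  +0.93) reproduce the published utilization split (azithromycin
  dominant for respiratory indications, FQ dominant for UTI), and the FQ
  drug mix follows the published frequencies (ciprofloxacin and
  levofloxacin ~90%);
* a rare composite-case process: the probability of being a true case is
  logistic with baseline −6.35 plus confounder effects plus `θ` for the
  FQ arm. True cases receive 2 + Poisson(0.66) affected SOCs (matching
  the published ~2.66 SOCs per case), onset days geometric-shaped over
  1–30 (median 8, ~38% beyond day 10), confirmation delays 30 +
  geometric over 30–90 (median ≈ 42), and a disability claim at days
  30–120. The baseline is calibrated once so the composite incidence
  lands near the published 0.2% (observed ≈ 0.22–0.27% at n = 50,000) —
  the per-SOC and per-case rates are artifact choices, since only the
  composite incidence is published;
* arm-independent background noise: per-SOC background AE episodes
  (≈ 15% of entries show ≥ 1 confirmed AE, echoing the published
  per-drug tables), background disability with log-odds increasing by
  0.30 per confirmed SOC, exclusion conditions, steroid/chemotherapy
  dispensings, historical disability claims with flagged continuations,
  and 45 negative-control conditions at rate 0.015 per person, uniform
  over the observation period and independent of arm unless a shared
  bias term is injected.

**The estimand.** `θ` is defined on the composite-case process, so the
matched OR targets exactly `exp(θ)`. Defining `θ` on per-SOC hazards
instead would make the composite OR roughly `exp(2θ)` at rare rates and
leave the generator without a usable ground truth. Background
(arm-independent) composite cases arise at ~1e-4 and dilute the observed
OR toward the null by a few percent at `θ = log 2`; the recovery tests use
CI coverage, which absorbs this.

What the generator does **not** emulate: billing semantics, costs, plan
types, per-indication drug preferences within the FQ class, mortality and
attrition correlated with adverse events, code-level correlation
structure beyond the injected confounders, and real ICD-9 chapter
structure (all codes outside the three indication families are synthetic
stand-ins; the vocabulary file is the injection point for real code
sets). Passing tests therefore demonstrate that the *methods* are
implemented correctly and recover known truth under claims-like
structure, not that the published estimates would reproduce on the
licensed data.

The ground-truth sidecar (`truth.csv`) records confounder carriage, the
anticipated arm and true case status; it is written for tests only and
never read by any pipeline stage.

## Numerical and reproducibility choices

* Dates are day-resolution; all window arithmetic is integer days.
* One seed drives everything; per-table sub-streams are derived
  deterministically (`seed * 131 + k * 9973 mod 2^31 − 1`), so each table
  is independently reproducible, and end-to-end reruns are identical.
* Degenerate inputs: zero persons yield empty, schema-complete tables;
  zero matched pairs abort estimation with a named error; zero discordant
  pairs make the conditional OR undefined (named error; single zero cells
  are 0.5-corrected and flagged); all-identical scores trim nothing;
  fewer than 5 usable negative controls abort calibration.
* Report rounding follows the published display precision: 2 d.p. for
  odds ratios and per-case means, 1 d.p. for percentages.

## Problem sizes used in the test-suite

Oracle-equivalence tests run brute-force per-person validators on
instances of ≤ 1,000 persons and exhaustive matching on ≤ 12 entries.
Pipeline recovery properties (null coverage with confounding on, and
recovery of a doubled odds ratio) run the complete pipeline at 20,000
simulated persons per seed across 20 seeds each, requiring ≥ 90% CI
coverage of the truth; runs whose matched pairs are fully concordant
carry no conditional-likelihood information and are excluded from the
coverage denominator. The calibration type-I property (shared systematic
bias absorbed by the empirical null while nominal p-values over-reject)
is simulated at the matched-pair count level — 45 controls plus a
true-null outcome per seed, 200 seeds — which isolates precisely the
estimator-and-calibration path the property is about. These sizes are the
package's chosen test conditions; the generator's scientific defaults are
independent of them.

## Known limitations

* The SOC membership lists, the 45 control conditions and the exclusion
  code sets are synthetic placeholders behind a validated configuration
  schema; swapping in licensed vocabularies changes no code.
* Matched CIs use Wald intervals on the discordant-pair closed form;
  exact conditional intervals are not implemented.
* Calibrated confidence intervals (as opposed to calibrated p-values) are
  out of scope, as are asymmetric empirical nulls.
* The cohort builder reads a single diagnosis stream; reconciling
  conflicting diagnosis sources is left to real-data adapters.
* Person-time at risk censors only at the qualifying outcome; by
  construction eligibility guarantees full observation of the
  time-at-risk window, so no other censoring exists in-cohort.
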