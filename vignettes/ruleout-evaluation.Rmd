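---
title: "Evaluating rule-out triage in cancer screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating rule-out triage in cancer screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleout)
```

## The problem

Screening mammography programmes read millions of examinations a year,
the vast majority of them cancer free. A *rule-out* device is an AI
reader operated at an extreme, high-sensitivity operating point: it
marks a subset of examinations as nonsuspicious so they bypass human
interpretation entirely, receiving a negative prediction (BI-RADS 1).
Because radiologists never see ruled-out examinations, the device can
only *remove* detections, never add them — which makes retrospective
evaluation tractable, but also means the evaluation must account for the
whole downstream pathway: callbacks, diagnostic workups, biopsies and
the cancer detection rate, not just discrimination.

This package implements that evaluation as a pipeline of small, testable
stages. This vignette records the models and estimators, the parameters
that matter, and the design decisions taken where the methodology left
genuine choices.

## Outcome labeling

Screening records arrive as two tables: examinations (one row per
screening exam, with a device score, reader and scanner) and events
(per-breast screening assessments, diagnostic assessments, and biopsy
pathology, each dated). Each breast at each examination receives one of
eight labels, totally ordered by severity:

| label | meaning | rule |
|---|---|---|
| N | negative | screening BI-RADS 1 |
| S | screening benign | screening BI-RADS 2 |
| D | diagnostic benign | recall (BI-RADS 0) resolved by a negative diagnostic assessment |
| U | unknown | evidence insufficient for any other label |
| P | pathology benign | benign biopsy pathology |
| H | high risk | nonupstaged high-risk pathology |
| I | interval cancer | malignant pathology within the screening interval after a negative/benign screen, before the next screen |
| M | malignant | malignant pathology on the recall pathway |

Examination labels are the maximum of the two breast labels, so a
malignancy on either side dominates. The N, S and D labels additionally
require a later screening examination at least `followup_min_months`
(default 24) after the index exam and *no biopsy event anywhere in the
patient's history*; breasts failing that are U and excluded from
analysis. Against an outcome window of *w* months the positive class is
{M, I} with the cancer date inside the window, the negative class is
{N, S, D, P, H}, and U is excluded.

Decisions worth recording, where the scheme admits ambiguity:

* **Month arithmetic** uses calendar-month offsets with the day of
  month clamped to month end (`add_months("2015-01-31", 1)` is
  February 28), so window logic is independent of leap years.
* **Window boundaries** are half-open: a cancer is inside the window
  when its date lies in (exam, exam + *w* months]. Same-day pathology
  on a recalled breast belongs to that exam's callback pathway, not the
  interval.
* **M/I exams whose cancer falls outside the evaluation window** are
  *excluded* from that window's analysis rather than counted negative:
  the evaluation never treats a known cancer as a negative, and
  relabeling would contaminate specificity.
* **The follow-up clock for N/S/D starts at the index exam date**, also
  for D (not at the diagnostic resolution); this is the simpler reading
  and is applied uniformly.
* **Competing pathology** within the window resolves to the most severe
  (malignant > high risk > benign), mirroring the max-propagation rule.
* **Screening BI-RADS 3**, which can arise from mapped UK opinions, is
  treated as callback-equivalent: screening negatives are exactly
  assessments 1 and 2.

UK reader opinions are mapped onto BI-RADS before labeling (screening:
normal→1, benign→2, anything else→0; diagnostic: benign→3,
suspicious/uncertain→4, malignant→5; a diagnostic "normal", which the
mapping tables leave unstated, is taken as a negative diagnostic
assessment, code 1).

## Operating point and workflow simulation

Given validation scores and positive flags, the operating threshold is
the *largest* candidate value (observed scores plus 0) whose positive
retention fraction meets the target sensitivity — maximising automation
subject to the sensitivity constraint:

```{r}
select_operating_threshold(c(0.2, 0.5, 0.9), rep(TRUE, 3),
                           target_sensitivity = 2/3)
```

Ties at the threshold are *retained* for human reading: a score rules
out only when strictly below the threshold. When the constraint cannot
afford to drop even one positive, the minimum positive score is returned
with a warning. Thresholds can be selected globally or per scanner
model; per-scanner selection matters when the score distribution differs
by hardware, and the package evaluates each stratum at its own point in
that mode.

The workflow simulation (`apply_ruleout()`) assumes radiologists'
readings of retained examinations are unaffected by the device — the
standard retrospective assumption, and the reason the combined
sensitivity identity

$$\text{sens}_{\text{human+AI}} = \text{sens}_{\text{radiologist}}
  \times \text{sens}_{\text{relative}}$$

holds exactly: the device-retained detections are a subset of the
radiologist's detections. The identity is asserted to machine precision
on every generated cohort in the test suite.

## Metrics and prevalence rebalancing

With radiologist true positives defined as positives assessed BI-RADS
0/4/5/6:

* **relative sensitivity** — retained radiologist detections /
  radiologist detections;
* **absolute sensitivity** — retained positives / positives;
* **rule-out rate** — fraction of examinations scored below threshold;
* **FP callback reduction** — fraction of recalled cancer-negative
  examinations ruled out;
* **benign biopsy reduction** — fraction of P/H examinations ruled out
  (biopsy avoided); biopsies are counted at examination level since
  labels are exam-propagated;
* **specificity** — negatives assessed 1/2 (plus, with the device,
  negatives ruled out) / negatives;
* **CDR** — radiologist detections (retained ones, with the device) per
  1000 examinations.

Evaluation sets are usually case-enriched. Prevalence-dependent metrics
(rule-out rate, the reductions, CDR, specificity) accept per-subclass
weights `target(c) / observed_proportion(c)`, which make weighted
subclass proportions equal the target vector exactly. The target vector
is a required user input: natural subclass prevalences are
population-specific and no default can claim generality — the
generator's defaults used in examples are documented as illustrative.
Sensitivity-type metrics condition on the cancer class and are reported
unweighted.

Per-reader and per-scanner summaries follow the inclusion rule of at
least 10 cancer-positive and 10 cancer-negative examinations per
stratum; excluded strata still contribute to collective estimates, in
which each examination carries equal weight. The flow report normalises
the workflow accounting to 10 000 screening examinations and conserves
counts at every node (total = ruled out + read; read = callbacks +
negatives; biopsies ≤ callbacks).

## Inference

**Noninferiority.** Sensitivity and CDR comparisons between the
standard and rule-out workflows are paired: every examination is read
under both. With `b` detections lost to rule-out and `c` gained
(structurally 0), and margin $\delta$ (0.05 for sensitivity, 0.00025
per-exam for CDR's 0.25 per 1000), the package uses a score-type z on
the paired difference $\hat d = (b - c)/n$ with the variance constrained
to the boundary null and a $0.5/n$ continuity correction:

$$z = \frac{\delta - \hat d - 1/(2n)}{\sqrt{(2c/n + \delta -
\delta^2)/n}}, \qquad p = 1 - \Phi(z).$$

The exact variant of the reference paired test is not fully specified in
the methodology this follows, so the statistic was chosen to track the
exact enumeration of the boundary null — for $c = 0$, $B \sim
\mathrm{Bin}(n, \delta)$ and $p_{\text{exact}} = P(B \le b)$ — within
0.02 in the decision-relevant tail (the approximation is loosest, about
0.03, where $b$ is near $n\delta$). An empirical-variance Wald z was
rejected because it deviates from the exact enumeration by more than
0.1 at small counts. With no discordant pairs at all the exact
$p = (1-\delta)^n$ is used directly; note that identical workflows are
therefore *not* automatically declared noninferior at small $n$ — there
is genuinely not enough information.

```{r}
noninferiority_paired_z(b = 2, c = 0, n = 595, margin = 0.05)
```

**Bootstrap.** CIs are percentile intervals over `n_reps` (default
2000) resamples, drawn at examination or patient level. Resampling can
be stratified by outcome subclass, so each replicate preserves subclass
counts — without this, prevalence-adjusted metrics are undefined
whenever a rare subclass vanishes from a resample. Degenerate replicates
are redrawn up to 10 times before being marked undefined; more than 50%
undefined aborts with a diagnostic. Percentile (rather than BCa)
intervals keep the stratified scheme simple and are standard for these
proportions. One-sided superiority p values invert the bootstrap
distribution: $p = (1 + \#\{\text{replicates} \le 0\})/(n_{\text{reps}}
+ 1)$. The examination-level default matches the common simplification
of treating a patient's examinations as independent; the patient-level
option addresses that acknowledged correlation.

Calibration is part of the test suite: type-I error of the
noninferiority test at the margin boundary over 1000 simulated cohorts,
and 95% CI coverage for the rule-out rate within [0.92, 0.98] over 500
simulations.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable without
clinical data and so that true metric values are available in closed
form. One examination is generated as:

1. **Subclass draw.** Cancer with probability
   $\pi_C E / (\pi_C E + 1 - \pi_C)$ (enrichment factor $E$ tilting the
   cancer odds), then M vs I by their natural ratio. Cancer-free
   examinations draw N/S/D/P/H from the assigned reader's conditional
   distribution: the callback classes D/P/H are scaled to the reader's
   false-positive callback rate (split between biopsy and no-biopsy
   paths by the configured biopsy fraction), N/S fill the rest. By
   default both dials equal the values implied by the prevalence
   vector, so the marginal subclass mix is exactly
   `natural_prevalence`; overriding them re-tilts the mix, and the
   closed forms account for it.
2. **Reader behaviour.** A drawn M is detected with the reader's
   sensitivity; misses are relabeled I. Interval cancers therefore
   arise by two routes — true interval draws and reader misses — both
   carrying label I, deliberately not distinguished downstream (missed
   cancers and true interval cancers are not discernible in outcome
   data either).
3. **Events.** Assessments conformant with the final subclass (N→1,
   S→2, D/P/H/M→0 recall, I→1 or 2) on the affected side, a clean
   contralateral side, diagnostic resolution for D at one month, biopsy
   pathology for P/H/M at one month, interval-cancer pathology at a
   uniform month within the interval, and follow-up screens at 25–30
   months for N/S/D. Detected cancers use assessment 0 (the screening
   recall code) so that source-data screening assessments stay within
   {0, 1, 2}.
4. **Scores.** Device scores are Beta draws conditional on the final
   subclass. Defaults give high separability (cancers right-shifted,
   interval cancers intermediate — they are partly invisible at
   screening) without claiming to match any real model's score
   distribution; every shape is configurable. Missed-M interval cancers
   draw from the I law, keeping the closed forms exact.

The generating subclass, not just the emitted events, is recorded, and
the round-trip property — relabeling the events recovers the subclass
for 100% of examinations — is asserted on a 10 000-exam cohort in the
acceptance suite. `effective_prevalence()` returns the post-reader
subclass distribution (the weighting target for natural-population
metrics), and `true_metric()` gives closed-form expectations such as

$$\text{rule-out rate}(t) = \sum_c \pi_c F_c(t),$$

with $F_c$ the class-conditional Beta CDF. Parameter recovery —
prevalence-weighted estimates on a 10×-enriched cohort of 50 000
examinations matching the closed forms within 3 Monte Carlo standard
errors (delta-method SEs for the weighted ratios) — is an acceptance
test. Closed forms are provided for single-read configurations;
double-read mode, which generates first/final opinions through a simple
concordance model to exercise the per-reader stratified analysis, has no
closed-form oracle.

What the generator does *not* emulate: real score distributions and
their scanner dependence (scanner here is an independent stratification
factor, not a score modifier), demographic structure, multiple
examinations per patient (each examination gets its own patient, so
patient-level bootstrap collapses to exam-level on generated data),
drifting reader behaviour over time, and missing or contradictory
records beyond what the validators reject. Passing tests on synthetic
cohorts therefore demonstrate correctness of the estimators and
labeling logic under conformant data, not performance claims about any
real device or population.

## Problem sizes and numerical choices

Simulation-based tests use cohorts of 2000–50 000 examinations with
fixed seeds, 200–500 bootstrap replicates in orchestration tests and
400–500 in calibration tests; these sizes put Monte Carlo error well
below the asserted tolerances while keeping the default suite quick.
Candidate thresholds are restricted to observed scores plus zero, and
sensitivity feasibility is compared with `>=` on exact binomial
fractions, so threshold selection involves no floating tolerance.
Bootstrap reproducibility is guaranteed by seeding and restoring the
RNG state around each call. Degenerate inputs (no positives, no
callbacks, vanished subclasses, zero-variance paired counts) are
rejected with informative errors or handled by the documented exact
fallbacks rather than returning NaN.

## Known limitations

* The evaluation assumes radiologist behaviour is unchanged on retained
  examinations; prospective reader effects are out of scope.
* Natural prevalence vectors must be supplied by the user; the package
  ships no authoritative population mix.
* The paired noninferiority statistic is a documented approximation to
  an exact enumeration; for very small cohorts use the exact binomial
  p directly (it is what the degenerate path computes).
* Whether recalled-but-benign (BI-RADS 3-equivalent) examinations count
  as callbacks in reduction metrics is a convention; this package
  counts every non-{1,2} screening assessment as a callback.
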