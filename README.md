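# ruleout

Retrospective evaluation of semiautonomous **rule-out triage** in breast
cancer screening.

A rule-out device is an AI reader operated near 100% cancer sensitivity:
examinations it scores below an operating threshold are marked
nonsuspicious and removed from the radiologist worklist (assigned
BI-RADS 1); everything else keeps the original clinical assessment.
Evaluating such a device retrospectively requires more than an ROC
curve, because the quantity of interest is the *downstream* effect on a
screening programme: how many examinations still need human reading, how
many false-positive callbacks and benign biopsies are avoided, and
whether the cancer detection rate survives. This package implements that
evaluation pipeline for biostatisticians and evaluation teams working
with longitudinal screening records (or entirely without data, via a
synthetic cohort generator with known ground truth).

## What it computes

**Outcome labeling.** Each breast's screening history is reduced to an
ordered outcome label

```
N (negative) < S (screening benign) < D (diagnostic benign) < U (unknown)
  < P (pathology benign) < H (high risk) < I (interval cancer) < M (malignant)
```

with examination labels propagated as the maximum of the two breasts.
N/S/D require ≥ 2 years of follow-up and a biopsy-free patient history;
interval cancers are malignancies within the screening interval after a
negative/benign screen, before the next screen. Against an outcome
window of *w* months, the cancer-positive class is {M, I} with the
cancer inside the window; {N, S, D, P, H} are negative; U is excluded.

**Operating point.** On a validation set the threshold *t* is the
largest score value such that

  sens(t) = #{positives with score ≥ t} / #positives ≥ target (0.99 or 0.97),

which maximises the rule-out volume subject to the sensitivity
constraint.

**Workflow metrics**, optionally reweighted from a case-enriched set to
a natural screening population (weight = target prevalence / observed
proportion per subclass): rule-out rate, false-positive callback
reduction, benign biopsy reduction, specificity, cancer detection rate
(per 1000), absolute/relative device sensitivity, and the combined
workflow sensitivity identity

  sens(human+AI) = sens(radiologist) x relative sensitivity(device),

which holds exactly because the device can only remove detections.

**Inference.** Paired noninferiority testing of sensitivity (5% margin)
and CDR (0.25 per 1000 margin) via a score-type z on discordant pairs
(exact paired-binomial enumeration in the degenerate case), stratified
bootstrap percentile CIs, and one-sided superiority p values by CI
inversion.

**Synthetic cohorts.** `generate_cohort()` draws subclasses from a
configurable (enrichment-tilted) prevalence vector, simulates reader
sensitivity and callback behaviour, interval cancers by two routes
(true interval draws and reader misses), two scanner strata and
class-conditional Beta device scores — and emits event streams that
relabel exactly to the generating subclass, plus closed-form metric
expectations (`true_metric()`) for parameter-recovery testing.

## Worked example

```r
library(ruleout)

cfg    <- generator_config(n_exams = 20000, enrichment_factor = 10, seed = 2024)
cohort <- generate_cohort(cfg)
exams  <- classify_exams(cohort$exams, window_months = 12)

point <- select_operating_threshold(exams$device_score,
                                    exams$class == "positive",
                                    target_sensitivity = 0.99)
point
#> Rule-out operating point
#>   threshold: 0.177358
#>   target sensitivity: 0.99
#>   achieved validation sensitivity: 0.99 (900 positives, 20000 exams)

w <- prevalence_weights(subclass_counts(exams), effective_prevalence(cfg))
100 * ruleout_rate(exams, point, w)            # 60.1  (% of exams automated)
100 * fp_callback_reduction(exams, point, w)   # 21.1  (% of FP callbacks avoided)
100 * benign_biopsy_reduction(exams, point, w) # 6.2   (% of benign biopsies avoided)
cdr(exams, NULL, w); cdr(exams, point, w)      # 3.40 / 3.40 per 1000: CDR unchanged

flow_table(exams, point, w)
#>               node standard    ruleout
#> 1            total    10000 10000.0000
#> 2        ruled_out        0  6008.8064
#> 3 radiologist_read    10000  3991.1936
#> 4        callbacks      954   759.8280
#> 5 screen_negatives     9046  3231.3657
#> 6  benign_biopsies      120   112.5462
#> 7 cancers_detected       34    34.0000
```

Reading the flow table: at this operating point the device reads 60% of
the (prevalence-weighted) examinations as nonsuspicious, callbacks per
10 000 screens drop from 954 to 760 and benign biopsies from 120 to
112.5, while the 34 detected cancers per 10 000 are untouched — the
rule-out threshold was chosen so that scores of detected cancers stay
above it. Sensitivity inference on the same cohort (no detections lost):

```r
pos  <- exams[exams$class == "positive", ]
lost <- sum(radiologist_true_positive(pos) & pos$device_score < point$threshold)
noninferiority_paired_z(b = lost, c = 0, n = nrow(pos), margin = 0.05)
#>   Exact paired-binomial noninferiority test (no discordant pairs)
#> data:  b = 0, c = 0, n = 900
#> p-value = 8.938e-21
#> conclusion: noninferior
```

`run_evaluation(config)` orchestrates all of the above from CSV inputs
to a report bundle (labeled exams, operating point JSON, metric table
with bootstrap CIs, flow tables, per-reader and per-scanner
breakdowns); `inst/scripts/ruleout-cli.R` wraps the same functions as
`simulate` / `label` / `threshold` / `evaluate` / `report` subcommands.

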