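---
title: "Hemorrhage risk stratification as a screening test: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemorrhage risk stratification as a screening test: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemrisk)
```

## The problem

Obstetric hemorrhage units screen every admission with a three-tier
risk-assessment checklist. This package asks the screening-test question:
how well do the tiers separate deliveries that go on to experience
hemorrhage-related morbidity from those that do not? The analysis has four
stages — classify, score, tabulate, evaluate — and each is a small, testable
function.

## The classification rules

The classifier is a pure function of a 19-field risk-factor profile.
Medium-tier items each count once; high-tier items classify as high
unconditionally; two or more medium items escalate to high; one medium item
is medium; nothing triggered is low.

Three rules needed interpretation, and the package resolves them as follows:

* **Hematocrit < 30 "and other risk factors"** — unlike the other high-tier
  items this one is written as a conjunction, so it counts as a high item
  only when at least one other medium or high item is triggered. A
  hematocrit of 28 alone leaves a delivery low risk; the same hematocrit
  plus an induction of labor is high risk.
* **Bleeding disorder vs coagulopathy** — the low-tier wording ("no known
  bleeding disorder") and the high-tier wording ("known coagulopathy") are
  treated as one concept: either recorded flag triggers the high item. No
  operational distinction between them is available in the field set.
* **Multiple gestation** — a singleton pregnancy is a low-tier requirement,
  and a non-singleton pregnancy must therefore break low-eligibility; it is
  counted as one medium item (it is not listed as a high item). It is
  included in the medium-item list returned by `medium_risk_items()` so the
  returned item lists always determine the level.

All numeric boundaries are strict as printed: BMI > 35, estimated fetal
weight > 4 kg, > 4 previous vaginal births, platelets < 100,000/µL,
hematocrit < 30, blood loss ≥ 1000 mL (the one inclusive threshold). A
missing numeric never triggers its item; a record whose assessment fields
are *all* missing is excluded at ingest and counted in the run log.

## The composite outcome

Composite morbidity is the union of four overlapping indicators:
hemorrhage (EBL ≥ 1000 mL), any pRBC transfusion, ICU admission, and an
additional hemorrhage-related procedure (hysterectomy or dilation and
curettage). Reports always show the union *and* the raw component counts,
because the components are not additive — a transfused hemorrhage counts
once in the composite.

## Screening diagnostics

Each contrast (medium vs low, high vs low, medium+high vs low) forms a 2×2
table against the low-risk referent; records at the excluded tier are
dropped, not pooled. From the table: sensitivity, specificity, PPV, NPV and
the cross-product diagnostic odds ratio dOR = (TP·TN)/(FP·FN), with a Woolf
(log-normal) 95% interval,
$\exp\left(\log \mathrm{dOR} \pm z_{1-\alpha/2}\sqrt{1/TP+1/FP+1/FN+1/TN}\right)$.

Numerical choices:

* **Zero cells** use the Haldane–Anscombe correction (+0.5 to all four
  cells) before the odds ratio and interval, and set a `correction_applied`
  flag. This is deterministic and testable; it never fires on the
  calibrated cohort sizes.
* **Odds ratio, not risk ratio.** The tool's published summary language
  equates the diagnostic OR with a relative risk, but the printed values are
  cross-product odds ratios (the combined-contrast risk ratio would be
  ≈ 4.24, not 4.58), so the package computes odds ratios throughout and
  says so in its outputs.
* **Woolf only.** One interval method is implemented. Exact conditional
  intervals were considered and rejected: the conditional MLE behind them
  is not the cross-product estimate the reports print, and mixing the two
  invites misreading. At these cell sizes the log-normal approximation is
  excellent (coverage is property-tested at 95% ± 2.5%).
* **Rounding** happens only at report time: 2 decimal places for
  diagnostics, 1 for percentages; JSON output carries full precision. The
  full-precision combined PPV is 0.0946 — "a 9% chance" — and the package
  reports that value rather than a coarser rounded figure.
* **Zero denominators** (e.g. PPV with no test-positives) raise an error
  naming the statistic rather than returning NaN.

## The synthetic cohort generator

The generator emulates the published study conditions: 14,803 low-risk,
26,163 medium-risk and 15,937 high-risk deliveries (56,903 total), per-tier
composite probabilities 330/14803, 2084/26163 and 1898/15937, and per-tier
hemorrhage probabilities 304/14803, 1986/26163 and 1822/15937. These
defaults *are* the study conditions and are not tuning knobs.

**Overlap model.** Published tables give only marginal component counts per
tier, not their joint distribution, so transfusion, ICU admission and the
additional-complication indicator are drawn conditionally on hemorrhage
status. Within each tier the no-hemorrhage conditional probabilities are
taken proportional to the component marginals and scaled — by
one-dimensional root finding at spec construction — so the expected
no-hemorrhage union equals the composite excess over hemorrhage; the rest of
each marginal is assigned to hemorrhage records. The result matches every
published marginal and the composite union exactly in expectation (this is
asserted analytically in the tests). The solved conditionals are documented
constants of the generator, not claims about the real cohort; an alternative
reading in which the published transfusion counts are already
hemorrhage-exclusive would change only these internal constants, not any
marginal the evaluation sees.

**Profiles.** Each record receives a risk-factor profile consistent with its
tier: low profiles trigger nothing (numerics are drawn in non-triggering
ranges, hematocrit ≥ 30, with ~20% of each nullable numeric missing); medium
profiles trigger exactly one medium item, sampled from a weight table
roughly ordered by clinical frequency (induction and prior cesarean
dominate); high profiles take one of three routes — one unconditional high
item (55%), escalation via two medium items (35%), or low hematocrit plus a
medium item (10%). Any positive weights preserve the outcome calibration,
because outcomes depend only on the tier. With zero misclassification noise
the classifier recovers the assigned tier for every record — a tested
round-trip invariant.

**Blood loss magnitudes** only need to land on the correct side of the
1000 mL threshold. Non-hemorrhage records draw from a log-normal body
(meanlog log 350, sdlog 0.5) truncated below 1000 mL by inverse-CDF
sampling; hemorrhage records draw 1000 mL plus a log-normal excess (meanlog
log 250, sdlog 0.8). Any supported-on-the-correct-side choice leaves all
evaluation results unchanged.

**Misclassification noise** (default 0) emulates recorded-tier scoring
error: a flipped record keeps its recorded tier and tier-calibrated
outcomes, but its profile is drawn from a different tier. Observed
classifier/recorded-tier disagreement then concentrates at the chosen rate.

**Seeding.** One integer master seed is split arithmetically into
per-tier, per-stage streams (profile, hemorrhage, components, blood loss,
transfusion units, procedures, misclassification), so identical spec + seed
gives byte-identical CSV output and adding a stage never perturbs earlier
draws.

## What the tests do and do not show

The acceptance surface replays the published per-tier counts through the
evaluation stage (deterministic, exact to the printed precision) and runs
the generator at full scale (stochastic, judged within Monte-Carlo error of
the closed-form value; one 56,903-record replicate's log-dOR has standard
error ≈ 0.058). Property tests cover classifier monotonicity, equivalence
with an independent brute-force oracle on 10,000 random profiles and on the
full medium-item lattice, the dOR–sensitivity/specificity identity, Bayes
consistency of the predictive values at 10⁻¹², and Woolf coverage over
simulated tables. Simulation sizes (500–1000 tables, 10,000 profiles) were
chosen to keep the default suite fast while leaving the binomial tolerance
bands discriminating.

Passing these tests shows the pipeline is internally correct and calibrated
to the published marginals. It does **not** show the generator resembles
real deliveries beyond those marginals: covariate correlations, site
clustering across hospitals, repeat assessments at pre-birth and postpartum
time points, and the true joint distribution of morbidity components are
all unmodeled, and the rule set is applied exactly as written, whereas
recorded tiers in practice contain scoring errors (which the
misclassification knob only caricatures).

## Known limitations

* The evaluation is timing-agnostic: which administration of the tool
  (admission, pre-birth, postpartum) produced a recorded tier is out of
  scope.
* No imputation: missing risk factors simply do not trigger items, which in
  real data biases tiers downward for incompletely charted deliveries.
* Transfusion timing is not modeled; any recorded pRBC administration
  counts toward the composite.
* Between-tier covariate hypothesis testing and multiplicity adjustment are
  intentionally absent — the package evaluates the tiers as a screening
  test, nothing more.
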