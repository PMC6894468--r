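---
title: "The Duplication of Behaviour analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Duplication of Behaviour analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupbehav)
```

## The model

The Duplication of Behaviour Law is a descriptive, population-level model
of how engagement is shared across competing activities. Its empirical
claim is that the proportion of activity A's engagers who also engage in B
depends chiefly on B's overall prevalence, not on which activity A is.
Everything the package computes follows from a binary person × activity
engagement matrix over a recall window:

- penetration `p_B`: percent of the base engaging in B at least once;
- duplication `d[A,B]`: percent of A's engagers also engaging in B
  (asymmetric; at full precision `d[A,B]·n_A = d[B,A]·n_B`, both equalling
  100 × the joint engager count — the package tests this invariant);
- column average `d̄_B`: mean of `d[·,B]` over the other activities;
- duplication coefficient `D = mean(d̄_B) / mean(p_B)`;
- expected value `E_B = D·p_B`, the Law's quantitative benchmark;
- deviation `δ[A,B] = d[A,B] −` reference`_B` (column average by default,
  `E_B` optionally), positive = more co-occurrence than the reference;
- MAD: mean `|δ|` over off-diagonal cells.

The model is deliberately assumption-light: no likelihood is fitted and no
confounders enter. Its one substantive assumption is minimal segmentation —
that engagement in an activity is not strongly conditioned on demographics.
The user-profile analysis checks exactly that, by comparing each activity's
engager composition (gender, age bins) against the unweighted mean
composition across activities and summarizing departures as a composition
MAD.

## Assumptions and interpretation

`D = 1` means engaging in one activity leaves the probability of engaging
in any other at the population average; `D < 1` means activities within the
set compete (engaging in one depresses the rest), as is typical *within* a
category such as Exercise and Sport sub-domains. Deviations of at least
±5 percentage points are treated as practically important, a conventional
cut-off inherited from leisure-activity duplication research; cells in
[4, 5) are marked "near" the cut-off. A *partition* requires both
directions of a pair to clear the threshold with the same sign —
one-sided excursions are flagged but are not partitions. The MAD < 5
segmentation verdict is likewise conventional and the package labels it
configurable rather than principled; the boundary MAD = 5 is assigned to
"segmented".

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| deviation `threshold` | 5 | pp | conventional practical-importance cut-off |
| `near_band` | 4 | pp | reproduces the "just short of the cut-off" marker |
| segmentation verdict threshold | 5 | pp of MAD | conventional; arbitrary by its own admission |
| duration weights | 5:2 weekday:weekend | — | a week has 5 weekdays and 2 weekend days |
| age bins | [0,20), [20,40), [40,60), 60+ | years | half-open bins consistent with both printed header conventions |

## Design choices that were genuinely open

**Engagement window.** Published duplication tables of everyday domains
show near-universal sharing, which is only attainable when engagement means
"any record across the whole ~3-day recall window", not per day. The
package therefore pools all recalled days (`window = "pooled"`); a
`per_day` mode is exposed for sensitivity analysis, treating person-days as
units.

**Weighting.** The 5:2 weekday:weekend weighting applies only to duration
summaries (`weighted_daily_minutes()`); a binary indicator cannot be
day-weighted without inventing a threshold, so dichotomization is
unweighted. Persons who recalled only one day type fall back to that
type's mean.

**Deviation sign.** Methods prose in this literature is sometimes worded
"average minus observed", but every printed table and all interpretation
("more likely to engage than expected") use observed − reference; the
package uses `δ = observed − reference`, verified against the signs of the
published flagged cells.

**Diagonal.** Self-cells are undefined and excluded from column averages,
D, deviations and MAD; this is the convention that reproduces published
Average rows.

**Rounding.** All statistics are computed at full precision and rounded
only for display (half-away-from-zero, matching printed tables). The
re-keyed fixtures necessarily carry printed (already-rounded) values;
statistics recomputed from them reproduce the printed footers (D, MAD,
correlation), while individual expected-value or deviation cells can
differ from print by ±1 pp because the original authors worked on
unrounded data — tests on such cells use a ±1 pp band.

**Spearman ties.** Average ranks (the `stats::cor` default), documented
because published sources rarely state their tie handling. The published
Average and Expected rows for the sport sub-domains have identical rank
vectors, so every tie convention yields exactly 1.00 there. For the
everyday domains the published fit correlation is internally inconsistent
across its own report (0.99 in the table, 1.00 in the text, ≈0.995 when
recomputed from printed footers), so the package treats that value as
indicative only and does not benchmark against it.

**Sub-domain base.** At `level = "subdomain"` the person base is first
restricted to Exercise and Sport engagers, and penetration is relative to
that base — matching the published sub-domain tables whose prevalences sum
far above what a full-sample base would give. Composition tables report
their demographic base `n` alongside, because published base sizes can
differ between tables without explanation (2238 vs 2307 in the source
study); the discrepancy is surfaced, not hidden.

**Persons missing demographics** are kept for duplication analysis (which
needs no demographics) and dropped, with a logged count, from composition
analysis.

## The synthetic generator: what it emulates and what it does not

`synthetic_config()` defaults encode the study conditions the analysis was
built around: n = 2307 persons, the eleven everyday domains at their
observed prevalences (100, 100, 94, 93, 92, 91, 88, 87, 86, 55, 14), a
mean of 3.1 recalled days (1 + Poisson), a 5/7 weekday probability, a
44/56 gender split and 33/40/10/17 age-bin shares. Ages are drawn
uniformly within bins (16–19, 20–39, 40–59, 60–89), spanning roughly the
adult range of such convenience samples.

Engagement is independent Bernoulli per activity — the simplest structure
consistent with the Law's qualitative pattern (duplication tracking
prevalence, D → 1 as n grows). Pairwise tilts implement controlled
violations: the joint probability of a pair becomes `λ·pA·pB`, clipped to
the Fréchet bounds with a warning, realized by drawing A and then B from
its conditional distribution given A. Higher-order dependence is
intentionally unsupported. Demographic skews multiply one group's
engagement probability for one activity (clipped at 1 with a warning),
shifting that activity's engager composition in closed form.

Durations are log-normal around domain-typical medians (e.g. 480 min for
Sleep, 45 min for sport), rescaled so no person-day exceeds 1440 minutes;
they exist so the duration pathway is exercisable and carry no
calibration weight. The generator works at domain/sub-domain level — each
config label doubles as its own diary code (with a `Domain/Subdomain`
slash convention) — and does not simulate a full 520-code compendium or
time budgets that exhaust the 24-hour day across all activities.
Consequently, passing calibration tests show the *pipeline* is unbiased
under the Law's own assumptions; they cannot show that real diaries
satisfy those assumptions.

One subtlety of diary-based analysis: a person appears in a diary only if
they recorded something, so penetration from a diary is relative to
persons with any record. Under the default config the universal Sleep
domain anchors the base; configs without a universal activity should read
penetration off the cohort's engagement matrix directly.

## Numerical choices and degenerate inputs

- Activities tie-broken alphabetically when penetrations are equal, so
  table layouts are deterministic.
- Zero-engager activities are dropped with a warning naming them; a
  single-activity table, an empty record set, a sub-domain analysis with
  no sport engagers, and a rank correlation on fewer than three activities
  are errors.
- `threshold ≤ 0` is a parameter error; `near_band` may not exceed the
  threshold.
- Person-day durations are validated to sum to ≤ 1440 minutes; generated
  durations are rounded *down* to 0.1 min so rescaled days cannot creep
  back over the budget.

## Problem sizes

The test suite and calibration checks use cohorts of 40–10 000 persons and
2–11 activities. At n = 5000 with four activities, the Monte-Carlo
standard error of D is below 0.01, so the null-calibration check
(|D − 1| < 0.03, about three standard errors) is comfortably discriminating
while running in seconds; the brute-force enumeration oracles are applied
to matrices of at most 10 persons and 5 activities, where exhaustive
looping is instant.

## Known limitations

- Dichotomous engagement discards time spent; two people who run 5 and
  500 minutes a week are identical to the analysis.
- A ~3-day window under-detects rare activities' co-occurrence; duplication
  among low-prevalence activities is noisy (visible in the published
  Cultural column).
- No significance testing of deviations is provided, because the method as
  published defines practical importance by the ±5 pp convention, not by
  inference.
- The generator's independence-plus-tilts structure is not a full
  Dirichlet-type model of repertoire choice; it is a testbed, not a
  behavioural theory.
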