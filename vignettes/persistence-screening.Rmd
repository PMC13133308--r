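---
title: "Persistence-based physiologic screening for retrospective ARDS case-finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence-based physiologic screening for retrospective ARDS case-finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardsscreen)
```

## The problem

Retrospective ICU studies routinely identify acute respiratory distress
syndrome (ARDS) by the physiologic component of the Berlin definition
alone: a PaO2/FiO2 ratio (P/F) below 300 mm Hg recorded together with a
positive end-expiratory pressure (PEEP) of at least 5 cm H2O. Transient
hypoxaemia is common in critical illness, so a single qualifying
measurement captures a heterogeneous acute hypoxaemic respiratory failure
(AHRF) population in which true ARDS may be a small minority. Requiring
the criteria to persist — for 24, 48 or 72 hours of consecutive daily
windows — progressively enriches the screen-positive cohort for
adjudicated ARDS, at the cost of excluding rapidly resolving or rapidly
fatal disease. `ardsscreen` implements this screening cascade as a tested
pipeline over tabular EHR extracts, together with the two enrichment
signals most often bolted onto such screens (radiology-report keyword
rules and ICD codes) and the diagnostic-accuracy statistics needed to
evaluate all of them against expert adjudication.

## Harmonisation model

Blood-gas derived P/F values and ventilator PEEP settings arrive as
separate timestamped event streams. The package pairs them in two steps:

1. **P/F formation.** A PaO2 is matched with an FiO2 at the identical
   timestamp or within 5 minutes (the same blood-gas record); PaO2 values
   with no FiO2 in that margin are dropped (counted and warned). FiO2
   recorded on the percent scale (values in (1, 100]) is divided by 100;
   the transform is idempotent, and values above 100 are rejected rather
   than guessed at. PaO2 is assumed to be in mm Hg; kPa sources must be
   converted by the caller (multiply by 7.50062) — deliberately not
   automatic, because silent unit inference is a classic EHR failure mode.
2. **PEEP pairing.** Each P/F point takes the nearest-in-time PEEP within a
   configurable tolerance (default 2 h), ties broken toward the earlier
   PEEP so that the settled ventilator state before the gas draw wins.
   Points with no PEEP inside the tolerance are kept but marked unpaired
   and excluded from window means.

Paired points are aggregated into non-overlapping 24-hour windows anchored
at ICU admission; a stay of `L` hours has `ceiling(L / 24)` windows, the
last possibly partial. The anchor is a genuine design choice: anchoring at
first hypoxaemia would make the window grid depend on the quantity being
detected. Admission anchoring is deterministic and label-independent;
onset is then *defined* as the start of the first qualifying window. A
window's `mean_pf` is the mean over points whose paired PEEP is at least
5 cm H2O, and the window qualifies when that mean is below 300 mm Hg. A
window with no eligible point is undefined and never qualifies; setting
`carry_forward_windows = 1` optionally bridges a single empty window with
the previous mean for sparsely sampled sources.

## Persistence classes

The first unbroken run of qualifying windows is the stay's episode
("sustained" is read as consecutive: a broken run restarts the count, and
a later longer run never displaces the first). With `n` the run length:

* **H24**: `n >= 1`; **H48**: `n >= 2`; **H72**: `n >= 3`, *or* `n >= 2`
  with death on day 3 of the episode, operationalised as a death time in
  `[onset + 48 h, onset + 72 h)`. The half-open interval keeps the death
  variant disjoint from qualification by survival — a subject alive at
  `onset + 72 h` can never qualify through it.
* **ANYTIME_ONLY**: no window qualifies but at least one single paired
  measurement met the criteria. Because a qualifying window implies at
  least one qualifying measurement, the four cohorts nest monotonically —
  a property asserted on randomized fixtures in the test suite.
* Subjects dying within 48 h of onset are flagged `excluded_early_death`,
  mirroring the design exclusion applied to 72-h study cohorts.
* Durations are counted in whole 24-h windows ("48 h" means two
  consecutive qualifying windows) because the cascade is built from daily
  means; sub-daily run lengths are not defined in this model.

For subjects with several ICU stays, the stay with the earliest qualifying
onset is retained. Missed-case strata (`h0_24`, `h24_48`, `h48_72plus`)
classify each screened subject by how long their first run lasted.

Ventilation context is reported as two columns: a `vent_flag = 1` event
inside the onset window (`vent_at_onset`) and at or after onset
(`vent_after_onset`); the underlying sources rarely define these concepts
precisely, so the package states its reading rather than inheriting one.

## Enrichment signals

Keyword rules are Boolean expressions (AND/OR/NOT, parentheses) over
case-insensitive substring patterns on word stems ("opacit" hits
"opacity" and "opacities"), compiled to a stable tree that round-trips
through serialisation. Negation masking is on by default: within a
sentence (split crudely but deterministically on `.;:`), a pattern
occurrence preceded by a cue such as "no ", "without " or "resolved" does
not count. Masking can only remove positives, never create them. Rules are
applied to a stay's reports in two windows — 0–48 h from onset, or any
time during the admission — and the shipped sets T1–T6 widen strictly by
OR-ing clauses, so keyword-positive cohorts grow monotonically from T1 to
T6. The shipped rules and the ICD code-set (`J80`, `51882`, `5185`,
`J9600*`) are **illustrative defaults**, not a published instrument; both
are ordinary arguments, so a site's own lists drop in without code
changes. ICD codes are canonicalised (uppercase, dot-free) before set
membership, with trailing-`*` prefix wildcards.

## Accuracy layer

Evaluation against the three-category adjudication label (definite ARDS /
possible ARDS / non-ARDS AHRF) reduces to a 2x2 table under an explicit
positive definition. The default treats definite ARDS as positive and
*excludes* possible cases — the convention under which published coded
counts reproduce exactly — with an `as_negative` mode provided. Metrics
with a zero margin are undefined (`NA`), never zero. Binomial intervals
default to Wilson score (closed form, cross-checked in tests against an
independent score-test inversion) with Clopper–Pearson (exact Beta
quantiles) as the alternative; the exact interval is wider at both ends
and conservative in coverage, the score interval near-nominal. Cohen's
kappa uses the standard margin-product expected agreement over the three
categories. The finite-population margin of error
`z * sqrt(p(1-p)/n) * sqrt((N-n)/(N-1))` reproduces the design
calculation for reviewing a large fraction of a finite screen-positive
pool (2000 of 3940 at p = 0.5 gives about ±1.5%). Odds ratios use the
cross-product with a log-scale Wald interval and a flagged
Haldane–Anscombe correction when a cell is empty. No multiplicity
correction is applied anywhere: the outputs are descriptive accuracy
summaries, not a family of hypothesis tests.

## What the synthetic generator emulates

`default_calibration()` encodes the study conditions the pipeline is
meant to operate under:

* **Class mixture** 49.65% definite ARDS, 6.4% possible, 43.95% non-ARDS
  AHRF — the composition of a 72-h screened adjudication cohort. A
  separate `"icu"` preset adds 65% fast resolvers (transient hypoxaemia
  clearing after day 1) to emulate an unselected screen-positive ICU
  population.
* **Severity trajectories**: measurement-level P/F is log-normal around
  day-wise medians (ARDS 170/189/196 mm Hg on days 1–3; possible
  189/190/199; non-ARDS 196/205/212), with `sdlog` moment-matched to the
  corresponding interquartile ranges and a linear recovery slope after
  day 3 (8/12/15 mm Hg per day — slower recovery for ARDS, consistent
  with its slower observed resolution). Fast resolvers start at a median
  of 240 mm Hg and jump above 500 from day 2, so they reach the 24-h
  screen but (by construction) never the 72-h cohort.
* **PEEP** is charted with every blood gas and at four independent routine
  checks per day, floored at 5 cm H2O while ventilated, with class
  day-medians of 10 (ARDS) and 8 cm H2O (others).
* **Death** follows a flat per-day hazard per class (0.0268 ARDS, 0.0188
  possible, 0.0461 non-ARDS), chosen so that cumulative mortality over the
  class's median stay matches 27.8% / 21.9% / 34.6%; the within-day death
  time is uniform. The exact timing law is invented — only the daily scale
  is anchored. Length of stay is log-normal around class medians
  12.1/13.3/9.1/5 days (sdlog 0.5, capped at 28).
* **ICD assignment**: an ARDS-related code with probability 0.76 for
  definite ARDS (sensitivity), 0.53 for non-ARDS (1 − specificity 0.47),
  0.60 for possible; every stay also carries an unrelated background code.
* **Keyword emission**: each class has a non-decreasing probability vector
  across T1–T6 (ARDS reaches T3 at 0.49; non-ARDS at 0.24, i.e. T3
  specificity 0.76, spanning T1 0.43→T6 0.77 sensitivity and 0.78→0.29
  specificity). The index report is placed 6–36 h after admission and
  carries the narrowest-tier phrase its draw selects, so the nested rules
  recover the whole gradient from a single draw; 10% of keyword-negative
  reports carry a negated mention to exercise masking.
* **Reproducibility**: each subject has its own RNG stream derived from
  (seed, subject index), so growing the cohort never reshuffles existing
  subjects — asserted byte-for-byte in the tests.

What it does *not* emulate: multi-stay subjects, kPa blood gases,
missing-data structure beyond post-extubation PEEP absence, correlation
between ICD coding and severity, report language drift, or realistic
ventilation onset (every synthetic subject is ventilated from admission,
so the ventilated-at-onset fraction is 100%, higher than real cohorts).
Passing the recovery tests therefore demonstrates that the pipeline
measures what the generator encodes — not that real EHR extracts are this
clean.

## Problem sizes and numerical choices

The analysis scripts use a 2000-subject cohort (the adjudication-review
scale); parameter-recovery checks use 20,000 subjects, where binomial
standard errors on the calibrated probabilities are about half a
percentage point, and a 2000-subject review sample drawn from the
simulated 72-h cohort for the yield check. The flat death hazard starts at
admission, so classes with higher hazard lose slightly more subjects to
the 48-h design exclusion; the simulated 72-h yield therefore sits about
one percentage point above the raw class mixture — the survivorship
behaviour such screens exhibit — and the recovery test uses a
three-standard-error band around the calibrated mixture. Report-style
rounding is half-away-from-zero (`round_half_up()`), matching how clinical
tables round, not IEEE banker's rounding. Timestamps are ISO-8601 at
minute resolution; all interval arithmetic is in hours as doubles.

## Known limitations

* Sentence segmentation for negation is a three-character splitter, not a
  clinical NLP model; rule semantics are substring-level by design.
* The screen counts persistence in whole admission-anchored windows;
  criteria sustained across a window boundary but for under 24 h in each
  window can be missed — an inherent property of daily-mean cascades.
* Confidence intervals on screened-cohort yields treat the review sample
  as a simple random sample; no design-based variance beyond the
  finite-population margin helper is implemented.
* The generator's adjudication labels are latent truth by construction;
  inter-observer disagreement is modelled nowhere, so kappa utilities are
  exercised on explicit tables rather than simulated raters.
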