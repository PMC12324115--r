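---
title: "Reconstructing dialysis care trajectories from day-level event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing dialysis care trajectories from day-level event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtraj)
```

## The problem

Patients with end-stage kidney disease move between kidney replacement
therapies (KRTs): peritoneal dialysis (PD, typically a daily home
therapy), hemodialysis (HD, typically thrice-weekly in-centre sessions),
and kidney transplantation (KT).  Conventional registries record only
coarse modality changes — short transfers are often below the reporting
threshold — whereas exhaustive claims databases record every reimbursed
session, down to a single day.  `pdtraj` reconstructs the full
trajectory from such day-level streams: it assigns a raw modality to
every covered day, collapses days into episodes, classifies six states,
and summarises the cohort's pathways.

The six states are `PD`, `HD`, `MIX` (mixed dialysis: a short, unstable
alternation between PD and HD, usually driven by clinical
complications), `HYB` (hybrid dialysis: a deliberate, stable regime of
PD on most days plus one or two weekly HD sessions), `KT` and `DEATH`.
Distinguishing the two PD+HD combination regimes is the analytical core:
*mixed* is instability to be traversed, *hybrid* is a maintained
prescription.

## From events to episodes

The input is one row per event: `patient_id, day, event` with
`event ∈ {HD, PD, KT, DEATH}` and `day` an integer offset (day 0 is the
study start).  `build_daily_coverage()` turns this into per-day raw
coverage:

* an HD session covers its own day; two sessions at most
  `hd_gap_tolerance` days apart (default **7**, which spans twice- and
  thrice-weekly schedules) have the gap between them bridged as HD.  The
  tolerance after the *last* session is never appended — exposure is
  counted conservatively, and an HD episode therefore ends on its last
  session day;
* a day with both an HD session and PD coverage counts as HD, so a
  one-day transfer during PD splits the PD spell and remains visible;
* from a `KT` event until the day before the next dialysis event the
  coverage is `KT`.  The data carry no explicit graft-failure record, so
  the return of dialysis activity is used as the proxy that closes the
  transplant interval; without further dialysis the interval runs to
  death or censoring.

`segment_episodes()` is then run-length encoding over the covered days:
maximal runs of one modality become episodes with closed-interval day
arithmetic (`duration = end − start + 1`).  An uncovered day closes the
running episode; consequently two same-modality episodes may be adjacent
across a gap at the *episode* level.  The state level re-merges them
(below), so state sequences always alternate.

## The six-state rules

`classify_states()` applies, in order:

1. **Hybrid detection** (`detect_hybrid()`), on the *raw* events —
   the collapsed coverage cannot be used because HD-over-PD priority and
   gap bridging make a hybrid week look like pure HD.  Starting at an HD
   session day, consecutive `hybrid_week_len`-day windows (default
   **7**) are tiled forward while every window contains at least one HD
   session *and* one PD day; the interval ends at the last event day
   inside the tiled span and is kept if it spans at least
   `hybrid_min_days` (default **90**, "at least three months", tested
   non-strictly).  Tiling from the interval start rather than calendar
   weeks keeps the rule independent of calendar alignment.
2. **Mixed detection** (`detect_mixed()`), on episodes: a greedy scan
   accumulates runs of alternating PD/HD episodes, each strictly shorter
   than `mixed_max_days` (default **30**, "less than a month"); a run of
   at least `mixed_min_run` episodes (default **3**, i.e. at least two
   switches) becomes one MIX interval from first start to last end.  A
   KT episode, or any episode at or above the threshold, closes the run.
   A mixed run never straddles a transplant: mixed is an HD↔PD
   phenomenon.
3. **Relabeling and merging**: day precedence is `HYB > MIX` > raw
   modality.  Hybrid outranks mixed deliberately — a stable alternation
   must not be consumed as instability.  Episode fragments not covered
   by an overlay survive as their raw state when at least one day
   remains.  Adjacent intervals with identical states are merged,
   bridging uncovered gap days inside the stretch.  A death appends a
   one-day `DEATH` interval; the preceding interval is clipped to end
   the day before.

A patient's last interval is flagged `censored` exactly when the patient
has no death event — they were still under observation when the window
closed.  (A "reaches the censoring day" rule would misclassify HD
spells, which end at their last session a few days short of the
censoring day.)

All thresholds live in `analysis_config()` and are deliberately
calendar-free: "a month" is 30 days, "three months" 90 days, "a week" a
7-day tiled window.

## Trajectory summaries

* `extract_transitions()` — every adjacent state pair; `DEATH` only ever
  a destination.
* `first_transition_group()` — the four major first transitions
  (`PD→HD`, `PD→DEATH`, `HD→PD`, `PD→KT`) plus `other`/`none`; a
  partition of the cohort.
* `pattern_table()` — patients grouped by their first 2 or 3 states with
  median durations of the first and second intervals.  Medians use
  **completed spells only**: a censored spell has an unknown true
  length, though censored patients still count toward pattern
  membership.
* `modality_count_distribution()` — the number of KRTs per patient,
  counting repeats and counting MIX and HYB each as a modality in its
  own right; histogram capped at 10.
* `point_prevalence()` — alive / on dialysis / on PD at a day `t`, with
  the nesting `on_pd ≤ on_dialysis ≤ alive` guaranteed by construction.
* `compare_transition_definitions()` — registry emulation: for each
  minimum-duration threshold (defaults 30/60/90/180 days), every
  non-terminal interval shorter than the threshold is absorbed into its
  neighbours (merged when both sides match, else into the preceding
  state, mirroring a registry that never saw the short spell) and
  transitions are recounted.  Counts are monotone non-increasing in the
  threshold.
* `build_sankey()` — the step-indexed alluvial graph of the first
  `sankey_max_states` states (default **4**).  Time is not represented.
  Each node stores a `terminal_remainder` — patients with no outgoing
  link (still on the technique, dead, or truncated at the depth
  limit) — rather than a phantom sink node, because renderers handle
  missing outflow natively and the remainder has a direct reading:
  flow conservation `count = outflow + remainder` holds at every node.

Medians and quartiles use one fixed convention (`traj_quantile()`): the
inverse empirical CDF with averaging at jumps (the median of an even
sample is the midpoint of the central pair), so test oracles can match
exactly.

## The synthetic cohort

The source data class this package targets — a national registry linked
to a claims database — is access-restricted, so the package ships a
simulator that emulates its day-level streams.  `generate_cohort()`
draws each patient from a named *archetype*: an ordered list of spells
with lognormal (median-parameterised, geometric SD 2.0 — waiting times
are right-skewed and only medians/IQRs are published) or fixed
durations, plus a terminal event.  The default archetypes mirror the
most frequent published trajectory patterns with their pattern medians
as defaults (e.g. 394 d of PD before a definitive HD transfer, a 9-day
HD interruption in PD–HD–PD, a 33-day mixed spell resolving to 339 d of
PD, 522 d of PD before transplantation); unpublished third-spell
medians default to 365 d.  The default mix weights twelve archetypes by
their published pattern frequencies.

Emission rules: PD spells emit one coverage event per day (the
simulator assumes daily PD reimbursement coding; lump-sum coding
variants are not emulated), HD spells emit
`hd_sessions_per_week` sessions on a fixed days-1/3/5 weekly pattern
(fixed rather than random so gap-tolerance behaviour is reproducible),
`MIXBLOCK` expands into ≥ 3 alternating short sub-spells, `HYBBLOCK`
emits daily PD plus one weekly HD session, and the observation window
(default **4383 d**, a 12-year registry horizon) truncates and flags
whatever it cuts.

Three consistency floors keep the emitted truth labels valid
descriptions of the realized stream — without them the generator would
mislabel its own output:

* spells bordering a `MIXBLOCK` are floored at `mixed_max_days` (HD
  spells at `mixed_max_days + 7`, since an HD episode ends at its last
  session and can sit up to a week short of its spell), so a stable
  neighbouring spell can never be drawn short enough to be absorbed
  into the mixed run;
* mixed sub-spells are floored at `hd_gap_tolerance + 1` days: a faster
  alternation is *unobservable*, because session bridging swallows the
  intervening PD days — a fact about the measurement process the
  simulator must respect, not a classifier defect;
* `HYBBLOCK` durations are floored at `hybrid_min_days`.

These floors sit far below every shipped median, so configured medians
are preserved (verified in the tests at n = 1000 within 15 %).  Truth
labels are emitted by the generator from its own structure and never
re-derived by the classifier, keeping recovery tests circularity-free.
A truncated mixed block that loses sub-spells below the minimum run
degrades its truth to the raw labels, since the mixed regime no longer
exists in the emitted stream.

What the simulator does **not** emulate: covariates (age, diabetes,
emergency start — out of scope), coding errors beyond an optional
uniform event-dropout rate, staggered entry (all patients enter at
day 1; the observation window does the censoring work), lump-sum PD
reimbursement coding, and any correlation between archetype and
duration beyond the archetype's own medians.  Passing recovery tests
on these cohorts therefore shows the *rules* are implemented correctly
and invertible on clean streams; it does not validate the rules against
messy real-world coding.

## Problem sizes and verification

The test suite checks episode segmentation against an independent
day-scan/run-length oracle on 500 randomized streams of up to 120 days,
classifies a 1,000-patient cohort drawn from the twelve-archetype mix
and requires at least 99 % exact state-sequence recovery (mismatches
must be window-truncation-flagged), verifies the configured duration
medians on dedicated 1,000-patient single-archetype cohorts, and checks
the conservation laws (Sankey flow, first-transition partition,
prevalence nesting, transition-count conservation, registry
monotonicity) plus byte-identical reruns under fixed seeds.  These
sizes keep the full suite in the low minutes on one CPU while holding
median sampling error near 3 %.

## Known limitations

* The transplant-interval end is a proxy (next dialysis event); real
  graft-failure dates are not in the event stream.  The gap tolerance
  and all rule thresholds are first-class parameters precisely because
  the underlying coding conventions vary between claims systems.
* Whether the original hybrid rule used calendar weeks, and whether a
  mixed run may straddle a brief transplant, is not determined by the
  published definitions; this package fixes tiled windows and
  no-straddling, and exposes the thresholds.
* Pattern-table medians exclude censored spells; published
  pattern tables do not always state their convention, so small
  systematic differences against any particular publication are
  expected.
* Cohort-level headline shares depend on the archetype mix; the shipped
  mix covers only the twelve most frequent published patterns, so rare
  pathways are absent by construction.
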