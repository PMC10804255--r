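---
title: "Deriving and applying an interval-floor rule for recurrent suicide-attempt codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying an interval-floor rule for recurrent suicide-attempt codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadedup)
library(dplyr)
```

## The model

Suicide risk prediction models trained on EHR data usually define their
outcome by suicide-attempt ICD codes. A single attempt, however, commonly
produces many such codes across the encounters it triggers — the ED
presentation, each day of an inpatient stay, outpatient follow-up. Treating
every recurrent code as a new outcome while earlier codes of the same event
serve as predictors leaks the outcome into the feature set.

The quantity this package is built around is a positive predictive value
defined on *code pairs*. After collapsing a patient's coded encounters to
day level, each coded day is paired with the immediately preceding coded
day; the pair's PPV is the probability that its second code marks an
attempt distinct from the event indexed by the first:

$$\widehat{\mathrm{PPV}} = k/n, \qquad
\mathrm{CI}_{95} = \hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n},$$

with $k$ the number of pairs labeled distinct among $n$. Pairs are treated
as independent observations — deliberately ignoring their nesting within
patients — because that mirrors how a prediction pipeline would consume the
codes. The Wald interval is **not clipped** to $[0,1]$: near-degenerate
strata (e.g. 22 distinct of 23 pairs) legitimately report an upper bound
above 1, and reproducing the reference tables pins the method down to
exactly this unclipped normal approximation with $z = 1.96$. Display
rounding is half-away-from-zero (`round_half_up()`), the convention the
reference tables use; base R's round-half-even cannot reproduce them.

An *interval-floor curve* evaluates, for each floor $d \ge 1$ days, the PPV
over pairs with intercode interval $\ge d$. `derive_rule()` picks, per
stratum, the smallest $d$ whose PPV reaches a benchmark (default 0.90). The
operational rule combines the two most reliable signals — clinical setting
and elapsed time, both robust to idiosyncratic coding practices: *a code
documented in an ED at least `ed_floor_days` after the preceding code is a
new event*. Method concordance is computed and reported but contributes no
floor to the default rule; in practice disagreeing methods mostly reflect
codes that simply omit the method (`other`), not genuinely different
attempts.

## Case-definition details

ICD-9 codes match on the prefixes E95, 965, 967, 969, 881. ICD-10-CM codes
match on X71–X83, T14.91, or T36–T65 with intent character `2`. All
character positions are counted in the normalized, period-free string. For
most T-family stems the intent character is the 6th character
(`T43.012A` → `T43012A`); for stems whose family has no fourth subdigit
(T36.9, T37.9, T39.9, T41.4, T42.7, T43.9, T45.9, T47.9, T49.9, and the
T51–T65 analogues, e.g. T58.0, T61.1, T64.8) it is the 5th
(`T42.72XA` → `T4272XA`). Where the stated stem lists could be tokenized in
more than one way, we resolve them with this period-free counting
convention and document it rather than guessing any other tokenization;
codes too short to reach the required position never match (no padding).

The code→method mapping is not part of the printed case definition, so the
package ships an editable two-column prefix table
(`inst/extdata/method_map.csv`): T36–T65 and ICD-9 965/967/969/E950–E952 →
poisoning; X78/X79, 881, E956 → cutting/piercing; E953 →
hanging/strangulation/suffocation; X80/X81, E957 → jumping; X72–X74, E955 →
firearm; everything else (including T14.91 and X71 drowning) → other.
Longest prefix wins; any matched code with no entry falls back to `other`.

## Day-level aggregation and pairing

The exact same-day combination rules used during the original chart review
are not public, so the package's collapse rules are its own documented
choices:

* a day with **any** ED encounter is an ED day — the ED visit is the
  clinically salient presentation, and this errs on the side of evaluating
  the (stricter) ED branch of the rule;
* a day's method set is the **union** of its encounters' categories, and
  two days share a method iff their sets intersect — one shared specific
  method is stronger evidence of a shared event than disjoint sets;
* intervals are whole calendar-day differences, timezone-free, so every
  pair has interval ≥ 1.

For cross-tabulations that need one category per day, a multi-method day is
assigned its highest-priority category in the order poisoning, cutting or
piercing, hanging/strangulation/suffocation, jumping, firearm, other — a
deterministic tie-break that prefers specific methods over unspecified
ones.

The narrow sampling frame selects patients with at least one pair 1–90 days
apart (a window enriched for leaked codes); the broad frame requires only
≥ 1 day. In both, *all* pairs of a selected patient enter the analysis,
including >90-day pairs of narrow-frame patients.

## Applying a rule

`apply_rule()` measures each day's interval to the **immediately preceding
coded day**, leaked or not, because that is how the pairs behind the
derivation are constructed; a `since_last_event` mode (interval to the last
accepted event) is available but non-default. The first coded day of a
record has no preceding code for the rule to test, so its treatment is
explicit configuration: `first_code_is_event` (default — risk models need
an index attempt) or `first_code_ignored`. The shipped default rule is a
5-day ED floor with no global floor; a permissive preset
(`sa_rule(5, 53)`) additionally accepts any code 53 days after its
predecessor. By default the derived floor is the *smallest* qualifying one
even if the curve later dips below the benchmark (curves based on few pairs
fluctuate); `strict = TRUE` requires the benchmark at every larger floor.

## What the synthetic generator emulates

`simulate_cohort()` draws, per patient, 1 + geometric(0.30) true attempts
separated by shifted-lognormal gaps (median ≈ 52 days, heavy right tail).
Each attempt triggers a cascade: an index presentation (ED with
probability 0.80), possible admission (0.30 after ED; direct inpatient
presentations always) with geometric length of stay and daily
inpatient/ICU coding, a possible repeat ED visit for the same event when
not admitted (probability 0.60, offset 1 + geometric(0.55) days), and
Poisson(0.20) follow-up codes in mostly non-ED settings. No leaked code is
emitted more than `leak_horizon = 21` days after the event's index code.
Codes are drawn from per-version, per-method pools that all pass the case
definition; post-index ICD-10 codes flip their extension character to "D"
with probability 0.5; 12% of patients are ICD-9-era.

The repeat-ED-visit component deserves a note: without it, nearly all
second-code-ED pairs are true new events and the ED/ED stratum collapses.
Real cohorts contain many short-interval nonindependent ED/ED pairs
(same-event re-presentations), which is exactly what makes a nonzero ED
floor necessary; this component is their source in the simulation.

With the default configuration and 2000 patients, generated cohorts show
≈ 83–85% nonindependent pairs, a median intercode interval of 1 day,
roughly half of pairs non-ED/non-ED and a quarter ED/ED, and a derived ED
floor of 5 days at PPV ≈ 0.93–0.94 — chosen once, by simulation across
seeds, to sit inside realistic bands for these descriptives, and not
revisited.

What the generator does **not** emulate: care sought outside the observed
system (truncated cascades), calendar-driven ICD-9→ICD-10 transitions,
coding-practice drift, within-patient correlation of presentation styles,
and long-horizon leakage — real records occasionally attach a code to an
event months later, which is one reason an all-settings floor derived from
these simulations (≈ 7–9 days) is far smaller than the ≈ 53 days reported
from chart-reviewed registry data. Passing tests on simulated cohorts
therefore demonstrate that the pipeline recovers the structure it is given
(floors below the leakage horizon at the benchmark PPV, high precision of
the derived rule against ground truth), not that any particular floor value
transfers to a given health system; the rule should be re-derived locally
with `derive_rule()` where labeled data exist.

## Numerical and design choices

* Floors are evaluated on the integer grid 1..max(interval); counts at
  floor $d$ come from reverse cumulative sums, so curves are exact, not
  binned.
* $n = 0$ strata report `NA` estimates with a warning — never a fabricated
  0 — and appear in tables with their zero counts.
* Degenerate proportions ($k \in \{0, n\}$) keep their zero-width Wald
  intervals; no continuity correction is applied, matching the reference
  computation.
* `aggregate_days()` is idempotent, and `apply_rule()` rejects unsorted or
  duplicated patient-days rather than silently reordering.
* All randomness flows from a single integer seed
  (`simulate_cohort(cfg, seed = )`), leaving the session RNG untouched.

## Problem sizes

The test suite and the reproduction script use 2000-patient simulated
cohorts (≈ 5500 narrow-frame pairs) for stochastic checks — large enough
that the derived ED floor is stable across seeds — plus 1000 random small
patients for the brute-force pairing oracle and constructed fixtures with
known thresholds for exact floor recovery.

## Limitations

The package deduplicates *codes into events*; it does not attempt fuzzy
episode merging, probabilistic event assignment, or sub-day visit logic,
and it inherits the case definition's validation context (codes, not
narrative notes). Settings must be mappable to the five canonical
categories; encounters whose setting cannot be mapped are rejected or
skipped explicitly. PPV inference ignores within-patient clustering by
design, so confidence intervals describe the pair population as a
prediction pipeline sees it, not patient-level uncertainty.
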