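---
title: "Microanalysis of caregiver–infant dyadic interactions with dyadkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microanalysis of caregiver-infant dyadic interactions with dyadkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkit)
```

## The problem

In many primates, including the common marmoset, infant care is shared among
family members, and each caregiver brings an individual "parenting style" to
the interaction: how quickly they respond to a separated, calling infant
(*sensitivity*), how much they resist the infant riding on their body
(*tolerance*, whose negative expression is rejection — rolling, pushing,
biting), and how much carrying they provide overall (*care quantity*). The
infant, in turn, tunes its attachment behavior — clinging, staying mounted,
and vocal signaling — to the style of the specific caregiver it is with.

dyadkit analyzes the standard assay for these questions: a brief
separation–reunion ("retrieval") test in the home cage. The caregiver and the
basket-confined infant are joined by opening a shutter; the moment all four
infant limbs contact the caregiver's body is *retrieval*, and the session
continues for a fixed nominal duration (600 s, or 300 s in some designs)
after the first retrieval, or from assay start when no retrieval occurs.
Behavior is manually coded in 0.2-s bins; calls are annotated with onset,
offset, caller and type (phee, twitter, tsik, trill, cry/"ngä", and others).

## Social-context segmentation

Every session window is partitioned into five mutually exclusive,
collectively exhaustive contexts:

* `Alone_BeforeRET` — before the first retrieval;
* `Holding` — carried without caregiver locomotion;
* `Transport` — carried while the caregiver locomotes;
* `During_Rejection` — from the onset of a rejection bout to 9.4 s after its
  end (overlapping extents merged);
* `Alone_AfterRET` — all remaining uncarried time after the first retrieval.

The 9.4-s offset exists to capture infant behavior still under the influence
of the preceding rejection, so `During_Rejection` takes precedence over the
carried and alone states; in particular, if the infant is dismounted inside
the offset, that time remains `During_Rejection` rather than
`Alone_AfterRET`. Times are stored as continuous seconds with half-open
intervals `[onset, offset)`, but ingestion snaps every time to the 0.2-s
coding grid (round-half-even to one decimal, then to the nearest bin
multiple), and segmentation runs on integer bin indices. The partition is
therefore exact: segments tile the window with zero gaps and overlaps by
construction, which the test suite verifies on 1,000 randomized simulated
sessions. We treat the offset interval as half-open, `[r_start,
r_end + 9.4)`; whether the original coding convention closed the right
endpoint is unknowable from the outside, and at 0.2-s resolution the choice
moves one bin at most.

## Forced vs voluntary dismounts

Not every dismount means the same thing: an infant may be thrown off by a
rejection, or may leave on its own (an avoidant, attachment-relevant act).
The empirical separation comes from the distribution of
rejection-to-dismount intervals. For every dismount, `extract_intervals()`
measures the time since the end of the most recent preceding rejection in
the same session (a dismount with no preceding rejection has no interval).
`log_survivorship()` computes the empirical survivor function
S(t) = P(T ≥ t) of those intervals, and `fit_breakpoint()` fits a
continuity-constrained two-segment line to (t, ln S) by profiled least
squares: every observed t with at least three points on each side is a
candidate breakpoint, the hinge model `y ~ t + max(t − c, 0)` is fitted by
OLS for each, and the minimal total SSE wins, ties resolved toward the
smaller breakpoint. A fit is flagged *degenerate* when two segments improve
on a single line by less than 1% of SSE. On data of this design the
breakpoint falls near 9.4 s: dismounts with intervals up to that threshold
are classified *forced*, dismounts with longer intervals — or none — are
*voluntary*.

Three conventions are deliberate and exposed as arguments:

* an interval exactly at the threshold is **forced** (`inclusive = TRUE`),
  consistent with the context offset spanning up to 9.4 s after the
  rejection end; a strict-inequality variant is one flag away;
* the threshold used downstream is the grid-rounded 9.4 s; the fitted
  breakpoint is retained for re-estimation on new datasets rather than
  substituted automatically;
* the interval attaches to the most recent rejection even across a
  re-retrieval within the same session (never across sessions). Carrying
  episodes in this assay are separated by seconds-to-minutes; an interval
  spanning a re-retrieval is long and classifies as voluntary either way,
  and the simpler rule has no hidden episode-bookkeeping.

The survivor convention is S(t) = P(T ≥ t), i.e. S at the smallest observed
interval is 1; duplicated interval values collapse to the smallest survivor
proportion at that value.

## Caregiver parameters and infant metrics

Per session, `parenting_params()` computes:

* `RET_Latency` — time to first retrieval; censored at the window length
  when no retrieval occurred. Censored latencies carry a flag: they may
  enter rank-based statistics but are excluded from dyad means.
* `%Carry` — carried duration as a percentage of the session window.
* `%Rejection` — rejection-bout duration as a percentage of carried time.
  The denominator is a design choice (the assay-specific definition is not
  public); we default to carried time, matching the family-reunion
  definition (rejecting bins / carrying bins), and expose a per-window
  alternative. `%Rejection` is undefined (NA) in sessions with no carrying.

`infant_metrics()` computes the infant side: `avoidance_count` is the sum
of voluntary dismounts and *cling refusals* — a caregiver contact bout of
at least 1.0 s containing no infant cling onset (an explicit refusal code,
when present, is trusted instead). The 1.0-s minimum makes the measure
robust to fleeting touches that afford no cling opportunity.
Calls-while-carried counts infant calls with onset in `Holding` or
`Transport`; `During_Rejection` is its own reporting category since the
contexts are exclusive. Call frequencies are per minute of context time and
are undefined — NA, never zero — for contexts of zero duration. Per-context
call-type proportions use six categories (phee, twitter, tsik, trill, cry,
other). Avoidance before PND 28 (postnatal weeks 0–3) is flagged
`premature`, the age below which voluntary dismounting is normally rare.

Dyad-level aggregation (`summarize_dyads()`) averages sessions within a
caregiver–infant pair; the DI_SC/SI_DC comparison (`dyad_distance_pairs()`)
min–max-normalizes the two attachment metrics over dyads and compares
segment lengths between the two littermate dyads of one caregiver (DI_SC)
against those of one infant with two caregivers (SI_DC) by rank-sum test. A
smaller DI_SC indicates the caregiver, not the infant, sets the interaction
pattern.

Family-reunion sessions are coded with one-zero sampling in 10-s bins
(`one_zero_aggregate()`): a bin scores 1 if the behavior overlaps it at
all. Carrier-to-carrier transfers classify as *direct* (adjacent bins) or
*nondirect* (at least one not-carried bin intervening) via
`classify_transfers()`.

## Statistics

The package's inferential toolkit is intentionally small and exactly
testable:

* `wilcoxon_signed_rank()` and `wilcoxon_rank_sum()` compute exact
  enumeration p-values for small samples (signed-rank up to n = 25 via a
  convolution over mid-ranks, which remains valid under ties; rank-sum up
  to min(n) = 8 without ties) and tie-corrected normal approximations with
  0.5 continuity correction beyond. Two-sided p-values are twice the
  smaller tail, capped at 1. Both match `stats::wilcox.test` where the
  latter is exact, and brute-force enumeration everywhere the suite checks.
* `correlation_matrix()` computes Spearman (product–moment correlation of
  mid-ranks) or Pearson matrices with pairwise-complete observations and
  Holm or Benjamini–Hochberg adjustment via `stats::p.adjust`. Which
  adjustment a given analysis used is a per-figure choice in this
  literature; both are provided and tagged in the output.
* `cohen_kappa()` is the closed-form chance-corrected agreement.
* `permutation_group_compare()` replaces mixed-model group contrasts:
  group labels are permuted at the dyad (cluster) level so repeated
  sessions of one dyad move together, preserving the pseudoreplication
  control that random effects provide, with the add-one p-value
  (1 + #{|T*| ≥ |T|}) / (1 + n_perm). GLMMs with AIC-based model selection
  are deliberately out of scope: `attachment_model_matrix()` exports a tidy
  model frame so any mixed-model tool can refit.

## The session simulator

`simulate_session()` / `simulate_cohort()` generate pipeline-ready sessions
from latent caregiver styles (sensitivity, tolerance, carry motivation —
constant across an individual's sessions) and infant states (avoidance
baseline, anxiety gain, rearing condition). The generative structure:

* retrieval latency ~ Exponential(0.02 · sensitivity) per second, censored
  at the nominal duration (the most sensitive caregivers retrieve in tens
  of seconds; a few percent of sessions end unretrieved, as in real
  cohorts);
* carrying alternates Holding/Transport dwells (means 20 s and 6 s);
* rejection bouts (mean 1.6 s) arrive during carrying with hazard
  0.010 · (1 − tolerance) per second; each forces a dismount with
  probability 0.62 after a truncated-exponential delay on (0, 9.4];
* voluntary dismounts arrive at 0.0009 · (1 + 6 · avoidance) per second;
* after a dismount, re-retrieval arrives at a rate scaled by sensitivity
  and carry motivation; caregiver contact bouts while the infant is alone
  are cling opportunities refused with probability equal to the infant's
  avoidance;
* infant calls are a marked Poisson process: high rates alone
  (18/min before retrieval, 10/min after), low while carried (1.5/min),
  intermediate during rejection; type mixes are twitter/phee-weighted
  before retrieval, trill-dominant while carried, tsik-dominant during
  rejection, cry-weighted alone after retrieval. An anxiety stream adds
  tsik/cry calls while carried at 8 · anxiety_gain · (1 − tolerance) per
  minute, so intolerant carriers elicit more, and more negative, carried
  calls.

All defaults live in `inst/extdata/sim-defaults.yaml` and are overridable
through `sim_config()`. The true parametric forms of these laws are unknown;
exponential hazards are the standard minimal assumption for bout-structured
behavior, and every rate is swappable via config. Two calibrations are
deliberate: the voluntary hazard is set so roughly one third of dismounts
are voluntary (matching the observed overall share), and the forced-delay
mean is 4.5 s — spreading forced mass across most of the (0, 9.4] support —
so that the log-survivorship of the generated intervals has a crisp corner
at the support boundary and the two-phase structure is genuinely present,
not an artifact of the fitted model. The artificial-rearing condition
raises the avoidance baseline, multiplies alone-context call rates
(increasingly past PND 30), and lowers direct-transfer propensity after
PND 12.

The simulator reproduces the qualitative structure of real sessions, not
their full richness: no acoustic content, no holding-site/body-position
coding, no breastfeeding or object-play behaviors, no developmental drift
within a caregiver's style, and independence between sessions given the
latent parameters. Passing recovery tests therefore demonstrates that the
pipeline measures what the generator encodes — not that real data satisfy
the generator's assumptions.

## Study sizes and reproducibility

All randomness descends from one master seed through per-session counter
substreams, so any cohort is reproducible piecewise. The packaged
acceptance study (`run_acceptance_suite()`, `scripts/acceptance.R`) uses:
200 replicates of n = 130 intervals for breakpoint recovery (±2 s
tolerance); 1,000 randomized sessions for the partition invariant with
offset monotonicity spot-checked on 100; a 60-dyad cohort (15 families × 2
caregivers × 2 littermates, three sessions per dyad) for the
association-sign pattern among `%Carry`, `RET_Latency` and `%Rejection` and
for the tolerance median-split contrasts (30 dyads per side); a 40-infant
cohort (20 families, one artificially reared infant each, sessions through
PND 35) for the Art/Cont contrasts; 40 random small instances per Wilcoxon
routine against brute-force enumeration; and 1,000 null replicates for
empirical type-I error, using 14 pairs for the exact signed-rank test
(where its attainable two-sided level, 0.0494, is closest to the nominal
5%) and 10 clusters of 3 for the permutation test (where the add-one
p-value is exactly calibrated).

## Known limitations

* The behavior-code vocabulary is open by design (unknown codes warn, not
  fail); only the core codes drive the analysis.
* The breakpoint estimator searches observed interval values; it cannot
  return a change point between observations, which at 0.2-s binning is
  immaterial.
* `%Rejection` depends on the denominator convention; comparisons across
  datasets should fix it explicitly.
* The isolation-recording assay is ingested but analyzed only as a single
  implicit context; the developmental call-type shift under isolation has a
  rate-trend hook in the simulator but no dedicated analysis.
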