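---
title: "Methods: behavioural state-sequence analysis of object play"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural state-sequence analysis of object play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playseq)
```

## The problem

`playseq` analyses how juvenile pigs play with a familiar object (two tug
toy ropes) in their home pen. Four littermates are observed together for 30
minutes; every 5 seconds each pig's state is scored instantaneously for
object play and no-play, and locomotor and social play are recorded
one-zero within the interval. After merging rare states, each pig
contributes a categorical sequence of length 360 over the alphabet

* `NoP` — no play,
* `ObjP` — object play, with or without simultaneous locomotor/social
  elements,
* `LocSocP` — locomotor and/or social play without the object.

The questions the pipeline addresses: do individual pigs follow a small
number of distinct play patterns; are those patterns group-driven; can
individuals be typed as initiators or joiners of object play; and is play
synchronised within a group beyond chance?

## Sequence construction

`build_state_sequence()` merges the two scoring channels with the priority
`ObjP > LocSocP > NoP`: an instantaneous object-play state wins over any
simultaneous flags (object-play combinations remain object play), and the
one-zero flags alone give `LocSocP`. Intervals without a record are
missing (`NA`). In a full design, 60 pigs x 360 intervals = 21,600 records;
the default generator drops records at rate 295/21600 to emulate realistic
scoring gaps. Missing data are handled by least assumption throughout:
transition pairs that span a missing interval are skipped, the complexity
measures use observed positions only, and optimal matching drops missing
positions before alignment (the indel operations absorb the resulting
length differences). Nothing is imputed.

## Complexity measures

Three per-sequence measures quantify how varied a pig's play is.

*Longitudinal entropy* is the Shannon entropy of the within-sequence state
distribution normalised by `log(3)`, so 0 means a constant sequence and 1
an even split over the three states. Natural logarithms are used for the
entropy itself.

*Turbulence* is `log2(phi(x) * (s2_max + 1) / (s2 + 1))`, where `phi(x)`
counts the distinct subsequences of the sequence of spell states
(`count_distinct_subsequences()`, by the recurrence
`phi_t = 2 phi_{t-1} - phi_{k-1}` with `k` the previous occurrence of the
same symbol) and `s2` is the variance of spell durations. The *population*
variance (divide by the number of spells) is used so that the bound
`s2_max = (n - 1)(1 - tbar)^2` is exactly attainable and a single-spell
sequence has turbulence exactly 1. The subsequence count is exact up to
2^53 (integer arithmetic in doubles); beyond that the relative error of
the count, and hence the absolute error of its base-2 logarithm, is
negligible for any sequence of length 360.

*Complexity index* is `sqrt(q/(l - 1) * h)`: the geometric mean of the
normalised number of state changes and the normalised entropy, in [0, 1].

## Optimal matching and clustering

Pairwise dissimilarity between sequences uses optimal matching: the
minimal cost of turning one sequence into the other with insertions and
deletions at cost 1 and substitutions at cost
`SC(i, j) = 2 - p(j|i) - p(i|j)` derived from the observed lag-1
transition rates — states that frequently follow one another are cheap to
exchange. Rates are pooled over all 60 sequences (per-stratum pooling is
available but the pooled matrix is the default; with equal-length
sequences no length normalisation is needed). The dynamic programme is
implemented in C++ (`src/om.cpp`); the 1,770 pairwise alignments of
360-step sequences take about a second.

The distance matrix is clustered by Ward's method in the Ward.D2
convention (Lance–Williams updates on squared dissimilarities, monotone
merge heights); the classic Ward.D variant is available by flag since
either reading of "Ward's method" is defensible. The number of clusters is
selected over k = 2..8 by average silhouette width, with Hubert's C index
reported alongside; when the two criteria disagree both candidate k are
returned and the silhouette choice wins. Silhouette was made primary
because it is an absolute per-animal quality measure with a fixed [-1, 1]
scale, whereas C compares a sum against its combinatorial extremes and is
near 0 for every reasonable cut of well-separated data, making it the
weaker arbiter (both criteria are still computed and reported).

## Player typing

Each object-play onset is scored as an *initiation* (first pig to touch a
toy) or a *join* (another pig already playing). Each object-play interval
is scored *alone* or *together*. A pig is an initiator if a two-sided 90%
confidence interval for its initiation share lies entirely above 0.5, a
joiner if entirely below, otherwise mixed; solitary/social is classified
the same way from the share of object-play intervals spent alone. The
exact Clopper–Pearson interval is the default — event counts per pig are
small (tens), where Wald intervals undercover; Wilson and Wald are
available by flag. The initiator/joiner axis uses onset events as the
denominator and the solitary/social axis uses interval counts, reading
"proportion of time" as scored intervals.

Association between the two classifications is summarised by Kendall's
tau-b on the 3x3 contingency table, with the asymptotic standard error
under the alternative (the form mainstream statistical packages print).
The sign of tau-b flips when either category order is reversed; this
package fixes rows initiator < mixed < joiner and columns solitary <
mixed < social, under which the reference 60-pig cross-classification gives tau-b =
+0.614 — the magnitude is what is compared. Fisher's exact test for r x c
tables is exact for small tables and Monte-Carlo (with stated replicate
count and seed) for large ones.

## Transition-rate comparison and bout models

Lag-1 transition matrices are computed per pig, group, sex and player
type. For each off-diagonal transition, a 2x2xK Cochran–Mantel–Haenszel
test (transitioned vs not, initiator vs joiner, stratified by the 15
groups; hypergeometric variances, no continuity correction) asks whether
the transition probability differs between player types; Bonferroni
correction uses the number of off-diagonal transitions tested (6). Strata
with a zero margin carry no information and are skipped with a warning.

Object-play bout durations (maximal runs of `ObjP`, in intervals) are
modelled by fixed-effects Poisson regression with group, treatment, sex
and player type as class effects and the bout's start time as covariate.
Time is measured in seconds from test start (start index x 5). Random
effects are not used: with 15 groups already entering as a fixed class
effect the fixed-effects model is identifiable and simpler. Complexity
traits are analysed by a general linear model with the same class effects
plus birth weight and 9-week weight as covariates; marginal (Type-III)
F-tests with sum-to-zero contrasts are reported, and the player-type
factor enters one axis at a time (initiator/joiner/mixed or
solitary/social/mixed).

## Synchrony

Per interval, `simultaneity_counts()` counts how many of the four pigs are
in the target state, and `count_transitions()` gives the 5x5 transition
matrix of that count. Two null models are shipped side by side, because
"expected by chance" is genuinely ambiguous:

* an analytic independence model (`expected_simultaneity()`): the
  Poisson-binomial tail probability that at least k pigs play at once
  given each pig's marginal play probability;
* a cyclic-shift permutation test (`cyclic_shift_null()`): every pig's
  sequence is rotated by an independent uniform offset, which preserves
  each pig's marginal distribution *and* autocorrelation exactly while
  destroying cross-pig alignment. The one-sided p-value is
  `(1 + #{null >= observed})/(1 + n_perm)`, and the observed share is
  accompanied by a Wilson 95% interval.

One operating characteristic deserves emphasis. At a dense play marginal
(about 0.38 per pig), the share of intervals with *at least two* players
is higher under independence (0.49) than under perfect synchrony (0.38):
synchrony concentrates co-play into fewer intervals. The pair statistic
therefore has no power against coupling in dense regimes, and synchrony
tests on such data should target trios (`k = 3`) — the order at which
group play exceeds chance in this paradigm — or be run at sparse
marginals. The calibration suite does the former.

## The synthetic generator

Raw observations from the original experiment are not redistributable, so
`generate_dataset()` simulates the full design with planted ground truth;
it is first-class, tested code, and every pipeline stage is exercised on
its output.

Each group draws a play *archetype* governing its pigs' object-play entry
and persistence probabilities over time:

* **A** — plays intensely for the first 10 minutes (120 intervals), then
  stops;
* **B** — sustained play throughout;
* **C** — intermittent moderate play, alternating 5-minute play and rest
  blocks anchored to test start.

Groups are allocated to archetypes deterministically in proportion to the
mixture weights (default 0.3/0.3/0.4) in seed-shuffled order, so every
archetype is represented. The shared block template of archetype C is a
deliberate design choice: an "intermittent" class whose pigs drift out of
phase has no within-class cohesion under optimal matching (its
within-class distances equal its distances to the other classes), so
phase-free intermittency is unrecoverable *in principle*; the template
makes C a coherent planted pattern while remaining intermittent in
profile. Defaults were calibrated once, by simulation, so that pooled
state marginals average about 49% `ObjP`, 5% `LocSocP` and 46% `NoP`
across seeds — the long-run shares this paradigm produces — and are not
revisited.

Pigs are coupled: the log-odds of *entering* object play rise by `gamma`
(default 0.8) per penmate currently playing. Coupling acts on object-play
entry only; `LocSocP` is generated at a low rate independent of the toy,
reflecting that locomotor/social play is not driven by the play object.
Each pig also carries a planted player type. Types modulate the
willingness to start playing alone and bout persistence
(initiators up, joiners down), and set `pi_init`: when a pig starts
playing while a penmate is already playing, the onset is an initiation (on
the free toy) with probability `pi_init`, otherwise a join; an onset with
no playing penmate is necessarily an initiation. A pig plays "alone" in an
interval when no penmate plays in it. Toys are chosen at bout onset
(preferred toy with probability 0.7) and kept for the bout. Latency to
approach the toy is drawn lognormal with type-dependent location
(initiators quickest).

Three presets fix study conditions:

* `preset_study()` — 15 groups x 4 pigs x 360 intervals, missingness
  295/21600, the archetype mixture above;
* `preset_strong_types()` — one homogeneous high-turnover archetype,
  `pi_init` 0.9/0.1, strong coupling, so every pig accumulates well over
  20 onsets and most onsets are informative about type;
* `preset_sync_null(gamma)` — one time-homogeneous archetype with a 120-
  interval warm-up so recorded sequences are (approximately) stationary,
  the regime in which the cyclic-shift null is exact; the base entry rate
  falls with `gamma` (log-linear interpolation of anchors calibrated at
  gamma 0, 1, 2) so power comparisons across coupling strengths are made
  at matched play marginals near 0.38.

All randomness flows from one seeded stream per dataset with documented
draw order, so a configuration plus seed is byte-reproducible.

### What the generator does and does not emulate

It reproduces the design's shape (group sizes, sequence length,
missingness), the three-state dynamics with realistic stability (about
80% self-transition for `NoP`/`ObjP`), group-level play profiles,
initiator/joiner heterogeneity, onset/company/toy annotations and group
coupling. It does not emulate the handling treatment's behavioural
consequences or any body-weight effect on play (treatment and weights are
simulated as inert covariates), sub-5-second timing, or observer error
beyond missingness. One emergent consequence worth knowing: under the
dense coupled defaults nearly every pig plays mostly with company, so the
solitary/social axis classifies almost everyone as social and the
simulated initiator/joiner x solitary/social cross-table can be
degenerate. The initiator/joiner axis is the planted, recoverable one;
the solitary/social label in the ground truth is recorded as *emergent*
(majority of realised company), not as a dial.

## Numerical choices and degenerate inputs

* Transition-matrix rows with no visits are all-zero and flagged rather
  than renormalised; substitution costs built from such matrices warn.
* `hubert_c()` returns 0 with a warning when all pairwise distances are
  equal; `select_k()` flags the all-identical configuration as degenerate.
* Singleton clusters contribute silhouette 0, as does the `a = b = 0`
  case.
* The Poisson and linear models drop aliased columns with a warning
  rather than failing on rank-deficient designs.
* `classify_proportion()` with zero events returns mixed with a
  `no_events` flag.
* Proportion CIs against 0.5: classification compares the CI to 0.5
  directly; ties (a bound exactly at 0.5) fall into "mixed".

## Problem sizes

The test-suite and acceptance computations run the full 60-pig design for
distance/clustering recovery, 60 pigs for type recovery, 400 simulated
groups for the type-I calibration of the synchrony test and 150 per
coupling strength for its power curve, with 999 permutations per group —
sizes at which the Monte-Carlo error of a rejection rate is about one
percentage point.

## Known limitations

* The solitary/social axis is emergent, not planted (above), so the
  reference cross-table's structure is checked on the reference counts
  themselves rather than re-derived from simulation.
* The cyclic-shift test assumes within-pig stationarity; applied to
  archetype-A groups (play concentrated early) it would reject for
  time-locked profile reasons rather than interval-scale coupling. The
  calibration preset is stationary by construction for exactly this
  reason.
* Turbulence depends on spell structure only through the DSS and duration
  variance; two sequences with identical spells in different orders can
  score identically.
* The CMH comparison treats transition opportunities as independent
  Bernoulli trials within pig-group cells, ignoring within-pig
  autocorrelation; this matches the original analysis strategy but is
  anti-conservative for strongly autocorrelated sequences.
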