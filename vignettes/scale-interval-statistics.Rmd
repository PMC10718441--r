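---
title: "Interval statistics for musical scale corpora: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval statistics for musical scale corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalestats)
```

## The problem

A musical scale is a sequence of unique pitches; because pitch is perceived
logarithmically, scales are represented here as strictly increasing note
positions in cents from the tonic (`1200 * log2(f1/f2)`; an octave is 1200
cents). *Steps* are adjacent-note intervals; *intervals* in general are all
pairwise differences, of which an instrument with `N` notes offers
`N(N-1)/2`. An *octave scale* spans exactly 1200 cents with notes assumed
to repeat each octave.

Given a corpus of scales from many societies, the package answers three
families of questions:

1. **Between scales** — pooled over a corpus, which interval sizes appear
   as scale notes more or less often than chance?
2. **Within scales** — does an individual scale place its intervals
   significantly closer to (or farther from) a target interval, such as the
   octave, than a random arrangement of its own steps would?
3. **Diversity** — how do observed scales compare with the exhaustive
   universe of possible scales, in particular with respect to equidistance
   (equal step sizes) and note-position entropy?

Because "more often than chance" has no canonical meaning for culturally
transmitted objects, every test is run against explicit generative null
models, and the testing machinery itself is calibrated on data generated
under its own null.

## Null models

All three models preserve the corpus *layout* — the number of scales and
the number of notes in each — so that differences are attributable to
interval content, not sample structure.

* **Lognorm.** Scale notes are drawn independently from a lognormal
  distribution fitted to the pooled notes by maximum likelihood (`mu` =
  mean of logs, `sigma` = population standard deviation of logs — the true
  MLE, not the `n-1` variant). The lognormal shape encodes two hard
  constraints: very small intervals are limited by pitch discrimination,
  very large ones by anatomy and instrument size. Independence is a
  deliberate simplification — notes within a scale are chosen jointly by
  musicians — so this model serves the between-scales pooled comparison,
  not within-scale structure. Sampled notes are sorted ascending;
  duplicate draws are perturbed by 1e-9 cents to keep notes strictly
  increasing.
* **Shuffle.** Each scale's steps are kept as a multiset but arranged in
  uniformly random order. This preserves which step sizes a culture uses
  while destroying their arrangement.
* **Resample.** Steps are drawn i.i.d. with replacement from the pooled
  empirical step distribution (no smoothing) and arranged in drawn order:
  indifferent to both step identity and arrangement.

## Between-scales significance

Societies are unevenly documented, so pooled statistics are computed on
society-balanced subsamples (at most 5 scales per society), averaged over
1000 subsampling rounds; the averaged per-bin counts are rounded to
integers for testing. Notes are histogrammed in 30-cent bins *centered* on
multiples of 30 over 0–2700 cents — centering keeps the canonical
intervals at or near bin centers (1200 sits exactly at a center; 700 falls
inside the bin centered at 690) instead of on bin edges, which would split
their counts.

For each bin the null probability `p_i` is the lognormal integral over the
bin (Lognorm) or the mean bin proportion across generated alternative
corpora (Shuffle/Resample). With `k_i` of `n` notes observed in bin `i`,
the reported tail is `P(X >= k_i)` when `k_i/n > p_i` (direction "more"),
else `P(X <= k_i)` ("less"), `X ~ Binomial(n, p_i)`. Significance uses a
Bonferroni-corrected threshold `alpha / #bins` (91 bins at the defaults),
and 95% confidence bands for the observed proportions come from a
percentile bootstrap over scales (1000 replicates). `n` is the total
pooled note count; bins only partition the 0–2700 range, which in practice
contains all notes.

## Within-scale permutation test

For target `I` and window `w = 100` cents, the deviations `|v - I|` of all
pairwise intervals `v` with `|v - I| <= w` are collected for the original
scale and for each of 50 step-shuffled arrangements. The test statistic is
the Mann-Whitney AUC (the normalized U) of an arrangement's deviations
against the pool of all the other arrangements' deviations.

The p-value is *not* taken from the combinatorial Mann-Whitney null.
That reference assumes two independent samples, but here the pooled
shuffled deviations share the tested scale's own step multiset: every
single-step interval is invariant under shuffling and therefore appears,
exactly tied, in every arrangement. Under the combinatorial reference the
test proved several-fold conservative — on null data it rejected at 1–2%
instead of 5%. Instead the package exploits the exchangeability that the
shuffling construction provides: under the null hypothesis that step order
carries no information, the original arrangement is exchangeable with its
shuffles, so the two-sided p-value is the permutation rank of the
original's extremity `|AUC - 0.5|` among the shuffles' extremities. Ties
in extremity are split at half weight (the mid-p convention, appropriate
here because the significance decision is made on the *converged mean* of
the per-repeat p over `n_repeat` repeats, where an unbiased per-repeat
estimate is wanted); a fully degenerate permutation distribution — every
arrangement equally extreme, as for a perfectly equidistant scale whose
shuffles are identical to itself — reports p = 1. Block sums of the same
steps taken in different orders are kept as exact ties by routing the
original through the same cumulative-sum arithmetic as the shuffles and
snapping deviations to a 1e-6-cent grid (measurement error in real corpora
is at least a full cent).

A scale with no interval inside the window of a target is *untested* for
that target and excluded from the denominator: it carries no information
about `I`. Direction is "closer" when the original's mean deviation is
below the pooled shuffled mean. The standalone `mwu_test()` additionally
provides the classical two-sample Mann-Whitney test (exact enumeration
when both samples have at most 8 values, Monte-Carlo permutation when only
one is that small, tie- and continuity-corrected normal approximation
otherwise) for general use and for verification against brute-force
enumeration in the test suite.

### Calibration and its limits

`null_calibration()` reruns the whole sweep on corpora drawn from the
Resample model and reports the fraction of performed tests flagged
significant. On scales with enough informative intervals the test is
exact: simulated 8-step scales with continuous steps reject at 4.7–5.0%
at `alpha = 0.05`. On corpora of small scales (4–9 steps) the aggregate
fraction settles near 3%, below the nominal 5%, for a structural reason:
many scale/target pairs admit *no* rejection at any threshold, because
their window content is invariant under shuffling — single steps at low
targets, the total span at targets near the span, and (for 4–5-step
scales) arrangement spaces so small that the original's interval multiset
recurs among shuffles with probability above `alpha`. These degenerate
tests are still counted in the denominator (they satisfy the tested
precondition), so the aggregate sits below `alpha` whenever they are
frequent. The calibration band reported per target makes this visible.

### Noise sensitivity

`noise_sensitivity_curve()` quantifies how intonation and measurement
noise mask intentional octaves. A test set is built by sampling steps from
the measured-scale step pool and snapping every note at or above 1200
cents to an exact octave transposition of the nearest lower non-tonic
note (`generate_octave_locked_testset()`). The default layout draws 9–15
steps per scale, emulating fixed-pitch instruments whose compass spans
roughly 1.5–2.5 octaves — the instruments that dominate octave evidence in
real corpora — so each scale carries several exact octave pairs. Gaussian
noise of standard deviation `sigma` is then added to all non-tonic notes
and the octave test is run per scale. Even at `sigma = 0` detection stays
below 1 (about 0.9 at the defaults): windows hold only a handful of
deviations, which caps the attainable permutation extremity. Detection
decays to the chance band by `sigma` around 100–300 cents.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure of published
cross-cultural scale databases; its defaults are the package's study
conditions and are exercised directly by the test suite.

* ~8 regions of synthetic labels, societies assigned round-robin; society
  counts and scales per society configurable (tests use 25 societies, 6
  scales each).
* Note counts (steps per scale) weighted `4:0.10, 5:0.35, 6:0.03, 7:0.35,
  8:0.10, 9:0.07` — pentatonic and heptatonic scales dominate real
  corpora and hexatonic scales are conspicuously rare.
* Measured-scale steps from a truncated normal (mean 200, sd 55 cents,
  hard bounds 60–500), rescaled to span exactly 1200 for octave-anchored
  scales (probability 0.8). A quarter of measured scales are drawn
  near-equidistant (equidistant internal notes plus jitter). Half of the
  anchored scales extend past the octave with 1–3 upper notes that are
  exact octave transpositions of the lowest non-tonic notes — instruments
  with a compass above an octave tune upper notes as octave duplicates,
  and this is precisely the structure the within-scale octave test
  detects (a scale whose *span* is its only octave interval cannot yield
  a shuffle-detectable octave, since shuffling preserves the span).
* With probability 0.5 the note nearest 700 cents is nudged to exactly
  700 before noise: the perfect-fifth anchor observed across traditions.
* 30% of scales are theory scales: exact integer-cent subsets of 12-tone
  equal temperament spanning the octave, built as compositions of 12
  semitones with parts weighted toward the whole tone and avoiding a note
  at the 600-cent tritone position, which documented theory traditions
  rarely use. Theory scales receive no intonation noise.
* Measured notes get Gaussian intonation noise (sd 10 cents — the stated
  upper bound on source measurement error), with monotonicity repaired by
  re-sorting and step bounds re-checked.

What the generator does *not* emulate: per-society scale inventories and
geography, realistic regional contrasts, tonal hierarchies, instrument
families, or historically linked societies. Tests passing on generated
corpora therefore demonstrate that the statistical machinery recovers
planted structure of the right kind and magnitude — octave and fifth
enrichment, tritone avoidance, near-equidistance — not that any particular
cultural claim holds in real data.

## Grid scales, equidistance and entropy

The universe of possible octave scales is enumerated exhaustively on a
cents grid: ordered step tuples at 20-cent resolution, each step within
60–320 cents, summing to 1200 (`grid_spec()`). Distinct orderings are
distinct scales, since note positions depend on order. The 7-note grid
holds 3,250,989 scales; the implementation counts by dynamic programming,
streams the full enumeration in C++ for statistics, and is verified in the
tests against the independent inclusion–exclusion closed form.

Equidistance is measured as the mean absolute deviation of the *internal*
notes (tonic and octave excluded — they are fixed by construction and
would dilute the statistic) from the equidistant reference
`k * 1200 / n`. Thresholds in use: 43 cents (the farthest observed real
scales sit from equiheptatonic), 30 and 10 cents for tighter labels. Of
the 7-note grid, 9.61% lies within 43 cents of equiheptatonic — the
baseline against which the observed clustering of real scales near
equidistance (a large majority in published corpora) is judged.

Per-note histograms (20-cent bins) and their Shannon entropies (bits; the
base only rescales and all comparisons are ordinal) summarize where notes
fall. On the full grid the middle notes (4 and 5) have the broadest
distributions and highest entropy — they are sums of several free steps.
Real corpora inverted this pattern, and the package provides the two
contrast constructions used to probe it: `sorted_variants()` (steps sorted
ascending, all rotations emitted — the arrangement farthest from
equidistance) and `shuffled_variants()` (random step order). Sorted
variants raise entropy markedly at the interior notes; at the two edge
notes the sorted construction's note distribution coincides in law with
the original's whenever steps are exchangeable, so edge-index comparisons
are uninformative and the shipped checks compare interior indices and the
overall level.

## Embedding and clustering

Scales with a common note count are compared as vectors of internal note
positions. `embed_and_cluster()` maps them to two dimensions with t-SNE
(exact gradient, perplexity calibrated per point by bisection, early
exaggeration, momentum gradient descent — adequate for corpora of
hundreds to a few thousand scales) and clusters the embedding with DBSCAN
(eps = 2 embedding units, minimum 5 samples; noise labelled -1). Both
algorithms are implemented in the package. Embedding coordinates are
arbitrary; only neighborhood structure is meaningful, and the tests assert
exactly that — planted cluster recovery and rank correlation between
embedded and original distances above 0.5 — never particular coordinates.

## Numerical conventions and degenerate inputs

* Histogram bins are half-open `[center - w/2, center + w/2)`.
* Cents are serialized with 3 decimals (lossless against the >= 1-cent
  measurement error of real sources); corpus round trips are exact to
  1e-3 cents.
* A lognormal fit with `sigma = 0` (all values equal) is flagged
  degenerate where a distribution is required.
* Octave inference (`infer_octave_scale()`) accepts spans within 50 cents
  of 1200 (rescaling proportionally by default), folds wider spans down by
  whole octaves, merges folded notes closer than 20 cents into their mean
  (anchored at tonic and octave), requires at least 4 surviving note
  positions, and in all-tonics mode deduplicates rotations by exact note
  equality. The tolerances exceed both the stated measurement error (10
  cents) and the grid resolution (20 cents).
* Empty corpora, empty windows, and infeasible grid specifications return
  empty/zero results rather than errors wherever the quantity is a count
  or fraction.

## Problem sizes used by the shipped checks

The test suite and the reproduction script run the analyses at moderate
sizes chosen as defaults for exploratory work: corpora of ~150 scales
(25 societies), 1000→100–300 balanced resamples for profiles, 50 shuffles
and 10–50 repeats for within-scale tests, 20 resampled null corpora for
calibration, and the full 7-note grid enumeration. All quantities reported
in the README were produced by these runs.

## Known limitations

* The within-scale aggregate calibration sits below the nominal level on
  corpora of small scales, for the structural reasons described above;
  per-target bands should be consulted rather than the aggregate alone.
* The Lognorm model is a pooled-notes null only; it makes no claim about
  within-scale dependence.
* The generator's regional and society structure is purely nominal;
  region-stratified analyses on generated data test bookkeeping, not
  cultural signal.
* t-SNE embeddings are stochastic given the seed and not comparable
  across runs with different seeds; cluster *identities* are arbitrary.
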