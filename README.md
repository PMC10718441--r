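# scalestats

Resampling statistics for cross-cultural corpora of musical scales.

Ethnomusicological databases describe scales as ordered note positions in
cents from the tonic (an octave is 1200 cents). A recurring question about
such corpora is which intervals — the octave, the fifth near 700 cents, the
second near 200 cents — occur more (or less) often than chance, and how
diverse scales really are compared with the universe of scales that could
exist. `scalestats` implements that analysis battery as a tested R package,
for researchers in music cognition and cultural evolution who want to run
interval-significance and diversity analyses on their own corpora, or to
study the behaviour of these statistics on synthetic data.

## What it computes

* **Null models of scale generation.** Three alternative-sampling models
  that preserve a corpus's layout (number of scales, notes per scale):
  independent notes from the maximum-likelihood lognormal fit
  (`fit_lognormal()`, `sample_lognorm_scales()`); within-scale step
  shuffling (`shuffle_corpus()`); and steps resampled i.i.d. from the
  pooled empirical step distribution (`resample_scales()`).
* **Between-scales interval significance** (`significance_profile()`).
  Pooled scale notes are histogrammed (30-cent bins centered on multiples
  of 30, range 0–2700 cents) over society-balanced subsamples (at most 5
  scales per society, averaged over 1000 resamples). Each bin count `k` out
  of `n` notes is tested against the model probability `p_i` with a
  one-sided binomial tail: `P(X >= k)` when `k/n > p_i`, else `P(X <= k)`,
  at a Bonferroni-corrected threshold `0.05 / #bins`, with percentile
  bootstrap bands.
* **Within-scale interval tests** (`within_scale_test()`,
  `interval_sweep()`, `null_calibration()`). For a target interval `I`, all
  pairwise deviations within `w = 100` cents of `I` are scored with the
  Mann-Whitney AUC against the pooled deviations of 50 step-shuffled
  arrangements; the two-sided p-value is the permutation rank of the
  original arrangement's extremity among the shuffles' (exact under the
  null by exchangeability), averaged over repeats. The sweep reports, per
  target in 200–2600 cents, the fraction of scales significantly closer
  or farther than chance, with a resampled-null calibration band.
* **Tuning-noise sensitivity** (`noise_sensitivity_curve()`): how often the
  octave test still fires on octave-locked instruments as Gaussian
  intonation noise grows.
* **Grid-scale enumeration and equidistance** (`grid_spec()`,
  `grid_scale_stats()`): exhaustive enumeration of all octave scales on a
  20-cent grid with steps in 60–320 cents, the fraction within a given mean
  note deviation of the equidistant scale, per-note histograms and Shannon
  entropies, plus sorted-step and shuffled-step rearrangements of real
  scales (`sorted_variants()`, `shuffled_variants()`).
* **Diversity across societies** (`embed_and_cluster()`): t-SNE embedding
  of same-size scale vectors with DBSCAN clustering (eps = 2, minimum
  samples = 5), both implemented in the package.
* **Synthetic corpus generator** (`generator_config()`,
  `generate_corpus()`): seeded corpora emulating the statistical structure
  of published scale databases — note counts concentrated on 5 and 7,
  steps peaked near 200 cents within 100–400, frequent exact octaves and
  fifths, near-equidistant and exact-ratio theory scales — so every stage
  is testable without the original sources.
* **Pipeline orchestration** (`run_pipeline()`): generate → between →
  within → diversity with derived per-stage seeds, TSV outputs and a JSON
  manifest with checksums.

## Worked example

```r
library(scalestats)

corpus <- generate_corpus(generator_config(n_societies = 25,
                                           scales_per_society = 6), seed = 1)
corpus
#> <scale_corpus> 150 scales, 25 societies, 8 regions
#>   kinds: measured=101, theory=49

prof <- significance_profile(corpus, model = "lognorm", seed = 2)
prof
#> <significance_profile> model = lognorm, n = 861 notes, 91 bins, Bonferroni alpha = 0.00055
#> significant bins:
#>  bin_center   k       p   q_tail direction
#>        ...
#>         210  37 0.02041 2.85e-05      more
#>         510  48 0.03254 2.92e-04      more
#>         600  10 0.02937 4.24e-04      less
#>         690  71 0.02567 2.86e-17      more
#>         ...
#>        1200 110 0.00986 4.12e-83      more
```

Bins containing the octave (1200), the fifth (690-cent bin covering 700),
the fourth (510) and the second (210) are flagged as used *more* than the
lognormal null predicts; the tritone region (600) is used *less* — the
qualitative interval structure reported for real cross-cultural corpora.

```r
sweep <- interval_sweep(corpus, n_repeat = 10, seed = 3)
sweep
#> <interval_sweep> 121 targets (200-2600 cents), window 100
#> top targets by fraction significantly closer:
#>  target frac_closer frac_farther n_tested
#>    1200      0.1241       0.0000      145
#>    1220      0.0621       0.0069      145
#>    1180      0.0552       0.0000      145

gstats <- grid_scale_stats(grid_spec(7), threshold = 43)
sprintf("grid scales: %d; within 43 cents of equiheptatonic: %.1f%%",
        gstats$count, 100 * gstats$fraction_within)
#> "grid scales: 3250989; within 43 cents of equiheptatonic: 9.6%"
```

The within-scale sweep peaks at the octave, and of the 3,250,989 possible
7-note octave grid scales only ~10% lie within 43 cents of the
equiheptatonic scale — the context against which the observed clustering of
real scales around equidistance is judged.

## Documentation

The methods vignette (`vignettes/scale-interval-statistics.Rmd`) describes
the statistical models, the permutation-test construction and its
calibration properties, the synthetic generator's design and its limits,
and the package's numerical conventions.
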