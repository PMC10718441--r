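#' Deviations of a scale's intervals from a target interval
#'
#' Finds all pairwise intervals of the scale within `w` cents of the target
#' `I` and returns their absolute distances from `I` (possibly empty).
#'
#' @param notes Strictly increasing note positions (cents), tonic first.
#' @param target Target interval `I` in cents.
#' @param window Window half-width `w` in cents (default 100).
#' @return Numeric vector of deviations, all `<= window`.
#' @export
windowed_deviations <- function(notes, target, window = 100) {
  iv <- all_pair_intervals(notes)
  d <- abs(iv - target)
  d[d <= window]
}

#' Two-sided Mann-Whitney U test
#'
#' The test used throughout the within-scale analysis. The two-sided p-value
#' is `P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)`, computed from: the exact
#' permutation distribution of U (with midrank treatment of ties) when both
#' sample sizes are at most `exact_max`; a Monte-Carlo permutation
#' distribution (`n_mc` draws) when only one sample is that small -- the
#' within-scale tests routinely compare a handful of original deviations
#' against thousands of pooled shuffled ones, where the normal approximation
#' is too discrete to ever reject; and a normal approximation with tie and
#' continuity correction when both samples are large.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest sample size for the exact enumeration (default 8).
#' @param n_mc Monte-Carlo permutation draws used when only one sample is
#'   small (default 199); consumes R's RNG stream.
#' @return List with `statistic` (U of `x` vs `y`), `p_value`, and `method`
#'   (`"exact"`, `"mc_permutation"` or `"normal"`).
#' @export
mwu_test <- function(x, y, exact_max = 8, n_mc = 199) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  mwu_cpp(as.numeric(x), as.numeric(y), as.integer(exact_max),
          as.integer(n_mc))
}

#' Within-scale interval significance test
#'
#' Tests whether the intervals of one scale are significantly closer to (or
#' farther from) a target interval than expected if the scale's step sizes
#' were arranged in random order. Per repeat, every arrangement (the
#' original plus `n_shuffle` step-shuffled variants) is scored with the
#' Mann-Whitney AUC of its windowed deviations against the pooled
#' deviations of the other arrangements; since the original is exchangeable
#' with its shuffles under the null, the two-sided p-value is the
#' permutation rank of the original's extremity `|AUC - 0.5|` among the
#' shuffles' (mid-p tie convention; a fully degenerate distribution, e.g.
#' an equidistant scale whose shuffles equal itself, reports p = 1). The
#' p-values are averaged over `n_repeat` repeats and significance is
#' decided on the mean p.
#'
#' @param record A [scale_record()].
#' @param target Target interval (cents).
#' @param window Window half-width (default 100 cents).
#' @param n_shuffle Shuffled variants per repeat (default 50).
#' @param n_repeat Repeats averaged (default 100).
#' @param alpha Significance level on the mean p (default 0.05).
#' @param seed Integer seed.
#' @return List with `tested`, `mean_p`, `direction` (`"closer"` if the mean
#'   original deviation is below the pooled shuffled mean, else
#'   `"farther"`), `significant`, `mean_dev_orig`, `mean_dev_shuffled`.
#'   An untested scale (no interval within the window) has `tested = FALSE`
#'   and `NA` results.
#' @export
within_scale_test <- function(record, target, window = 100, n_shuffle = 50,
                              n_repeat = 100, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(record, "scale_record"))
  res <- with_seed(seed,
    sweep_scale_cpp(record$notes, target, window,
                    as.integer(n_shuffle), as.integer(n_repeat)))
  tested <- res$tested[1]
  direction <- if (!tested) NA_character_
               else if (res$mean_dev_orig[1] < res$mean_dev_shuffled[1])
                 "closer" else "farther"
  list(tested = tested,
       mean_p = res$mean_p[1],
       direction = direction,
       significant = tested && res$mean_p[1] < alpha,
       mean_dev_orig = res$mean_dev_orig[1],
       mean_dev_shuffled = res$mean_dev_shuffled[1])
}

#' Within-scale interval sweep over a corpus
#'
#' Applies [within_scale_test()] to every scale for every target interval and
#' reports, per target, the fraction of tested scales whose intervals are
#' significantly closer to / farther from the target than chance. Scales
#' with no interval within the window of a target are excluded from that
#' target's denominator.
#'
#' @param corpus A [scale_corpus()].
#' @param targets Target intervals in cents (default a 20-cent grid over
#'   200-2600).
#' @param window,n_shuffle,n_repeat,alpha As in [within_scale_test()].
#' @param seed Integer seed.
#' @return An object of class `interval_sweep`: data frame with `target`,
#'   `frac_closer`, `frac_farther`, `n_tested`.
#' @export
interval_sweep <- function(corpus, targets = seq(200, 2600, by = 20),
                           window = 100, n_shuffle = 50, n_repeat = 100,
                           alpha = 0.05, seed = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  nt <- length(targets)
  closer <- farther <- tested <- numeric(nt)
  with_seed(seed, {
    for (rec in corpus$records) {
      res <- sweep_scale_cpp(rec$notes, targets, window,
                             as.integer(n_shuffle), as.integer(n_repeat))
      ok <- res$tested
      sig <- ok & !is.na(res$mean_p) & res$mean_p < alpha
      cl <- sig & res$mean_dev_orig < res$mean_dev_shuffled
      tested <- tested + ok
      closer <- closer + cl
      farther <- farther + (sig & !cl)
    }
  })
  out <- data.frame(target = targets,
                    frac_closer = ifelse(tested > 0, closer / tested, 0),
                    frac_farther = ifelse(tested > 0, farther / tested, 0),
                    n_tested = as.integer(tested))
  attr(out, "window") <- window
  attr(out, "alpha") <- alpha
  class(out) <- c("interval_sweep", "data.frame")
  out
}

#' @export
print.interval_sweep <- function(x, ...) {
  cat(sprintf("<interval_sweep> %d targets (%g-%g cents), window %g\n",
              nrow(x), min(x$target), max(x$target), attr(x, "window")))
  top <- x[order(-x$frac_closer), ][1:min(5L, nrow(x)), ]
  cat("top targets by fraction significantly closer:\n")
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.interval_sweep <- function(x, null_band = NULL, ...) {
  ylim <- c(0, max(x$frac_closer, x$frac_farther,
                   if (!is.null(null_band)) null_band$hi else 0) * 1.05)
  plot(x$target, x$frac_closer, type = "l", ylim = ylim,
       xlab = "interval (cents)", ylab = "fraction of scales significant",
       ...)
  lines(x$target, x$frac_farther, lty = 2)
  if (!is.null(null_band))
    polygon(c(null_band$target, rev(null_band$target)),
            c(null_band$lo, rev(null_band$hi)),
            border = NA, col = grDevices::adjustcolor("grey", 0.5))
  legend("topright", lty = c(1, 2), legend = c("closer", "farther"),
         bty = "n")
  invisible(x)
}

#' Null calibration of the interval sweep
#'
#' Repeats the sweep on corpora generated under the step-resampling null
#' (steps drawn i.i.d. from the corpus's pooled step distribution, layout
#' preserved). Because resampled scales carry no interval structure beyond
#' their step distribution, the long-run significant fraction should settle
#' near `alpha` -- the calibration check for the whole within-scale
#' machinery.
#'
#' @param corpus A [scale_corpus()] supplying the step pool and layout.
#' @param targets,window,n_shuffle,n_repeat,alpha As in [interval_sweep()].
#' @param n_null_sets Number of resampled corpora (>= 10; default 20).
#' @param seed Integer seed.
#' @return List with `band` (data frame `target`, `lo`, `hi`, `mean`:
#'   2.5/97.5 percentiles and mean of the per-target significant fraction),
#'   `mean_significant_fraction` (the fraction of all performed tests --
#'   scale/target pairs with an interval in the window -- flagged
#'   significant, averaged over null sets) and `per_set` (matrix of
#'   per-target significant fractions, sets x targets).
#' @export
null_calibration <- function(corpus, targets = seq(200, 2600, by = 20),
                             window = 100, n_shuffle = 50, n_repeat = 100,
                             alpha = 0.05, n_null_sets = 20, seed = NULL) {
  if (n_null_sets < 10) stop("n_null_sets must be >= 10", call. = FALSE)
  pool <- corpus_steps(corpus)
  layout <- corpus_layout(corpus)
  frac <- matrix(NA_real_, n_null_sets, length(targets))
  tested_any <- matrix(FALSE, n_null_sets, length(targets))
  overall <- numeric(n_null_sets)
  with_seed(seed, {
    for (s in seq_len(n_null_sets)) {
      alt <- resample_scales(pool, layout)
      sw <- interval_sweep(alt, targets, window, n_shuffle, n_repeat, alpha)
      frac[s, ] <- sw$frac_closer + sw$frac_farther
      tested_any[s, ] <- sw$n_tested > 0
      overall[s] <- sum((sw$frac_closer + sw$frac_farther) * sw$n_tested) /
        sum(sw$n_tested)
    }
  })
  frac[!tested_any] <- NA_real_
  band <- data.frame(
    target = targets,
    lo = apply(frac, 2, quantile, probs = 0.025, na.rm = TRUE, names = FALSE),
    hi = apply(frac, 2, quantile, probs = 0.975, na.rm = TRUE, names = FALSE),
    mean = colMeans(frac, na.rm = TRUE))
  list(band = band,
       mean_significant_fraction = mean(overall),
       per_set = frac)
}

#' Octave-detection sensitivity to intonation noise
#'
#' Builds an octave-locked test set (upper notes exact octave copies of
#' lower notes; see [generate_octave_locked_testset()]), adds Gaussian
#' intonation noise of increasing sd, and measures how often the
#' within-scale test still flags intervals significantly closer to the
#' octave. Even at sigma = 0 detection stays below 1 because small interval
#' samples cap the attainable Mann-Whitney significance.
#'
#' @param step_pool Step sizes (cents) to build the test set from.
#' @param n_scales Scales in the test set (default 100).
#' @param sigma_grid Noise sds in cents (default 0-300 by 25).
#' @param target Target interval (default the octave, 1200).
#' @param window,n_shuffle,n_repeat,alpha As in [within_scale_test()].
#' @param note_counts Step counts of the test-set scales (default 9:15; see
#'   [generate_octave_locked_testset()]).
#' @param n_boot Bootstrap replicates for the 95% CI over scales (default 200).
#' @param seed Integer seed.
#' @return An object of class `noise_curve`: data frame with `sigma`,
#'   `frac_closer`, `frac_farther`, `n_tested`, `ci_low`, `ci_high`.
#' @export
noise_sensitivity_curve <- function(step_pool, n_scales = 100,
                                    sigma_grid = seq(0, 300, by = 25),
                                    target = 1200, window = 100,
                                    n_shuffle = 50, n_repeat = 100,
                                    alpha = 0.05, note_counts = 9:15,
                                    n_boot = 200, seed = NULL) {
  if (any(sigma_grid < 0)) stop("sigma_grid must be >= 0", call. = FALSE)
  cfg <- generator_config()
  with_seed(seed, {
    base <- generate_octave_locked_testset(cfg, n_scales, step_pool,
                                           note_counts = note_counts,
                                           seed = NULL)
    rows <- lapply(sigma_grid, function(sig) {
      noisy <- add_intonation_noise(base, sig)
      cl <- fa <- logical(length(noisy))
      tested <- logical(length(noisy))
      for (i in seq_along(noisy$records)) {
        res <- sweep_scale_cpp(noisy$records[[i]]$notes, target, window,
                               as.integer(n_shuffle), as.integer(n_repeat))
        tested[i] <- res$tested[1]
        if (tested[i] && !is.na(res$mean_p[1]) && res$mean_p[1] < alpha) {
          if (res$mean_dev_orig[1] < res$mean_dev_shuffled[1]) cl[i] <- TRUE
          else fa[i] <- TRUE
        }
      }
      nt <- sum(tested)
      fc <- if (nt > 0) sum(cl) / nt else 0
      ff <- if (nt > 0) sum(fa) / nt else 0
      # percentile bootstrap of the closer-fraction over tested scales
      if (nt > 0) {
        ind <- cl[tested]
        bs <- vapply(seq_len(n_boot), function(b)
          mean(ind[sample.int(nt, nt, replace = TRUE)]), numeric(1))
        ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
      } else ci <- c(NA_real_, NA_real_)
      data.frame(sigma = sig, frac_closer = fc, frac_farther = ff,
                 n_tested = nt, ci_low = ci[1], ci_high = ci[2])
    })
    out <- do.call(rbind, rows)
    class(out) <- c("noise_curve", "data.frame")
    out
  })
}

#' @export
plot.noise_curve <- function(x, ...) {
  plot(x$sigma, x$frac_closer, type = "b", ylim = c(0, 1),
       xlab = "intonation noise sd (cents)",
       ylab = "fraction significantly closer to target", ...)
  polygon(c(x$sigma, rev(x$sigma)), c(x$ci_low, rev(x$ci_high)),
          border = NA, col = grDevices::adjustcolor("grey", 0.5))
  lines(x$sigma, x$frac_closer, type = "b")
  invisible(x)
}
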