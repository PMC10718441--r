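#' Society-balanced subsample of a corpus
#'
#' Retains at most `max_per_society` scales per society (uniformly at
#' random); societies with fewer records keep all of them. Grouping scales
#' from many societies over-weights heavily documented ones, so the
#' between-scales tests average over many such subsamples.
#'
#' @param corpus A [scale_corpus()].
#' @param max_per_society Cap per society (default 5).
#' @param seed Integer seed.
#' @return A [scale_corpus()].
#' @export
balanced_subsample <- function(corpus, max_per_society = 5, seed = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  if (max_per_society < 1) stop("cap must be >= 1", call. = FALSE)
  with_seed(seed, {
    keep <- unlist(lapply(corpus$society_index, function(idx) {
      if (length(idx) <= max_per_society) idx
      else sample(idx, max_per_society)
    }), use.names = FALSE)
    # unchecked: bootstrap resamples legitimately carry duplicated records
    scale_corpus_unchecked(corpus$records[sort(keep)])
  })
}

#' Histogram with bins centered on multiples of the bin width
#'
#' Bin edges are `center +/- width/2`, half-open `[low, high)`. Centering on
#' multiples of the width keeps canonical intervals (1200, 700 -> bin 690,
#' 200 cents) at or near bin centers instead of on edges.
#'
#' @param values Numeric values (cents).
#' @param bin_width Bin width in cents (default 30).
#' @param range Closed interval of bin centers to produce, as `c(lo, hi)`
#'   with both multiples of `bin_width` (default `c(0, 2700)`).
#' @return List with `centers` and integer `counts` (same length). Values
#'   outside `[lo - width/2, hi + width/2)` are not counted.
#' @export
interval_histogram <- function(values, bin_width = 30, range = c(0, 2700)) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (any(range %% bin_width != 0))
    stop("range endpoints must be multiples of bin_width", call. = FALSE)
  centers <- seq(range[1], range[2], by = bin_width)
  lo <- range[1] - bin_width / 2
  idx <- floor((values - lo) / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= length(centers) & !is.na(idx)]
  counts <- tabulate(idx, nbins = length(centers))
  list(centers = centers, counts = counts)
}

#' Lognormal bin probabilities
#'
#' Integrates `lnN(mu, sigma^2)` over each histogram bin: `p_i =
#' CDF(high_i) - CDF(low_i)`, the probability a note falls in bin `i` under
#' the lognormal null.
#'
#' @param params A [fit_lognormal()] result.
#' @param centers Bin centers (cents).
#' @param bin_width Bin width (cents).
#' @return Numeric vector of probabilities, one per bin.
#' @export
lognorm_bin_probabilities <- function(params, centers, bin_width) {
  if (params$sigma <= 0)
    stop("degenerate lognormal (sigma = 0)", call. = FALSE)
  lo <- pmax(centers - bin_width / 2, 0)
  hi <- pmax(centers + bin_width / 2, 0)
  plnorm(hi, params$mu, params$sigma) - plnorm(lo, params$mu, params$sigma)
}

#' Empirical bin probabilities under the shuffle or resample model
#'
#' Generates `n_sets` alternative corpora under the chosen model and returns
#' the mean proportion of notes falling in each bin (relative to all notes,
#' so the probabilities over the full positive axis sum to 1).
#'
#' @param model `"shuffle"` or `"resample"`.
#' @param corpus A [scale_corpus()].
#' @param centers,bin_width Histogram geometry (see [interval_histogram()]).
#' @param n_sets Number of alternative corpora (>= 100 recommended).
#' @param max_per_society Optional cap: when given, each alternative set is
#'   built from a fresh society-balanced subsample.
#' @param seed Integer seed.
#' @return Numeric vector of probabilities, one per bin.
#' @export
empirical_bin_probabilities <- function(model = c("shuffle", "resample"),
                                        corpus, centers, bin_width,
                                        n_sets = 200,
                                        max_per_society = NULL,
                                        seed = NULL) {
  model <- match.arg(model)
  rng <- c(min(centers), max(centers))
  with_seed(seed, {
    acc <- numeric(length(centers))
    for (s in seq_len(n_sets)) {
      base <- if (is.null(max_per_society)) corpus
              else balanced_subsample(corpus, max_per_society)
      alt <- null_corpus(base, model)
      notes <- corpus_notes(alt)
      h <- interval_histogram(notes, bin_width, rng)
      acc <- acc + h$counts / length(notes)
    }
    acc / n_sets
  })
}

#' One-sided binomial tail test of a bin count
#'
#' Given `k` observations out of `n` in a bin with null probability `p`,
#' reports the upper-tail probability `P(X >= k)` when `k/n > p` (direction
#' `"more"`) and the lower-tail probability `P(X <= k)` otherwise (direction
#' `"less"`). Low values flag bins whose counts deviate from the null.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Total observations.
#' @param p Null bin probability (vectorized with `k`).
#' @return List with `q_tail` and `direction` (both vectorized).
#' @export
binomial_tail_test <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]", call. = FALSE)
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  more <- k / n > p
  q <- ifelse(more,
              pbinom(k - 1, n, p, lower.tail = FALSE),
              pbinom(k, n, p))
  list(q_tail = pmin(q, 1), direction = ifelse(more, "more", "less"))
}

#' Between-scales interval significance profile
#'
#' Detects scale notes used more or less often than chance across a corpus.
#' Histogram counts of pooled non-tonic notes are averaged over `n_resamples`
#' society-balanced subsamples, rounded, and compared bin-by-bin with the
#' chosen null model via [binomial_tail_test()]; the significance threshold
#' is Bonferroni-adjusted (`alpha / #bins`). 95% confidence bands for the
#' observed bin proportions come from a percentile bootstrap over scales.
#'
#' @param corpus A non-empty [scale_corpus()].
#' @param model Null model: `"lognorm"` (notes drawn independently from the
#'   maximum-likelihood lognormal fit), `"shuffle"` (step order permuted
#'   within scales) or `"resample"` (steps drawn from the pooled empirical
#'   step distribution).
#' @param bin_width,range Histogram geometry (defaults 30 cents over
#'   0-2700).
#' @param max_per_society Society cap for the balanced subsamples (default 5).
#' @param n_resamples Number of balanced subsamples averaged (default 1000).
#' @param n_sets Alternative corpora for the empirical models (default 200).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha Family-wise significance level before correction (0.05).
#' @param seed Integer seed.
#' @return An object of class `significance_profile`: a data frame with one
#'   row per bin (`bin_center`, `k`, `p`, `q_tail`, `direction`,
#'   `significant`, `ci_low`, `ci_high`) and attributes `n`, `model`,
#'   `alpha_bonferroni`, `params`.
#' @export
significance_profile <- function(corpus,
                                 model = c("lognorm", "shuffle", "resample"),
                                 bin_width = 30, range = c(0, 2700),
                                 max_per_society = 5, n_resamples = 1000,
                                 n_sets = 200, n_boot = 1000, alpha = 0.05,
                                 seed = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  model <- match.arg(model)
  with_seed(seed, {
    centers <- seq(range[1], range[2], by = bin_width)
    nb <- length(centers)
    count_acc <- numeric(nb)
    total_acc <- 0
    pooled_notes <- vector("list", n_resamples)
    for (r in seq_len(n_resamples)) {
      sub <- balanced_subsample(corpus, max_per_society)
      notes <- corpus_notes(sub)
      h <- interval_histogram(notes, bin_width, range)
      count_acc <- count_acc + h$counts
      total_acc <- total_acc + length(notes)
      pooled_notes[[r]] <- notes
    }
    k <- round(count_acc / n_resamples)
    n <- max(round(total_acc / n_resamples), sum(k))

    p <- if (model == "lognorm") {
      params <- fit_lognormal(unlist(pooled_notes, use.names = FALSE))
      lognorm_bin_probabilities(params, centers, bin_width)
    } else {
      params <- NULL
      empirical_bin_probabilities(model, corpus, centers, bin_width,
                                  n_sets = n_sets,
                                  max_per_society = max_per_society)
    }

    bt <- binomial_tail_test(k, n, p)
    alpha_bonf <- alpha / nb

    # percentile bootstrap over scales of the observed bin proportions
    boot <- matrix(NA_real_, n_boot, nb)
    N <- length(corpus)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(N, N, replace = TRUE)
      bs <- scale_corpus_unchecked(corpus$records[idx])
      bs <- balanced_subsample(bs, max_per_society)
      notes <- corpus_notes(bs)
      h <- interval_histogram(notes, bin_width, range)
      boot[b, ] <- h$counts / max(length(notes), 1L)
    }
    ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)

    out <- data.frame(bin_center = centers, k = k, p = p,
                      q_tail = bt$q_tail, direction = bt$direction,
                      significant = bt$q_tail < alpha_bonf,
                      ci_low = ci[1, ], ci_high = ci[2, ])
    attr(out, "n") <- n
    attr(out, "model") <- model
    attr(out, "alpha_bonferroni") <- alpha_bonf
    attr(out, "params") <- params
    class(out) <- c("significance_profile", "data.frame")
    out
  })
}

# bootstrap resamples contain duplicate scale_ids; bypass uniqueness check
scale_corpus_unchecked <- function(records) {
  structure(list(records = records,
                 society_index = build_index(records, "society_id"),
                 region_index = build_index(records, "region")),
            class = "scale_corpus")
}

#' @export
print.significance_profile <- function(x, ...) {
  cat(sprintf("<significance_profile> model = %s, n = %d notes, %d bins, Bonferroni alpha = %.2g\n",
              attr(x, "model"), attr(x, "n"), nrow(x),
              attr(x, "alpha_bonferroni")))
  sig <- x[x$significant, c("bin_center", "k", "p", "q_tail", "direction")]
  if (nrow(sig)) {
    cat("significant bins:\n")
    print.data.frame(sig, row.names = FALSE, digits = 3)
  } else cat("no significant bins\n")
  invisible(x)
}

#' @export
plot.significance_profile <- function(x, ...) {
  q <- pmax(x$q_tail, 1e-16)
  plot(x$bin_center, q, log = "y", type = "n",
       xlab = "interval (cents)", ylab = "binomial tail probability", ...)
  open <- x$direction == "more"
  points(x$bin_center[open], q[open], pch = 1)
  points(x$bin_center[!open], q[!open], pch = 16)
  abline(h = attr(x, "alpha_bonferroni"), lty = 3)
  abline(v = c(200, 700), lty = 2, col = "grey")
  legend("bottomright", pch = c(1, 16), legend = c("more", "less"),
         bty = "n")
  invisible(x)
}
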