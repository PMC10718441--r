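#' Maximum-likelihood lognormal fit
#'
#' MLE of the lognormal distribution for pooled scale notes: `mu` is the mean
#' of the natural logs and `sigma` the population (1/n) standard deviation of
#' the logs -- the true maximum-likelihood estimator.
#'
#' @param values Positive values (cents); at least 2.
#' @return A list of class `lognorm_params` with elements `mu`, `sigma`, `n`.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite", call. = FALSE)
  lv <- log(values)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  structure(list(mu = mu, sigma = sigma, n = length(values)),
            class = "lognorm_params")
}

#' @export
print.lognorm_params <- function(x, ...) {
  cat(sprintf("<lognorm_params> mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

null_metadata_record <- function(id, society, notes) {
  scale_record(id, society_id = society, region = "null_model",
               country = "null_model", kind = "measured",
               method = "instrument", tonic_known = TRUE, notes = notes)
}

#' Sample scales with independent lognormal notes
#'
#' Per scale with `k` notes, `k - 1` non-tonic notes are drawn independently
#' from `lnN(mu, sigma^2)`, sorted ascending and prepended with the 0-cent
#' tonic; the layout is preserved exactly. Duplicate draws are perturbed by
#' +1e-9 cents so notes remain strictly increasing.
#'
#' @param params A [fit_lognormal()] result (or list with `mu`, `sigma`).
#' @param layout Integer vector of notes per scale (see [corpus_layout()]).
#' @param seed Integer seed.
#' @return A [scale_corpus()].
#' @export
sample_lognorm_scales <- function(params, layout, seed = NULL) {
  if (any(layout < 2L)) stop("layout entries must be >= 2", call. = FALSE)
  if (params$sigma == 0)
    warning("sigma = 0: degenerate point-mass notes", call. = FALSE)
  with_seed(seed, {
    records <- lapply(seq_along(layout), function(i) {
      k <- layout[i]
      v <- sort(rlnorm(k - 1L, params$mu, params$sigma))
      while (any(dup <- c(FALSE, diff(v) <= 0)))
        v[dup] <- v[dup] + 1e-9
      null_metadata_record(sprintf("lognorm_%04d", i), "null_lognorm",
                           c(0, v))
    })
    scale_corpus(records)
  })
}

#' Shuffle the step order of one scale
#'
#' Steps are replaced by a uniform-random permutation of themselves: the
#' step-size multiset, note count and total span are conserved exactly.
#'
#' @param record A [scale_record()].
#' @param seed Integer seed.
#' @return The record with reshuffled steps.
#' @export
shuffle_scale <- function(record, seed = NULL) {
  stopifnot(inherits(record, "scale_record"))
  with_seed(seed, {
    steps <- diff(record$notes)
    record$notes <- c(0, cumsum(sample_from(steps, length(steps))))
    record
  })
}

#' Shuffle the step order of every scale in a corpus
#'
#' @param corpus A [scale_corpus()].
#' @param seed Integer seed (one RNG stream over all records).
#' @return A [scale_corpus()] with per-scale shuffled steps.
#' @export
shuffle_corpus <- function(corpus, seed = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  with_seed(seed, scale_corpus(lapply(corpus$records, shuffle_scale)))
}

#' Resample scales from a pool of step sizes
#'
#' Each scale's steps are drawn i.i.d. with replacement from the empirical
#' step pool and arranged in the drawn order; the layout is preserved
#' exactly. By default the raw empirical multiset is used; `smooth_sd > 0`
#' draws from a Gaussian kernel-smoothed version of the pool instead
#' (each draw jittered by `N(0, smooth_sd^2)`, reflected at zero).
#'
#' @param pool Non-empty numeric vector of step sizes (cents).
#' @param layout Integer vector of notes per scale.
#' @param seed Integer seed.
#' @param smooth_sd Kernel bandwidth in cents (default 0 = no smoothing).
#' @return A [scale_corpus()].
#' @export
resample_scales <- function(pool, layout, seed = NULL, smooth_sd = 0) {
  if (length(pool) == 0L) stop("step pool must be non-empty", call. = FALSE)
  if (any(pool <= 0)) stop("steps must be positive", call. = FALSE)
  if (any(layout < 2L)) stop("layout entries must be >= 2", call. = FALSE)
  with_seed(seed, {
    records <- lapply(seq_along(layout), function(i) {
      steps <- sample_from(pool, layout[i] - 1L, replace = TRUE)
      if (smooth_sd > 0)
        steps <- abs(steps + rnorm(length(steps), 0, smooth_sd))
      null_metadata_record(sprintf("resample_%04d", i), "null_resample",
                           c(0, cumsum(steps)))
    })
    scale_corpus(records)
  })
}

#' Generate an alternative corpus under a named null model
#'
#' Convenience dispatcher used by the significance profiles: `"lognorm"`
#' fits the pooled note distribution and samples independent notes;
#' `"shuffle"` permutes each scale's steps; `"resample"` draws steps from the
#' pooled empirical step distribution. All three preserve the corpus layout.
#'
#' @param corpus A [scale_corpus()].
#' @param model `"lognorm"`, `"shuffle"` or `"resample"`.
#' @param seed Integer seed.
#' @return A [scale_corpus()] with the same layout as `corpus`.
#' @export
null_corpus <- function(corpus, model = c("lognorm", "shuffle", "resample"),
                        seed = NULL) {
  model <- match.arg(model)
  switch(model,
         lognorm = sample_lognorm_scales(fit_lognormal(corpus_notes(corpus)),
                                         corpus_layout(corpus), seed),
         shuffle = shuffle_corpus(corpus, seed),
         resample = resample_scales(corpus_steps(corpus),
                                    corpus_layout(corpus), seed))
}
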