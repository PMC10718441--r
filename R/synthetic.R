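#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure of published scale
#' databases: a few hundred scales from tens of societies spread over 8
#' regions; note counts concentrated on 5 and 7 (6 rare); step sizes peaked
#' near 200 cents and mostly within 100-400 cents; frequent exact or near
#' octaves (1200 cents) and fifths (700 cents); a subset of near-equidistant
#' scales; and a split between theory scales (exact integer-cent 12-TET
#' subsets) and measured scales (Gaussian intonation noise).
#'
#' @param n_societies Number of societies.
#' @param scales_per_society Integer range `c(min, max)`; per-society scale
#'   counts are drawn uniformly from it. A single number fixes the count.
#' @param note_count_weights Named probabilities over note counts (= steps
#'   per scale) 4..9. Defaults weight 5 and 7 heavily and make 6 rare.
#' @param step_mean,step_sd Mean and sd (cents) of the truncated-normal step
#'   distribution (defaults 200 and 55).
#' @param step_bounds_soft,step_bounds_hard Soft (bulk) and hard (truncation)
#'   step-size intervals in cents; the hard interval must contain the soft.
#' @param octave_anchor_prob Probability a measured scale is built to span
#'   exactly 1200 cents before noise (default 0.8).
#' @param fifth_anchor_prob Probability that the note nearest 700 cents is
#'   nudged to exactly 700 before noise (default 0.5).
#' @param equidistant_fraction Fraction of measured scales drawn
#'   near-equidistant: internal notes at equidistant positions plus Gaussian
#'   jitter of sd `noise_sd` (default 0.25).
#' @param octave_extension_prob Probability that an octave-anchored measured
#'   scale belongs to an instrument whose compass exceeds the octave: 1-3
#'   upper notes are appended as exact octave transpositions of the lowest
#'   non-tonic notes (default 0.5). This is the mechanism that puts exact
#'   octave *pairs* -- not just the octave note -- into measured scales,
#'   which is what the within-scale octave test detects.
#' @param theory_fraction Fraction of scales emitted as `kind = "theory"`
#'   with exact 12-TET-subset intervals (default 0.3).
#' @param noise_sd Sd (cents) of Gaussian intonation noise added to measured
#'   notes (default 10, the stated upper bound on source measurement error).
#' @param seed Default seed used by [generate_corpus()] when none is passed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_societies = 20,
                             scales_per_society = c(3, 8),
                             note_count_weights = c(`4` = 0.10, `5` = 0.35,
                                                    `6` = 0.03, `7` = 0.35,
                                                    `8` = 0.10, `9` = 0.07),
                             step_mean = 200, step_sd = 55,
                             step_bounds_soft = c(100, 400),
                             step_bounds_hard = c(60, 500),
                             octave_anchor_prob = 0.8,
                             fifth_anchor_prob = 0.5,
                             equidistant_fraction = 0.25,
                             octave_extension_prob = 0.5,
                             theory_fraction = 0.3,
                             noise_sd = 10,
                             seed = NULL) {
  if (length(scales_per_society) == 1L)
    scales_per_society <- rep(scales_per_society, 2L)
  w <- note_count_weights
  if (is.null(names(w)) || anyNA(suppressWarnings(as.integer(names(w)))))
    stop("note_count_weights must be named by note count", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8)
    stop("note_count_weights must sum to 1", call. = FALSE)
  probs <- c(octave_anchor_prob, fifth_anchor_prob, equidistant_fraction,
             octave_extension_prob, theory_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (step_bounds_hard[1] > step_bounds_soft[1] ||
      step_bounds_hard[2] < step_bounds_soft[2])
    stop("hard step bounds must contain the soft bounds", call. = FALSE)
  counts <- as.integer(names(w))
  # every anchored scale must be able to reach a 1200-cent span
  bad <- counts[counts * step_bounds_hard[1] > 1200 |
                counts * step_bounds_hard[2] < 1200]
  if (length(bad) && any(w[as.character(bad)] > 0))
    stop("infeasible config: note count(s) ", paste(bad, collapse = ", "),
         " cannot span an octave within the hard step bounds", call. = FALSE)
  structure(list(n_societies = n_societies,
                 scales_per_society = scales_per_society,
                 note_count_weights = w,
                 step_mean = step_mean, step_sd = step_sd,
                 step_bounds_soft = step_bounds_soft,
                 step_bounds_hard = step_bounds_hard,
                 octave_anchor_prob = octave_anchor_prob,
                 fifth_anchor_prob = fifth_anchor_prob,
                 equidistant_fraction = equidistant_fraction,
                 octave_extension_prob = octave_extension_prob,
                 theory_fraction = theory_fraction,
                 noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

synthetic_regions <- c("region_andes", "region_sahel", "region_maghreb",
                       "region_rift", "region_mekong", "region_ganges",
                       "region_baltic", "region_tundra")

#' Generate a synthetic scale corpus
#'
#' Deterministic given `seed`. Societies are assigned round-robin to a fixed
#' list of 8 synthetic region labels. Theory scales are exact integer-cent
#' 12-TET subsets spanning 1200 cents (avoiding the 600-cent tritone
#' position, which is rare in documented theory traditions); measured scales
#' are built from truncated-normal steps (rescaled to span 1200 when
#' octave-anchored), optionally near-equidistant, optionally fifth-anchored,
#' and then perturbed with Gaussian intonation noise.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [scale_corpus()].
#' @export
generate_corpus <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, {
    records <- list()
    sid <- 0L
    counts <- as.integer(names(config$note_count_weights))
    for (s in seq_len(config$n_societies)) {
      society <- sprintf("society_%03d", s)
      region <- synthetic_regions[((s - 1L) %% length(synthetic_regions)) + 1L]
      country <- sprintf("country_%03d", s)
      rng <- config$scales_per_society
      n_sc <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      for (k in seq_len(n_sc)) {
        sid <- sid + 1L
        nc <- sample_from(counts, 1L, prob = config$note_count_weights)
        if (runif(1) < config$theory_fraction) {
          notes <- theory_scale_notes(nc, config)
          rec <- scale_record(sprintf("scale_%04d", sid), society, region,
                              country, kind = "theory", method = "theory",
                              tonic_known = TRUE, notes = notes)
        } else {
          notes <- measured_scale_notes(nc, config)
          rec <- scale_record(sprintf("scale_%04d", sid), society, region,
                              country, kind = "measured",
                              method = if (runif(1) < 0.8) "instrument" else "song",
                              tonic_known = runif(1) < 0.3, notes = notes)
        }
        records[[sid]] <- rec
      }
    }
    scale_corpus(records)
  })
}

# exact 12-TET subset spanning the octave: a composition of 12 semitones
# into nc parts, each within the soft step bounds, avoiding a note at the
# 600-cent position. Parts are weighted toward the whole tone (2 semitones),
# the dominant step of documented theory scales.
theory_scale_notes <- function(nc, config) {
  lo <- max(1L, ceiling(config$step_bounds_soft[1] / 100))
  hi <- min(11L, floor(config$step_bounds_soft[2] / 100))
  if (nc * lo > 12 || nc * hi < 12)
    stop("infeasible theory scale: ", nc, " steps cannot sum to an octave",
         call. = FALSE)
  part_w <- c(0.20, 0.50, 0.25, 0.05, rep(0.01, 7))[lo:hi]
  for (try in 1:500) {
    parts <- sample(lo:hi, nc, replace = TRUE, prob = part_w)
    if (sum(parts) != 12L) next
    if (6L %in% cumsum(parts)[-nc]) next   # avoid the tritone note
    return(c(0, cumsum(parts)) * 100)
  }
  # deterministic fallback: near-equal composition, nudged off the tritone
  base <- rep(12 %/% nc, nc)
  extra <- 12 - sum(base)
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  cs <- cumsum(base)
  if (6L %in% cs[-nc] && nc >= 2L) {
    i <- which(cs == 6L)[1]
    if (base[i] > lo && base[i + 1L] < hi) {
      base[i] <- base[i] - 1L; base[i + 1L] <- base[i + 1L] + 1L
    } else if (base[i] < hi && base[i + 1L] > lo) {
      base[i] <- base[i] + 1L; base[i + 1L] <- base[i + 1L] - 1L
    }
  }
  c(0, cumsum(base)) * 100
}

rtruncnorm_steps <- function(n, mean, sd, bounds) {
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    draw <- rnorm(n, mean, sd)
    draw <- draw[draw >= bounds[1] & draw <= bounds[2]]
    take <- min(length(draw), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- draw[seq_len(take)]
      got <- got + take
    }
  }
  out
}

measured_scale_notes <- function(nc, config) {
  hard <- config$step_bounds_hard
  anchored <- runif(1) < config$octave_anchor_prob
  equi <- runif(1) < config$equidistant_fraction
  for (try in 1:200) {
    if (equi) {
      # near-equidistant octave scale: equidistant internal notes + jitter
      notes <- (0:nc) * 1200 / nc
      if (nc >= 2)
        notes[2:nc] <- notes[2:nc] + rnorm(nc - 1L, 0, config$noise_sd)
      notes <- c(0, sort(notes[-1L]))
    } else {
      steps <- rtruncnorm_steps(nc, config$step_mean, config$step_sd, hard)
      if (anchored) steps <- steps * 1200 / sum(steps)
      if (any(steps < hard[1] | steps > hard[2])) next
      notes <- c(0, cumsum(steps))
    }
    # fifth anchor: nudge the non-tonic, non-final note nearest 700 cents
    if (runif(1) < config$fifth_anchor_prob && nc >= 2) {
      internal <- 2:nc
      i <- internal[which.min(abs(notes[internal] - 700))]
      cand <- notes
      cand[i] <- 700
      if (all(diff(cand) > 0)) notes <- cand
    }
    # octave extension: instruments whose range exceeds the octave repeat
    # the lowest notes an octave up (exact octave pairs, before noise)
    if ((anchored || equi) && runif(1) < config$octave_extension_prob) {
      n_ext <- sample(seq_len(min(3L, nc - 1L)), 1L)
      notes <- c(notes, 1200 + notes[2:(1 + n_ext)])
    }
    # intonation noise on all non-tonic notes
    noisy <- notes
    noisy[-1L] <- noisy[-1L] + rnorm(length(notes) - 1L, 0, config$noise_sd)
    noisy <- c(0, sort(noisy[-1L]))
    st <- diff(noisy)
    if (all(st >= hard[1] & st <= hard[2])) return(noisy)
  }
  stop("could not draw a valid measured scale; check step bounds",
       call. = FALSE)
}

#' Generate an octave-locked test set
#'
#' Builds scales whose upper notes are exact octave transpositions of lower
#' notes, for measuring how intonation noise degrades octave detection.
#' Steps are sampled with replacement from `step_pool`; then every note at
#' or above 1200 cents is replaced by `candidate + 1200 * k` for the
#' non-tonic candidate note below 1200 (and integer `k >= 1`) that lands
#' nearest the original position. No noise is applied here; add it with
#' [add_intonation_noise()].
#'
#' @param config A [generator_config()] (supplies metadata conventions and
#'   the default seed).
#' @param n_scales Number of scales to build.
#' @param step_pool Non-empty numeric vector of step sizes (cents) to sample
#'   from, e.g. [corpus_steps()] of a corpus.
#' @param note_counts Candidate step counts per scale, sampled uniformly.
#'   The default `9:15` emulates fixed-pitch instruments whose compass spans
#'   roughly 1.5-2.5 octaves (xylophones, metallophones, and similar), so
#'   every scale carries several exact octave pairs.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [scale_corpus()] of `kind = "measured"` scales.
#' @export
generate_octave_locked_testset <- function(config = generator_config(),
                                           n_scales, step_pool,
                                           note_counts = 9:15,
                                           seed = config$seed) {
  if (length(step_pool) == 0L)
    stop("step_pool must be non-empty", call. = FALSE)
  if (any(step_pool <= 0))
    stop("step_pool must contain positive steps", call. = FALSE)
  with_seed(seed, {
    records <- vector("list", n_scales)
    for (i in seq_len(n_scales)) {
      nc <- sample_from(note_counts, 1L)
      steps <- sample_from(step_pool, nc, replace = TRUE)
      notes <- c(0, cumsum(steps))
      notes <- octave_lock_notes(notes)
      records[[i]] <- scale_record(sprintf("locked_%04d", i),
                                   society_id = "testset",
                                   region = "testset", country = "testset",
                                   kind = "measured", method = "instrument",
                                   tonic_known = TRUE, notes = notes)
    }
    scale_corpus(records)
  })
}

# snap notes >= 1200 to exact octave transpositions of lower non-tonic notes
octave_lock_notes <- function(notes) {
  lower <- notes[notes < 1200 & notes > 0]
  upper_idx <- which(notes >= 1200)
  if (!length(upper_idx) || !length(lower)) return(notes)
  for (i in upper_idx) {
    u <- notes[i]
    k <- pmax(1, round((u - lower) / 1200))
    cand <- lower + 1200 * k
    notes[i] <- cand[which.min(abs(cand - u))]
  }
  sort(unique(notes))
}

#' Add Gaussian intonation noise to a corpus
#'
#' Independent `N(0, sigma^2)` perturbations are added to every non-tonic
#' note; the tonic stays at 0 and monotonicity is repaired by re-sorting.
#' Deterministic given `seed`.
#'
#' @param corpus A [scale_corpus()].
#' @param sigma_noise Noise sd in cents (>= 0).
#' @param seed Integer seed.
#' @return A [scale_corpus()] with perturbed notes.
#' @export
add_intonation_noise <- function(corpus, sigma_noise, seed = NULL) {
  stopifnot(inherits(corpus, "scale_corpus"))
  if (sigma_noise < 0) stop("sigma_noise must be >= 0", call. = FALSE)
  if (sigma_noise == 0) return(corpus)
  with_seed(seed, {
    records <- lapply(corpus$records, function(r) {
      n <- r$notes
      v <- n[-1L] + rnorm(length(n) - 1L, 0, sigma_noise)
      # repair: reflect any note pushed below the tonic, then re-sort;
      # break exact collisions so notes stay strictly increasing
      v <- sort(abs(v))
      v[v < 1e-9] <- 1e-9
      while (any(dup <- c(FALSE, diff(v) <= 0)))
        v[dup] <- v[dup] + 1e-9
      r$notes <- c(0, v)
      r
    })
    scale_corpus(records)
  })
}
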