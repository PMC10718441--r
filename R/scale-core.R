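#' Convert a frequency ratio to cents
#'
#' Cents are the logarithmic pitch-interval unit: `1200 * log2(f1 / f2)`.
#' An octave (frequency ratio 2:1) is 1200 cents.
#'
#' @param f1,f2 Frequencies (Hz or any common unit); must be positive.
#' @return Interval size in cents; negative when `f1 < f2`.
#' @examples
#' cents_from_ratio(2, 1)   # octave, 1200
#' cents_from_ratio(3, 2)   # just fifth, ~701.955
#' @export
cents_from_ratio <- function(f1, f2) {
  if (any(!is.finite(f1)) || any(!is.finite(f2)) || any(f1 <= 0) || any(f2 <= 0))
    stop("frequencies must be positive and finite", call. = FALSE)
  1200 * log2(f1 / f2)
}

#' Cumulative note positions from step sizes
#'
#' Scale notes are the cumulative sums of the steps (adjacent-note
#' intervals), with the tonic at 0 cents prepended.
#'
#' @param steps Numeric vector of positive step sizes in cents.
#' @return Numeric vector of length `length(steps) + 1`, strictly increasing,
#'   starting at 0.
#' @seealso [steps_from_notes()], its inverse.
#' @export
notes_from_steps <- function(steps) {
  if (length(steps) < 1L || any(!is.finite(steps)) || any(steps <= 0))
    stop("steps must be positive finite numbers", call. = FALSE)
  c(0, cumsum(steps))
}

#' Step sizes from note positions
#'
#' @param notes Strictly increasing numeric vector of note positions in
#'   cents, starting at 0 (the tonic).
#' @return Successive differences, length `length(notes) - 1`.
#' @export
steps_from_notes <- function(notes) {
  check_notes(notes)
  diff(notes)
}

check_notes <- function(notes) {
  if (length(notes) < 2L)
    stop("a scale needs at least 2 notes", call. = FALSE)
  if (any(!is.finite(notes)))
    stop("notes must be finite", call. = FALSE)
  if (notes[1L] != 0)
    stop("the first note (tonic) must be 0 cents", call. = FALSE)
  if (any(diff(notes) <= 0))
    stop("notes must be strictly increasing", call. = FALSE)
  invisible(notes)
}

#' All pairwise intervals of a scale
#'
#' For `N` note positions this returns all `N * (N - 1) / 2` positive
#' differences `notes[j] - notes[i]`, `i < j` -- the full set of intervals
#' playable on an instrument with those notes, not just the scale notes.
#'
#' @param notes Strictly increasing numeric vector of note positions (cents).
#' @return Numeric vector (a multiset) of length `N * (N - 1) / 2`.
#' @export
all_pair_intervals <- function(notes) {
  if (length(notes) < 2L)
    stop("a scale needs at least 2 notes", call. = FALSE)
  if (any(diff(notes) <= 0))
    stop("notes must be strictly increasing", call. = FALSE)
  n <- length(notes)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  notes[j] - notes[i]
}

#' Equidistant reference scale
#'
#' Note positions of the perfectly equidistant `n`-note scale over `span`
#' cents: `k * span / n` for `k = 0..n`. The equiheptatonic scale is
#' `equidistant_reference(7)` (step 1200/7 ~ 171.43 cents).
#'
#' @param n Number of steps (>= 2).
#' @param span Total span in cents (default one octave, 1200).
#' @return Numeric vector of `n + 1` note positions including tonic and span.
#' @export
equidistant_reference <- function(n, span = 1200) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(span) || span <= 0)
    stop("`span` must be positive", call. = FALSE)
  (0:n) * span / n
}

#' Mean absolute deviation of internal notes from a reference scale
#'
#' Averages `|scale_note_i - reference_note_i|` over the internal notes only
#' (tonic and final/octave note excluded): those endpoints are fixed by
#' construction and would dilute the statistic. Used to measure how close a
#' scale is to the equidistant scale.
#'
#' @param scale_notes,reference_notes Note position vectors of equal length
#'   (including tonic and final note).
#' @return Mean absolute deviation in cents (single number).
#' @export
mean_note_deviation <- function(scale_notes, reference_notes) {
  if (length(scale_notes) != length(reference_notes))
    stop("scale and reference must have the same number of notes", call. = FALSE)
  m <- length(scale_notes)
  if (m < 3L) return(0)
  idx <- 2:(m - 1L)
  mean(abs(scale_notes[idx] - reference_notes[idx]))
}

#' Options for octave-scale inference
#'
#' @param tonic_mode How to pick the tonic: `"reported"`/`"first"` use the
#'   first note (positions are already relative to the reported tonic);
#'   `"all"` tries every note as a candidate tonic and returns one octave
#'   scale per distinct result.
#' @param fold_mode `"fold"` maps notes outside `[0, 1200]` into `[0, 1200)`
#'   by shifting by whole octaves; `"truncate"` keeps only notes in
#'   `[0, 1200 + octave_tolerance]`.
#' @param rescale If `TRUE`, spans within `1200 +/- octave_tolerance` are
#'   rescaled proportionally so the top note is exactly 1200 cents; if
#'   `FALSE` only the top note is snapped to 1200.
#' @param octave_tolerance Accepted deviation of the span from 1200 cents
#'   (default 50; larger than both measurement error and grid resolution).
#' @param merge_threshold Folded notes closer than this (cents) are merged
#'   into their mean (default 20).
#' @param min_notes Minimum number of note positions (tonic and octave
#'   included) an inferred scale must retain (default 4).
#' @return A list of class `octave_options`.
#' @export
octave_options <- function(tonic_mode = c("reported", "first", "all"),
                           fold_mode = c("fold", "truncate"),
                           rescale = TRUE,
                           octave_tolerance = 50,
                           merge_threshold = 20,
                           min_notes = 4) {
  out <- list(tonic_mode = match.arg(tonic_mode),
              fold_mode = match.arg(fold_mode),
              rescale = isTRUE(rescale),
              octave_tolerance = octave_tolerance,
              merge_threshold = merge_threshold,
              min_notes = min_notes)
  class(out) <- "octave_options"
  out
}

#' Infer octave scales from a measured scale
#'
#' Reduces a measured scale to one or more octave scales (notes in
#' `[0, 1200]`, last note exactly 1200) under the assumption that scale notes
#' repeat at the octave. Spans within `octave_tolerance` of 1200 are rescaled
#' (or snapped) to exactly 1200; wider spans are folded down by whole octaves
#' (or truncated); folded notes closer than `merge_threshold` are merged.
#'
#' @param record A [scale_record()] with `kind == "measured"`.
#' @param options An [octave_options()] list.
#' @return A list of `scale_record`s with `kind == "octave"` (possibly empty;
#'   an attribute `"reason"` explains an empty result).
#' @export
infer_octave_scale <- function(record, options = octave_options()) {
  stopifnot(inherits(record, "scale_record"))
  if (record$kind != "measured")
    stop("octave inference applies to measured scales", call. = FALSE)
  notes <- record$notes
  tonics <- switch(options$tonic_mode,
                   reported = 1L, first = 1L,
                   all = seq_along(notes))
  out <- list()
  reasons <- character(0)
  for (ti in tonics) {
    res <- infer_one_octave(notes, ti, options)
    if (is.character(res)) {
      reasons <- c(reasons, res)
      next
    }
    dup <- any(vapply(out, function(r) {
      length(r) == length(res) && all(abs(r - res) < 1e-9)
    }, logical(1)))
    if (!dup) out[[length(out) + 1L]] <- res
  }
  recs <- lapply(seq_along(out), function(i) {
    r <- record
    r$scale_id <- if (length(out) == 1L) paste0(record$scale_id, "_oct")
                  else paste0(record$scale_id, "_oct", i)
    r$kind <- "octave"
    r$notes <- out[[i]]
    r
  })
  if (length(recs) == 0L) attr(recs, "reason") <-
      paste(unique(reasons), collapse = "; ")
  recs
}

# one candidate tonic -> octave-scale notes, or a character reason on failure
infer_one_octave <- function(notes, tonic_idx, opt) {
  tol <- opt$octave_tolerance
  span <- max(notes) - notes[1]
  if (span < 1200 - tol)
    return("span below an octave; not foldable")
  if (abs(span - 1200) <= tol) {
    # near-octave span: bring it to exactly 1200, then rotate around the
    # candidate tonic under octave equivalence
    base <- notes - notes[1]
    if (opt$rescale) base <- base * 1200 / span
    else base[which.max(base)] <- 1200
    vals <- (base - base[tonic_idx]) %% 1200
  } else if (opt$fold_mode == "fold") {
    vals <- (notes - notes[tonic_idx]) %% 1200
  } else {
    rel <- notes - notes[tonic_idx]
    vals <- rel[rel >= 0 & rel <= 1200 + tol]
    if (length(vals) == 0 || abs(max(vals) - 1200) > tol)
      return("span exceeds an octave and no note near 1200 to truncate at")
    if (opt$rescale) vals <- vals * 1200 / max(vals)
    else vals[which.max(vals)] <- 1200
    vals <- pmin(vals, 1200)
  }
  vals <- sort(unique(c(0, vals)))
  if (max(vals) < 1200) vals <- c(vals, 1200)
  vals <- merge_close_notes(vals, opt$merge_threshold)
  if (is.null(vals)) return("tonic and octave merged; degenerate")
  if (length(vals) < opt$min_notes) return("too few notes after folding")
  vals
}

# merge runs of notes with successive gaps below `threshold` into their mean;
# clusters containing 0 or 1200 are anchored there. NULL if 0 and 1200 merge.
merge_close_notes <- function(vals, threshold) {
  if (threshold <= 0) return(vals)
  grp <- cumsum(c(1, diff(vals) >= threshold))
  out <- vapply(split(vals, grp), function(v) {
    has0 <- any(v == 0); has12 <- any(v == 1200)
    if (has0 && has12) return(NA_real_)
    if (has0) 0 else if (has12) 1200 else mean(v)
  }, numeric(1))
  if (anyNA(out)) return(NULL)
  unname(out)
}
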