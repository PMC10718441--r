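#' Grid-scale specification
#'
#' Defines the hypothetical universe of possible octave scales: ordered step
#' tuples on a cents grid, each step within `[step_min, step_max]`, summing
#' to `span`. Distinct orderings are distinct scales.
#'
#' @param n_notes Number of steps per scale.
#' @param resolution Grid resolution in cents (default 20).
#' @param step_min,step_max Step-size limits in cents (defaults 60 and 320);
#'   must be positive multiples of `resolution`, as must `span`.
#' @param span Total span in cents (default 1200).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(n_notes, resolution = 20, step_min = 60,
                      step_max = 320, span = 1200) {
  vals <- c(step_min, step_max, span)
  if (any(vals <= 0) || any(vals %% resolution != 0))
    stop("step_min, step_max and span must be positive multiples of the grid resolution",
         call. = FALSE)
  if (step_min > step_max) stop("step_min must be <= step_max", call. = FALSE)
  if (n_notes < 1 || n_notes != round(n_notes))
    stop("n_notes must be a positive integer", call. = FALSE)
  structure(list(n_notes = as.integer(n_notes), resolution = resolution,
                 step_min = step_min, step_max = step_max, span = span),
            class = "grid_spec")
}

grid_units <- function(spec) {
  list(lo = spec$step_min / spec$resolution,
       hi = spec$step_max / spec$resolution,
       span = spec$span / spec$resolution)
}

#' Count grid scales without enumerating them
#'
#' Dynamic-programming count of ordered step tuples on the grid: the number
#' of compositions of the span into `n_notes` bounded parts.
#'
#' @param spec A [grid_spec()].
#' @return The count (double; may exceed integer range).
#' @export
grid_scale_count <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  u <- grid_units(spec)
  if (spec$n_notes * u$lo > u$span || spec$n_notes * u$hi < u$span) return(0)
  # ways[s + 1] = number of ways to reach partial sum s
  ways <- numeric(u$span + 1)
  ways[1] <- 1
  for (k in seq_len(spec$n_notes)) {
    nxt <- numeric(u$span + 1)
    reach <- which(ways > 0) - 1L
    for (s in reach) {
      hi <- min(u$hi, u$span - s)
      if (hi < u$lo) next
      idx <- (s + u$lo):(s + hi)
      nxt[idx + 1L] <- nxt[idx + 1L] + ways[s + 1L]
    }
    ways <- nxt
  }
  ways[u$span + 1]
}

#' Materialize a grid enumeration
#'
#' Returns every ordered step tuple as a matrix row (cents). Guarded by
#' `max_rows` -- the full 7-note octave grid has over 3 million tuples; use
#' [grid_scale_stats()] for whole-grid statistics instead.
#'
#' @param spec A [grid_spec()].
#' @param max_rows Refuse to materialize more than this many tuples
#'   (default 1e6).
#' @return Numeric matrix with `n_notes` columns, one row per grid scale.
#' @export
grid_scales <- function(spec, max_rows = 1e6) {
  stopifnot(inherits(spec, "grid_spec"))
  u <- grid_units(spec)
  m <- grid_enumerate_cpp(spec$n_notes, u$lo, u$hi, u$span, max_rows)
  m * spec$resolution
}

#' Whole-grid equidistance and note statistics
#'
#' Streams over the full enumeration in one pass (nothing is materialized)
#' and reports: the tuple count, the fraction of grid scales whose internal
#' notes deviate from the equidistant reference by at most `threshold` cents
#' on average, per-internal-note position histograms (bins of one grid unit
#' centered on grid positions), and their Shannon entropies in bits.
#'
#' @param spec A [grid_spec()].
#' @param threshold Equidistance boundary in cents (default 43, the most
#'   distant real scales observed from the equiheptatonic reference).
#' @return List with `count`, `n_within`, `fraction_within`, `note_hist`
#'   (positions x internal-note matrix), `positions` (cents) and `entropy`
#'   (bits, one per internal note).
#' @export
grid_scale_stats <- function(spec, threshold = 43) {
  stopifnot(inherits(spec, "grid_spec"))
  u <- grid_units(spec)
  res <- grid_stats_cpp(spec$n_notes, u$lo, u$hi, u$span, spec$resolution,
                        threshold)
  hist <- res$note_hist
  positions <- (0:u$span) * spec$resolution
  ent <- apply(hist, 2, shannon_entropy_bits)
  list(count = res$count, n_within = res$n_within,
       fraction_within = if (res$count > 0) res$n_within / res$count else NA_real_,
       note_hist = hist, positions = positions, entropy = ent)
}

shannon_entropy_bits <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}
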