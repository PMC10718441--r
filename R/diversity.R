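#' Fraction of scales near the equidistant scale
#'
#' The fraction of scales whose internal notes deviate from the equidistant
#' reference by at most `threshold` cents on average (see
#' [mean_note_deviation()]).
#'
#' @param scales A list of note vectors, a numeric matrix (one scale per
#'   row), or a [scale_corpus()]. All scales must have the same note count
#'   and span.
#' @param threshold Boundary in cents.
#' @param span Scale span (default 1200).
#' @return The fraction in `[0, 1]`.
#' @export
equidistance_fraction <- function(scales, threshold, span = 1200) {
  notes <- as_note_matrix(scales)
  n <- ncol(notes) - 1L
  ref <- equidistant_reference(n, span)
  dev <- apply(notes, 1, mean_note_deviation, reference_notes = ref)
  mean(dev <= threshold)
}

# coerce list / matrix / corpus of uniform-note-count scales to a matrix
as_note_matrix <- function(scales) {
  if (inherits(scales, "scale_corpus"))
    scales <- lapply(scales$records, `[[`, "notes")
  if (is.matrix(scales)) return(scales)
  stopifnot(is.list(scales))
  len <- lengths(scales)
  if (length(unique(len)) != 1L)
    stop("all scales must have the same number of notes", call. = FALSE)
  do.call(rbind, scales)
}

#' Per-note-index histograms of internal note positions
#'
#' One histogram per internal note (the tonic and the final/octave note are
#' fixed and uninformative), with bins centered on multiples of `bin_width`.
#'
#' @param scales As in [equidistance_fraction()].
#' @param bin_width Bin width in cents (default 20).
#' @param range Bin-center range (default `c(0, 1200)`).
#' @return Matrix of counts: bins x internal notes; each column sums to the
#'   number of scales. Attribute `"centers"` holds the bin centers.
#' @export
note_index_histograms <- function(scales, bin_width = 20,
                                  range = c(0, 1200)) {
  notes <- as_note_matrix(scales)
  m <- ncol(notes)
  if (m < 3L) stop("scales need at least one internal note", call. = FALSE)
  centers <- seq(range[1], range[2], by = bin_width)
  out <- vapply(2:(m - 1L), function(j) {
    interval_histogram(notes[, j], bin_width, range)$counts
  }, integer(length(centers)))
  dimnames(out) <- list(NULL, paste0("note", 2:(m - 1L)))
  attr(out, "centers") <- centers
  out
}

#' Shannon entropy of note-position histograms
#'
#' Entropy in bits (log base 2) of each normalized per-note histogram;
#' `0 * log(0)` is taken as 0. A point mass has entropy 0; a uniform
#' histogram over `B` occupied bins has the maximum, `log2(B)`.
#'
#' @param histograms Count matrix from [note_index_histograms()] (or from
#'   [grid_scale_stats()]).
#' @return Numeric vector of entropies, one per column.
#' @export
note_index_entropy <- function(histograms) {
  if (length(histograms) == 0L) stop("empty histograms", call. = FALSE)
  if (is.matrix(histograms)) apply(histograms, 2, shannon_entropy_bits)
  else shannon_entropy_bits(histograms)
}

#' Sorted-step variants of a corpus
#'
#' The rearrangement that is farthest from equidistant: each scale's steps
#' are sorted ascending and all rotations of the sorted sequence are emitted
#' as scales (a scale with `k` steps yields `k` variants).
#'
#' @param corpus A [scale_corpus()].
#' @return A [scale_corpus()] of the rotated variants.
#' @export
sorted_variants <- function(corpus) {
  stopifnot(inherits(corpus, "scale_corpus"))
  records <- list()
  for (rec in corpus$records) {
    steps <- sort(diff(rec$notes))
    k <- length(steps)
    for (r in seq_len(k)) {
      rot <- steps[((seq_len(k) + r - 2L) %% k) + 1L]
      v <- rec
      v$scale_id <- sprintf("%s_sorted%02d", rec$scale_id, r)
      v$notes <- c(0, cumsum(rot))
      records[[length(records) + 1L]] <- v
    }
  }
  scale_corpus(records)
}

#' Step-shuffled variants of a corpus
#'
#' Delegates to [shuffle_corpus()]: each scale's steps in uniform-random
#' order, conserving the per-scale step multiset.
#'
#' @param corpus A [scale_corpus()].
#' @param seed Integer seed.
#' @return A [scale_corpus()].
#' @export
shuffled_variants <- function(corpus, seed = NULL) {
  shuffle_corpus(corpus, seed)
}

#' Embed scales in two dimensions and cluster them
#'
#' Maps scales with a common note count onto two dimensions with t-SNE
#' applied to their internal note vectors (distances in the embedding are
#' non-linearly related to the original cents distances but preserve
#' neighborhood ranks), then groups them with DBSCAN density clustering on
#' the embedding coordinates.
#'
#' @param corpus A [scale_corpus()] (or matrix/list of note vectors); all
#'   scales must share one note count.
#' @param eps DBSCAN neighborhood radius in embedding units (default 2).
#' @param min_samples DBSCAN core-point minimum (default 5).
#' @param perplexity t-SNE perplexity (default 30, capped at `(n - 1) / 3`).
#' @param n_iter t-SNE gradient-descent iterations (default 600).
#' @param seed Integer seed (t-SNE initialization is random).
#' @return An object of class `scale_embedding`: list with `coords`
#'   (n x 2), `cluster` (integer labels; noise is -1), `clusters` (per-cluster
#'   mean internal note positions, sizes, and region composition) and `meta`
#'   (region/society per scale when a corpus was given).
#' @export
embed_and_cluster <- function(corpus, eps = 2, min_samples = 5,
                              perplexity = 30, n_iter = 600, seed = NULL) {
  notes <- as_note_matrix(corpus)
  if (nrow(notes) < 4L) stop("need at least 4 scales", call. = FALSE)
  X <- notes[, -c(1L, ncol(notes)), drop = FALSE] # internal note vectors
  perplexity <- min(perplexity, floor((nrow(X) - 1) / 3))
  Y <- tsne_embed(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  labels <- dbscan_cluster(Y, eps = eps, min_pts = min_samples)
  meta <- NULL
  if (inherits(corpus, "scale_corpus"))
    meta <- data.frame(
      scale_id = vapply(corpus$records, `[[`, character(1), "scale_id"),
      society_id = vapply(corpus$records, `[[`, character(1), "society_id"),
      region = vapply(corpus$records, `[[`, character(1), "region"),
      stringsAsFactors = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  clusters <- lapply(ids, function(cid) {
    sel <- labels == cid
    list(id = cid, size = sum(sel),
         mean_notes = colMeans(X[sel, , drop = FALSE]),
         regions = if (!is.null(meta)) table(meta$region[sel]) else NULL)
  })
  labels[labels == 0L] <- -1L
  structure(list(coords = Y, cluster = labels, clusters = clusters,
                 meta = meta, internal_notes = X),
            class = "scale_embedding")
}

#' @export
print.scale_embedding <- function(x, ...) {
  k <- length(x$clusters)
  cat(sprintf("<scale_embedding> %d scales, %d cluster(s), %d noise point(s)\n",
              nrow(x$coords), k, sum(x$cluster == -1L)))
  for (cl in x$clusters)
    cat(sprintf("  cluster %d: %d scales; mean internal notes: %s\n",
                cl$id, cl$size,
                paste(round(cl$mean_notes), collapse = " ")))
  invisible(x)
}

#' @export
plot.scale_embedding <- function(x, ...) {
  cols <- ifelse(x$cluster == -1L, "grey", x$cluster + 1L)
  plot(x$coords, col = cols, pch = 16, xlab = "embedding 1",
       ylab = "embedding 2", ...)
  invisible(x)
}

#' Exact t-SNE embedding
#'
#' Plain (exact-gradient) t-distributed stochastic neighbor embedding to two
#' dimensions: Gaussian input affinities calibrated per point to the target
#' perplexity by bisection, Student-t output kernel, gradient descent with
#' momentum, adaptive gains and early exaggeration. Suitable for the corpus
#' sizes handled here (hundreds to a few thousand scales).
#'
#' @param X Numeric matrix, one observation per row.
#' @param perplexity Target perplexity (default 30).
#' @param n_iter Iterations (default 600).
#' @param learning_rate Gradient step size (default 200).
#' @param seed Integer seed for the random initialization.
#' @return n x 2 coordinate matrix.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 600,
                       learning_rate = 200, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity < 2) perplexity <- 2
  if (3 * perplexity >= n)
    stop("perplexity too large for ", n, " points", call. = FALSE)
  D2 <- as.matrix(dist(X))^2
  P <- perplexity_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag_until <- min(120L, n_iter %/% 4L)
    momentum <- 0.5
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= exag_until) P * 12 else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      if (it == 250L) momentum <- 0.8
      dY <- momentum * dY - learning_rate * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# per-point Gaussian bandwidths matched to target perplexity by bisection
perplexity_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - target
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' DBSCAN density clustering
#'
#' Classic density-based clustering on Euclidean distances: points with at
#' least `min_pts` neighbors within `eps` are core points; clusters are the
#' connected components of core points plus their border points; everything
#' else is noise.
#'
#' @param X Numeric matrix, one point per row.
#' @param eps Neighborhood radius.
#' @param min_pts Minimum neighborhood size (including the point itself)
#'   for a core point.
#' @return Integer labels: clusters numbered from 1, noise points 0.
#' @export
dbscan_cluster <- function(X, eps, min_pts) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n) # 0 = noise / unvisited
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cid
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}
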