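test_that("equidistance fractions count scales inside the boundary", {
  eq7 <- equidistant_reference(7)
  expect_equal(equidistance_fraction(list(eq7), threshold = 0), 1)
  diatonic <- c(0, 200, 400, 500, 700, 900, 1100, 1200)
  # the diatonic major deviates 38.10 cents: inside a 43-cent boundary,
  # outside a 30-cent one
  expect_equal(equidistance_fraction(list(eq7, diatonic), threshold = 43), 1)
  expect_equal(equidistance_fraction(list(eq7, diatonic), threshold = 30), 0.5)
  expect_error(equidistance_fraction(list(eq7, c(0, 600, 1200)),
                                     threshold = 43), "same number")
})

test_that("note-index histograms and entropies obey their identities", {
  eqs <- lapply(1:9, function(i) equidistant_reference(5))
  h <- note_index_histograms(eqs, bin_width = 20)
  expect_equal(ncol(h), 4)  # internal notes 2..5
  expect_true(all(colSums(h) == 9))
  # point-mass histograms have zero entropy
  expect_equal(unname(note_index_entropy(h)), rep(0, 4))
  # uniform over B occupied bins attains log2(B), the maximum
  expect_equal(note_index_entropy(rep(5, 16)), 4)
  counts <- c(7, 1, 0, 9, 3)
  expect_equal(note_index_entropy(counts),
               note_index_entropy(sample(counts)))
  expect_lte(note_index_entropy(counts), log2(sum(counts > 0)))
})

test_that("sorted variants are the rotations of the ascending steps", {
  r <- new_rec(c(0, cumsum(c(100, 300, 200))))
  out <- sorted_variants(scale_corpus(list(r)))
  expect_equal(length(out), 3)
  got <- lapply(out$records, function(x) diff(x$notes))
  expect_setequal(lapply(got, paste, collapse = ","),
                  list("100,200,300", "200,300,100", "300,100,200"))
  # equidistant input: k identical copies
  eq <- new_rec((0:4) * 300)
  out_eq <- sorted_variants(scale_corpus(list(eq)))
  expect_equal(length(out_eq), 4)
  for (x in out_eq$records) expect_equal(x$notes, eq$notes)
  # output count is the total number of steps
  co <- tiny_corpus()
  expect_equal(length(sorted_variants(co)), sum(corpus_layout(co) - 1))
})

test_that("shuffled variants conserve step multisets deterministically", {
  co <- tiny_corpus()
  sh1 <- shuffled_variants(co, seed = 3)
  sh2 <- shuffled_variants(co, seed = 3)
  expect_equal(as.data.frame(sh1), as.data.frame(sh2))
  for (i in seq_along(co$records))
    expect_equal(sort(diff(sh1$records[[i]]$notes)),
                 sort(diff(co$records[[i]]$notes)))
})

test_that("density clustering follows the DBSCAN definitions", {
  # fewer points than min_pts: everything is noise
  X <- matrix(c(0, 0, 10, 10, 20, 20), ncol = 2, byrow = TRUE)
  expect_equal(dbscan_cluster(X, eps = 100, min_pts = 5), rep(0L, 3))
  # duplicated points share a cluster
  Y <- rbind(matrix(0, 5, 2), matrix(50, 5, 2))
  lab <- dbscan_cluster(Y, eps = 1, min_pts = 3)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:10])), 1)
  expect_false(lab[1] == lab[6])
  expect_true(all(lab > 0))
})

test_that("embedding recovers planted clusters and neighborhood ranks", {
  set.seed(3)
  equi <- t(replicate(50, sort(1200 / 7 * (1:6) + rnorm(6, 0, 8))))
  diat <- t(replicate(50, sort(c(200, 400, 500, 700, 900, 1100) +
                                 rnorm(6, 0, 8))))
  X <- cbind(0, rbind(equi, diat), 1200)
  emb <- embed_and_cluster(X, seed = 7)
  labs <- emb$cluster
  expect_equal(sort(unique(labs[labs > 0])), c(1L, 2L))
  # each planted group lands (almost) entirely in one recovered cluster
  expect_gte(max(table(labs[1:50])), 45)
  expect_gte(max(table(labs[51:100])), 45)
  expect_false(names(which.max(table(labs[1:50]))) ==
                 names(which.max(table(labs[51:100]))))
  # embedding preserves neighborhood structure
  D1 <- as.matrix(dist(X[, 2:7]))
  D2 <- as.matrix(dist(emb$coords))
  rc <- mean(vapply(seq_len(100), function(i)
    cor(D1[i, -i], D2[i, -i], method = "spearman"), numeric(1)))
  expect_gt(rc, 0.5)
  # mixed note counts are rejected
  expect_error(embed_and_cluster(list(c(0, 600, 1200),
                                      c(0, 400, 800, 1200))), "same number")
  # per-cluster summaries carry sizes and mean note vectors
  sizes <- vapply(emb$clusters, `[[`, numeric(1), "size")
  expect_equal(sum(sizes), sum(labs > 0))
})
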