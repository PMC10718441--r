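test_that("cents arithmetic matches the defining logarithm", {
  expect_equal(cents_from_ratio(2, 1), 1200)
  expect_equal(cents_from_ratio(1, 1), 0)
  expect_equal(cents_from_ratio(3, 2), 701.955, tolerance = 1e-6)
  expect_equal(cents_from_ratio(1, 2), -1200)
  expect_error(cents_from_ratio(0, 1), "positive")
  expect_error(cents_from_ratio(2, -1), "positive")
})

test_that("steps and notes are inverse representations", {
  expect_equal(notes_from_steps(c(100, 200)), c(0, 100, 300))
  eq7 <- notes_from_steps(rep(1200 / 7, 7))
  expect_equal(eq7, (0:7) * 1200 / 7)
  expect_equal(eq7[8], 1200)
  expect_equal(steps_from_notes(c(0, 200, 400)), c(200, 200))
  expect_equal(steps_from_notes(c(0, 1200)), 1200)
  set.seed(42)
  for (i in 1:20) {
    s <- runif(sample(2:10, 1), 30, 500)
    expect_equal(steps_from_notes(notes_from_steps(s)), s)
  }
  expect_error(notes_from_steps(c(100, -5)), "positive")
  expect_error(steps_from_notes(c(0, 300, 200)), "increasing")
  expect_error(steps_from_notes(c(10, 20)), "tonic")
})

test_that("pairwise interval sets enumerate N(N-1)/2 differences", {
  expect_setequal(all_pair_intervals(c(0, 100, 300)), c(100, 300, 200))
  # brute-force double-loop oracle over a range of sizes
  set.seed(7)
  for (n in 2:30) {
    notes <- c(0, sort(runif(n - 1, 1, 3000)))
    got <- all_pair_intervals(notes)
    expect_length(got, n * (n - 1) / 2)
    brute <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      brute <- c(brute, notes[j] - notes[i])
    expect_equal(sort(got), sort(brute))
  }
  # equidistant 5-note scale: multiplicity N - k per interval width
  iv <- all_pair_intervals((0:5) * 240)
  expect_equal(as.vector(table(iv)), 5:1)
  expect_error(all_pair_intervals(c(0)), "at least 2")
})

test_that("equidistant references and note deviations behave as defined", {
  expect_equal(equidistant_reference(5, 1200), (0:5) * 240)
  expect_equal(equidistant_reference(2, 1200), c(0, 600, 1200))
  expect_equal(diff(equidistant_reference(7, 1200)),
               rep(171.428571, 7), tolerance = 1e-6)
  eq7 <- equidistant_reference(7)
  expect_equal(mean_note_deviation(eq7, eq7), 0)
  # 12-TET diatonic major vs equiheptatonic: hand-computed mean of the six
  # internal absolute deviations
  diatonic <- c(0, 200, 400, 500, 700, 900, 1100, 1200)
  expect_equal(mean_note_deviation(diatonic, eq7), 38.0952381,
               tolerance = 1e-6)
  # translation invariance of the deviation
  expect_equal(mean_note_deviation(diatonic + 50, eq7 + 50),
               mean_note_deviation(diatonic, eq7))
  expect_error(mean_note_deviation(diatonic, eq7[1:7]), "same number")
  expect_error(equidistant_reference(1, 1200), ">= 2")
})

test_that("octave inference folds, rescales and merges as specified", {
  # already an exact octave span: returned unchanged
  r <- new_rec(c(0, 200, 700, 1200))
  out <- infer_octave_scale(r)
  expect_length(out, 1)
  expect_equal(out[[1]]$notes, c(0, 200, 700, 1200))
  expect_equal(out[[1]]$kind, "octave")
  # span 1190 within tolerance: proportional rescale so steps sum to 1200
  r2 <- new_rec(c(0, 200, 700, 1190))
  out2 <- infer_octave_scale(r2)
  expect_equal(out2[[1]]$notes, c(0, 200, 700, 1190) * 1200 / 1190)
  expect_equal(sum(diff(out2[[1]]$notes)), 1200, tolerance = 1e-9)
  # note above the octave folds down and merges with an existing note
  r3 <- new_rec(c(0, 200, 700, 1200, 1400))
  out3 <- infer_octave_scale(r3)
  expect_equal(out3[[1]]$notes, c(0, 200, 700, 1200))
  # unfoldable: span far below an octave
  r4 <- new_rec(c(0, 200, 400, 700))
  out4 <- infer_octave_scale(r4)
  expect_length(out4, 0)
  expect_match(attr(out4, "reason"), "below an octave")
  # theory scales are rejected
  expect_error(infer_octave_scale(new_rec(c(0, 200, 1200), kind = "theory",
                                          method = "theory")), "measured")
})

test_that("inferred octave scales always span exactly 1200 cents", {
  co <- study_corpus(seed = 3)
  n_checked <- 0L
  for (rec in filter_corpus(co, kind = "measured")$records) {
    for (oc in infer_octave_scale(rec)) {
      expect_equal(sum(diff(oc$notes)), 1200, tolerance = 1e-6)
      expect_equal(oc$notes[1], 0)
      expect_true(all(diff(oc$notes) > 0))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50)
})

test_that("candidate-tonic mode deduplicates rotations by exact equality", {
  r <- new_rec(c(0, 240, 480, 720, 960, 1200))
  out <- infer_octave_scale(r, octave_options(tonic_mode = "all"))
  # perfectly equidistant: every rotation folds to the same octave scale
  expect_length(out, 1)
  expect_equal(out[[1]]$notes, (0:5) * 240)
  r2 <- new_rec(c(0, 200, 700, 1200))
  out2 <- infer_octave_scale(r2, octave_options(tonic_mode = "all",
                                                min_notes = 3))
  expect_gt(length(out2), 1)
  ids <- vapply(out2, function(x) paste(round(x$notes, 6), collapse = ";"),
                character(1))
  expect_false(anyDuplicated(ids) > 0)
})
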