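test_that("generator honours counts, seeds and config validation", {
  cfg <- generator_config(n_societies = 10, scales_per_society = 5)
  co <- generate_corpus(cfg, seed = 1)
  expect_equal(length(co), 50)
  expect_equal(length(co$society_index), 10)
  expect_lte(length(co$region_index), 8)
  # determinism: same seed identical, different seed different
  co2 <- generate_corpus(cfg, seed = 1)
  expect_equal(as.data.frame(co), as.data.frame(co2))
  co3 <- generate_corpus(cfg, seed = 2)
  expect_false(identical(as.data.frame(co)$notes, as.data.frame(co3)$notes))
  expect_error(generator_config(note_count_weights = c(`5` = 0.5, `7` = 0.4)),
               "sum to 1")
  expect_error(generator_config(octave_anchor_prob = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(step_bounds_hard = c(150, 400)),
               "hard step bounds")
  expect_error(generator_config(note_count_weights = c(`4` = 0.5, `25` = 0.5),
                                step_bounds_hard = c(60, 500)),
               "infeasible")
})

test_that("pooled step distribution peaks near 200 cents with few small steps", {
  co <- study_corpus(seed = 1)
  steps <- corpus_steps(co)
  expect_gt(length(steps), 800)
  h <- interval_histogram(steps, bin_width = 20, range = c(0, 600))
  modal <- h$centers[which.max(h$counts)]
  expect_gte(modal, 180)
  expect_lte(modal, 220)
  expect_lt(mean(steps < 100), 0.05)
  hard <- generator_config()$step_bounds_hard
  measured <- filter_corpus(co, kind = "measured")
  st_m <- corpus_steps(measured)
  expect_true(all(st_m >= hard[1] & st_m <= hard[2]))
})

test_that("note counts follow the configured weights (extension off)", {
  cfg <- generator_config(n_societies = 100, scales_per_society = 10,
                          octave_extension_prob = 0)
  co <- generate_corpus(cfg, seed = 5)
  counts <- corpus_layout(co) - 1L  # steps per scale
  obs <- table(factor(counts, levels = 4:9))
  gof <- chisq.test(obs, p = cfg$note_count_weights)
  expect_gt(gof$p.value, 0.01)
})

test_that("theory scales are exact noise-free 12-TET subsets", {
  co <- study_corpus(seed = 4)
  th <- filter_corpus(co, kind = "theory")
  expect_gt(length(th), 10)
  for (rec in th$records) {
    expect_true(all(rec$notes %% 100 == 0))
    expect_equal(rec$notes[length(rec$notes)], 1200)
    expect_false(600 %in% rec$notes)
  }
})

test_that("octave locking snaps upper notes to exact transpositions", {
  expect_equal(scalestats:::octave_lock_notes(c(0, 200, 700, 1250, 1930)),
               c(0, 200, 700, 1400, 1900))
  # entirely below the octave: unchanged
  expect_equal(scalestats:::octave_lock_notes(c(0, 200, 700, 1100)),
               c(0, 200, 700, 1100))
  co <- generate_corpus(generator_config(n_societies = 10,
                                         scales_per_society = 5), seed = 3)
  pool <- corpus_steps(co)
  ts <- generate_octave_locked_testset(generator_config(), 40, pool, seed = 9)
  for (rec in ts$records) {
    upper <- rec$notes[rec$notes >= 1200]
    lower <- rec$notes[rec$notes < 1200 & rec$notes > 0]
    for (u in upper)
      expect_true(any(abs((u - lower) %% 1200) < 1e-9 |
                      abs((u - lower) %% 1200 - 1200) < 1e-9))
  }
  expect_error(generate_octave_locked_testset(generator_config(), 5,
                                              numeric(0)), "non-empty")
})

test_that("intonation noise is zero-safe, recoverable and additive", {
  co <- tiny_corpus()
  expect_identical(add_intonation_noise(co, 0, seed = 1), co)
  # empirical sd of the injected perturbations over many notes
  big <- scale_corpus(lapply(1:500, function(i)
    new_rec((0:20) * 200, id = sprintf("n%03d", i))))
  noisy <- add_intonation_noise(big, 10, seed = 7)
  d <- unlist(lapply(seq_len(500), function(i)
    noisy$records[[i]]$notes[-1] - big$records[[i]]$notes[-1]))
  expect_gt(length(d), 9999)
  expect_gte(sd(d), 9.7)
  expect_lte(sd(d), 10.3)
  # two independent noise passes: variances add
  twice <- add_intonation_noise(noisy, 10, seed = 8)
  d2 <- unlist(lapply(seq_len(500), function(i)
    twice$records[[i]]$notes[-1] - big$records[[i]]$notes[-1]))
  expect_equal(var(d2), 200, tolerance = 0.1 * 200)
  expect_error(add_intonation_noise(co, -1), ">= 0")
})
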