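test_that("windowed deviations pick exactly the intervals near the target", {
  # intervals of [0, 500, 1200] are 500, 700, 1200; only 1200 is within 100
  expect_equal(windowed_deviations(c(0, 500, 1200), 1200, 100), 0)
  expect_length(windowed_deviations(c(0, 200, 400), 2000, 100), 0)
  set.seed(8)
  for (i in 1:10) {
    notes <- c(0, sort(runif(6, 50, 2000)))
    d <- windowed_deviations(notes, 700, 100)
    expect_true(all(d <= 100))
    expect_true(all(d >= 0))
  }
})

test_that("Mann-Whitney p-values match the brute-force permutation oracle", {
  set.seed(10)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:8, 1)
    x <- round(runif(n1, 0, 50))  # rounding forces ties
    y <- round(runif(n2, 0, 50))
    got <- mwu_test(x, y)
    oracle <- mwu_exact_oracle(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$statistic, oracle$statistic)
    expect_equal(got$p_value, oracle$p_value)
  }
  # tie-free exact case agrees with the independent wilcox.test implementation
  set.seed(11)
  for (i in 1:6) {
    x <- runif(5); y <- runif(6)
    got <- mwu_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  # large samples: normal approximation path tracks wilcox.test
  set.seed(12)
  x <- rnorm(40); y <- rnorm(45, 0.3)
  got <- mwu_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$method, "normal")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  # Monte-Carlo permutation path approximates the exact answer
  set.seed(13)
  x <- runif(3); y <- runif(14)
  mc <- mwu_test(x, y, n_mc = 20000)
  ex <- mwu_test(x, y, exact_max = 20)
  expect_equal(mc$method, "mc_permutation")
  expect_equal(mc$p_value, ex$p_value, tolerance = 0.05)
  expect_error(mwu_test(numeric(0), 1), "non-empty")
})

test_that("within-scale octave test separates locked scales from equidistant ones", {
  # perfectly equidistant: shuffles are identical, the test carries no
  # information and reports p = 1
  eq <- new_rec(notes_from_steps(rep(1200 / 7, 7)))
  res_eq <- within_scale_test(eq, 1200, n_repeat = 20, seed = 1)
  expect_true(res_eq$tested)
  expect_equal(res_eq$mean_p, 1)
  expect_false(res_eq$significant)
  # octave-locked 13-note scale with heterogeneous steps: six exact octave
  # pairs that shuffling destroys
  lower <- c(0, 130, 330, 540, 760, 950, 1130)
  locked <- new_rec(sort(c(lower, lower[2:7] + 1200)))
  res <- within_scale_test(locked, 1200, seed = 2)
  expect_true(res$significant)
  expect_equal(res$direction, "closer")
  expect_lt(res$mean_p, 0.01)
  expect_lt(res$mean_dev_orig, res$mean_dev_shuffled)
  # doubling the shuffle count leaves the verdict unchanged
  res100 <- within_scale_test(locked, 1200, n_shuffle = 100, seed = 3)
  expect_true(res100$significant)
  # no interval in window: untested
  far <- within_scale_test(new_rec(c(0, 200, 400)), 2600, seed = 4)
  expect_false(far$tested)
  expect_true(is.na(far$mean_p))
})

test_that("interval sweep aggregates per-target fractions and ignores metadata", {
  expect_equal(nrow(interval_sweep(scale_corpus(list()), seed = 1)), 121)
  co <- scale_corpus(lapply(1:10, function(i) {
    lower <- c(0, 130, 330, 540, 760, 950, 1130)
    lower[-1] <- lower[-1] + (i - 1)  # distinct but structurally identical
    new_rec(sort(c(lower, lower[2:7] + 1200)),
            id = paste0("L", i), society = paste0("s", i))
  }))
  sw <- interval_sweep(co, targets = c(700, 1200, 2500), n_repeat = 10,
                       seed = 5)
  expect_s3_class(sw, "interval_sweep")
  expect_true(all(sw$frac_closer + sw$frac_farther <= 1))
  expect_equal(sw$n_tested[sw$target == 1200], 10)
  expect_gt(sw$frac_closer[sw$target == 1200], 0.5)
  # relabeling societies does not change the result
  relabeled <- scale_corpus(lapply(co$records, function(r) {
    r$society_id <- "all_one"; r
  }))
  sw2 <- interval_sweep(relabeled, targets = c(700, 1200, 2500),
                        n_repeat = 10, seed = 5)
  expect_equal(as.data.frame(sw), as.data.frame(sw2))
})

test_that("null calibration produces a band that brackets its own mean", {
  co <- calibration_corpus(n_scales = 40)
  cal <- null_calibration(co, targets = seq(400, 1200, by = 200),
                          n_repeat = 5, n_null_sets = 10, seed = 6)
  expect_true(all(cal$band$lo <= cal$band$mean + 1e-9))
  expect_true(all(cal$band$hi >= cal$band$mean - 1e-9))
  expect_gte(cal$mean_significant_fraction, 0)
  expect_lt(cal$mean_significant_fraction, 0.2)
  expect_error(null_calibration(co, n_null_sets = 5), ">= 10")
})

test_that("octave detection degrades from near-ceiling to chance with noise", {
  co <- study_corpus(seed = 1)
  pool <- corpus_steps(filter_corpus(co, kind = "measured"))
  nc <- noise_sensitivity_curve(pool, n_scales = 60,
                                sigma_grid = c(0, 50, 300), n_repeat = 20,
                                seed = 7)
  expect_s3_class(nc, "noise_curve")
  expect_gt(nc$frac_closer[nc$sigma == 0], 0.7)
  expect_lt(nc$frac_closer[nc$sigma == 300], 0.15)
  expect_true(all(diff(nc$frac_closer) <= 0))
  expect_true(all(nc$ci_low <= nc$frac_closer + 1e-9 &
                    nc$frac_closer <= nc$ci_high + 1e-9))
})
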