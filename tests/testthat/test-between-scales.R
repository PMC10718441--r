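test_that("balanced subsampling caps every society at the limit", {
  recs <- list()
  for (s in 1:30) for (k in 1:10)
    recs[[length(recs) + 1]] <- new_rec(c(0, 200, 400, 700),
                                        id = sprintf("s%02d_%02d", s, k),
                                        society = sprintf("soc%02d", s))
  co <- scale_corpus(recs)
  sub <- balanced_subsample(co, 5, seed = 1)
  expect_equal(length(sub), 150)
  expect_true(all(lengths(sub$society_index) == 5))
  # a society under the cap keeps everything
  small <- scale_corpus(recs[1:3])
  expect_equal(length(balanced_subsample(small, 5, seed = 1)), 3)
  # a 12-record society is cut to exactly 5
  one <- scale_corpus(lapply(1:12, function(i)
    new_rec(c(0, 50 * i, 1200), id = paste0("r", i), society = "only")))
  expect_equal(length(balanced_subsample(one, 5, seed = 2)), 5)
  # cap respected across many reseeds
  for (sd in 1:20)
    expect_true(all(lengths(balanced_subsample(co, 5,
                                               seed = sd)$society_index) <= 5))
})

test_that("histogram bins are centered on multiples of the width", {
  h <- interval_histogram(c(1200, 1200, 700), bin_width = 30,
                          range = c(0, 2700))
  expect_equal(h$counts[h$centers == 1200], 2)
  # 700 falls in [675, 705), the bin centered at 690
  expect_equal(h$counts[h$centers == 690], 1)
  expect_equal(h$counts[h$centers == 720], 0)
  expect_equal(sum(interval_histogram(numeric(0), 30, c(0, 300))$counts), 0)
  set.seed(4)
  v <- runif(500, 0, 2700)
  expect_equal(sum(interval_histogram(v, 30, c(0, 2700))$counts), 500)
  expect_error(interval_histogram(1, 0), "positive")
  expect_error(interval_histogram(1, 30, c(0, 100)), "multiples")
})

test_that("lognormal bin probabilities integrate the fitted density", {
  params <- fit_lognormal(rlnorm(50, log(600), 0.5))
  # one huge bin covering the whole positive axis
  expect_equal(lognorm_bin_probabilities(params, 5e5, 1e6), 1,
               tolerance = 1e-6)
  # Monte-Carlo cross-check of one narrow bin
  p <- lognorm_bin_probabilities(structure(list(mu = log(600), sigma = 0.5),
                                           class = "lognorm_params"),
                                 600, 30)
  set.seed(9)
  draws <- rlnorm(1e6, log(600), 0.5)
  phat <- mean(draws >= 585 & draws < 615)
  expect_lt(abs(p - phat), 3 * sqrt(p * (1 - p) / 1e6))
  expect_error(lognorm_bin_probabilities(structure(list(mu = 1, sigma = 0),
                                                   class = "lognorm_params"),
                                         600, 30), "degenerate")
})

test_that("empirical bin probabilities are proportions that sum to one", {
  # shuffling an all-equidistant corpus is the identity: model probabilities
  # equal the observed note proportions exactly
  co <- scale_corpus(lapply(1:6, function(i)
    new_rec((0:5) * 240, id = paste0("e", i))))
  centers <- seq(0, 1500, by = 30)
  p <- empirical_bin_probabilities("shuffle", co, centers, 30, n_sets = 5,
                                   seed = 1)
  obs <- interval_histogram(corpus_notes(co), 30, c(0, 1500))
  expect_equal(p, obs$counts / sum(obs$counts))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  p2 <- empirical_bin_probabilities("resample", tiny_corpus(),
                                    seq(0, 2700, 30), 30, n_sets = 100,
                                    seed = 2)
  expect_equal(sum(p2), 1, tolerance = 0.02)
})

test_that("binomial tails match their closed forms and sum correctly", {
  bt <- binomial_tail_test(10, 10, 0.5)
  expect_equal(bt$q_tail, 0.5^10)
  expect_equal(bt$direction, "more")
  bt2 <- binomial_tail_test(0, 5, 0.2)
  expect_equal(bt2$q_tail, 0.8^5)
  expect_equal(bt2$direction, "less")
  bt3 <- binomial_tail_test(7, 7, 1)
  expect_equal(bt3$q_tail, 1)
  expect_equal(bt3$direction, "less")
  # upper and lower tails at the same k overlap in exactly pmf(k)
  for (k in 0:12) {
    up <- pbinom(k - 1, 12, 0.3, lower.tail = FALSE)
    lo <- pbinom(k, 12, 0.3)
    expect_equal(up + lo, 1 + dbinom(k, 12, 0.3))
  }
  expect_error(binomial_tail_test(5, 3, 0.5), "\\[0, n\\]")
})

test_that("significance profile is internally consistent on a small corpus", {
  co <- study_corpus(seed = 2)
  prof <- significance_profile(co, "lognorm", n_resamples = 100,
                               n_sets = 50, n_boot = 100, seed = 3)
  expect_s3_class(prof, "significance_profile")
  expect_equal(nrow(prof), 91)
  expect_true(all(prof$p >= 0 & prof$p <= 1))
  expect_true(all(prof$q_tail >= 0 & prof$q_tail <= 1))
  expect_lte(sum(prof$k), attr(prof, "n"))
  expect_equal(attr(prof, "alpha_bonferroni"), 0.05 / 91)
  expect_true(all((prof$direction == "more") ==
                    (prof$k / attr(prof, "n") > prof$p)))
  expect_true(all(prof$ci_low <= prof$ci_high))
  # a corpus generated from its own fitted lognormal shows no significant bins
  params <- fit_lognormal(corpus_notes(co))
  self <- sample_lognorm_scales(params, corpus_layout(co), seed = 4)
  prof_self <- significance_profile(self, "lognorm", n_resamples = 100,
                                    n_sets = 50, n_boot = 100, seed = 5)
  expect_equal(sum(prof_self$significant), 0)
})

test_that("all-identical scales under the shuffle model are never flagged", {
  co <- scale_corpus(lapply(1:8, function(i)
    new_rec((0:5) * 240, id = paste0("q", i), society = paste0("s", i))))
  prof <- significance_profile(co, "shuffle", bin_width = 30,
                               range = c(0, 1500), n_resamples = 50,
                               n_sets = 50, n_boot = 50, seed = 6)
  # shuffling identical equidistant scales is the identity, so observed
  # proportions equal the model probabilities (to rounding) and nothing
  # comes close to significance
  expect_equal(prof$p[prof$k > 0], prof$k[prof$k > 0] / attr(prof, "n"),
               tolerance = 1e-9)
  expect_true(all(prof$q_tail[prof$k > 0] > 0.5))
  expect_equal(sum(prof$significant), 0)
})
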