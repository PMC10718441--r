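# shared fixtures, built in code at test time

new_rec <- function(notes, id = "s1", society = "soc1", region = "reg1",
                    kind = "measured", method = "instrument") {
  scale_record(id, society, region, "country1", kind = kind,
               method = method, tonic_known = TRUE, notes = notes)
}

# a small deterministic corpus of hand-written scales
tiny_corpus <- function() {
  scale_corpus(list(
    new_rec(c(0, 204, 702, 1200), id = "t1", society = "socA", kind = "theory",
            method = "theory"),
    new_rec(c(0, 200, 400, 500, 700, 900, 1100, 1200), id = "t2",
            society = "socA", kind = "theory", method = "theory"),
    new_rec(c(0, 171.4, 342.9, 514.3, 685.7, 857.1, 1028.6, 1200), id = "m1",
            society = "socB"),
    new_rec(c(0, 240, 480, 720, 960, 1200), id = "m2", society = "socB"),
    new_rec(c(0, 185, 390, 605, 790, 1010, 1195), id = "m3", society = "socC")
  ))
}

# the default synthetic study corpus used by the structural checks
study_corpus <- function(seed = 1) {
  generate_corpus(generator_config(n_societies = 25, scales_per_society = 6),
                  seed = seed)
}

# corpus matching the null-calibration study conditions: ~150 scales with
# 4-9 steps drawn from a truncated normal (mean 200, sd 55, bounds [60, 500])
calibration_corpus <- function(seed = 11, n_scales = 150) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    nsteps <- sample(4:9, n_scales, replace = TRUE)
    rtnorm <- function(n) {
      st <- numeric(0)
      while (length(st) < n) {
        d <- rnorm(3 * n, 200, 55)
        st <- c(st, d[d >= 60 & d <= 500])
      }
      st[seq_len(n)]
    }
    recs <- lapply(seq_len(n_scales), function(i)
      new_rec(c(0, cumsum(rtnorm(nsteps[i]))), id = sprintf("cal%03d", i),
              society = sprintf("soc%02d", (i %% 25) + 1)))
    scale_corpus(recs)
  })
}

# independent brute-force oracle: exact two-sided Mann-Whitney permutation
# p-value by enumerating every assignment of the pooled values
mwu_exact_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  u_of <- function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  list(statistic = obs,
       p_value = mean(abs(us - mu) >= abs(obs - mu) - 1e-9))
}

# independent closed-form oracle for the grid-scale count:
# inclusion-exclusion over compositions with bounded parts (grid units)
grid_count_oracle <- function(n, lo_u, hi_u, span_u) {
  U <- span_u - n * lo_u
  if (U < 0 || span_u > n * hi_u) return(0)
  m <- hi_u - lo_u
  j <- 0:n
  terms <- (-1)^j * choose(n, j) * choose(U - j * (m + 1) + n - 1, n - 1)
  terms[U - j * (m + 1) < 0] <- 0
  sum(terms)
}
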