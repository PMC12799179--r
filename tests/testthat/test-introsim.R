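# The forward simulator, the pool-seq noise model and the closed-form
# backcross expectation.

test_that("synthetic cross is the parental mean, symmetric, fixation-preserving", {
  expect_equal(synthetic_cross(0.598, 0), 0.299)
  expect_equal(synthetic_cross(c(0, 1), c(0, 1)), c(0, 1))
  p <- c(0.2, 0.7, 0.05)
  q <- c(0.9, 0.1, 0.5)
  expect_identical(synthetic_cross(p, q), synthetic_cross(q, p))
  expect_error(synthetic_cross(c(0.1, 0.2), 0.5), "equal length")
  expect_error(synthetic_cross(1.2, 0.5), "\\[0, 1\\]")
})

test_that("expected backcross frequency follows the ancestry-halving recurrence", {
  # independent oracle: iterate the halving of donor ancestry explicitly
  recur <- function(p_vt, p_sk, n) {
    f <- (p_vt + p_sk) / 2
    for (i in seq_len(n)) f <- (f + p_vt) / 2
    f
  }
  for (n in c(0L, 1L, 3L, 8L))
    expect_equal(expected_backcross_frequency(0.598, 0, n), recur(0.598, 0, n))
  # zero backcrosses = the F1 itself
  expect_equal(expected_backcross_frequency(0.3, 0.8, 0),
               synthetic_cross(0.3, 0.8))
  # identical parents are a fixed point for any number of events
  expect_equal(expected_backcross_frequency(0.42, 0.42, 5), 0.42)
  # the design value: 8 backcross events from AF 0.598 against a fixed donor
  expect_equal(expected_backcross_frequency(0.598, 0, 8),
               0.598 * (1 - 1 / 512), tolerance = 1e-12)
})

test_that("two-step binomial noise is degenerate at fixation and deterministic under a seed", {
  d0 <- poolseq_noise(rep(0, 50), 30, 85)
  expect_true(all(d0$alt == 0) && all(d0$total == 85))
  d1 <- poolseq_noise(rep(1, 50), 30, 85)
  expect_true(all(d1$alt == 85))
  a <- poolseq_noise(rep(0.5, 100), 30, 85, seed = 99)
  b <- poolseq_noise(rep(0.5, 100), 30, 85, seed = 99)
  expect_identical(a, b)
  expect_error(poolseq_noise(0.5, 0, 85), ">= 1")
  expect_error(poolseq_noise(-0.1, 30, 85), "\\[0, 1\\]")
})

test_that("pool noise read frequencies are unbiased for the true frequency", {
  set.seed(11)
  for (p in c(0.1, 0.5, 0.9)) {
    n_draws <- 2e4
    d <- poolseq_noise(rep(p, n_draws), 30, 85)
    f <- d$alt / d$total
    se <- sqrt(p * (1 - p) * (1 / 60 + (1 - 1 / 60) / 85) / n_draws)
    expect_lt(abs(mean(f) - p), 3 * se)
  }
})

test_that("drift envelope threshold is the nearest-rank quantile", {
  expect_equal(unname(build_envelope(list(w = rep(3.7, 10)), 0.95)), 3.7)
  # enumeration oracle: 95th order statistic of 1..100
  expect_equal(unname(build_envelope(list(w = sample(1:100)), 0.95)), 95)
  m <- matrix(1:20, nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  th <- build_envelope(m, 0.5)
  expect_named(th, c("a", "b"))
  expect_equal(unname(th["a"]), sort(1:10)[5])
  expect_error(build_envelope(list(w = 1), 0.95), ">= 2")
})

test_that("the backcross design runs to completion under the experimental constants", {
  w <- toy_window(3)
  tr <- simulate_introgression(w, sim_params(), p_vt = c(0.598, 0.3, 0.9),
                               p_sk = c(0, 0.7, 0.1), seed = 5)
  expect_s3_class(tr, "trajectory_result")
  expect_identical(nrow(tr$freq), 17L)        # generations 0..16
  expect_true(all(tr$freq >= 0 & tr$freq <= 1))
  expect_identical(length(tr$alt), 3L)
  expect_true(all(tr$alt <= tr$total))
  # full determinism under a fixed seed
  tr2 <- simulate_introgression(w, sim_params(), p_vt = c(0.598, 0.3, 0.9),
                                p_sk = c(0, 0.7, 0.1), seed = 5)
  expect_identical(tr$freq, tr2$freq)
  expect_identical(tr$alt, tr2$alt)
  expect_error(simulate_introgression(w, sim_params(), c(0.5), c(0.5),
                                      mode = "nope"))
})

test_that("drift without introgression is a martingale in the mean", {
  w <- toy_window(2)
  p0 <- c(0.35, 0.6)
  set.seed(21)
  fin <- replicate(150, simulate_introgression(
    w, sim_params(), p_vt = p0, p_sk = p0, mode = "drift_only")$freq[17L, ])
  for (j in 1:2) {
    se <- stats::sd(fin[j, ]) / sqrt(ncol(fin))
    expect_lt(abs(mean(fin[j, ]) - p0[j]), 3.5 * se)
  }
})

test_that("expected heterozygosity decays through drift and bottlenecks", {
  w <- toy_window(2)
  set.seed(31)
  runs <- replicate(60, {
    tr <- simulate_introgression(w, sim_params(), p_vt = c(0.5, 0.5),
                                 p_sk = c(0.5, 0.5), mode = "drift_only")
    c(h0 = mean(2 * tr$freq[1L, ] * (1 - tr$freq[1L, ])),
      h16 = mean(2 * tr$freq[17L, ] * (1 - tr$freq[17L, ])))
  })
  expect_lt(mean(runs["h16", ]), mean(runs["h0", ]))
})

test_that("neutral introgression converges on the backcross recurrence mean", {
  w <- toy_window(2)
  p_vt <- c(1, 0.598); p_sk <- c(0, 0)
  expected <- expected_backcross_frequency(p_vt, p_sk, 8)
  set.seed(41)
  fin <- replicate(200, simulate_introgression(
    w, sim_params(), p_vt, p_sk, mode = "neutral_introgression")$freq[17L, ])
  for (j in 1:2) {
    se <- stats::sd(fin[j, ]) / sqrt(ncol(fin))
    expect_lt(abs(mean(fin[j, ]) - expected[j]), 3.5 * se)
  }
})

test_that("simulation parameter validation enforces the design invariants", {
  expect_error(sim_params(bottleneck_fraction = 1), "strictly in")
  expect_error(sim_params(n_migrants = 2000), "carrying_capacity")
  expect_error(sim_params(pool_diploids = 0), ">=")
  expect_error(window_spec("2R", 10, 5, 1e-8, 7))
  expect_error(window_spec("2R", 1, 100, 1e-8, 500), "inside")
  w <- window_spec("2R", 100, 399, 1e-8, c(150, 300))
  expect_equal(w$length, 300)
})
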