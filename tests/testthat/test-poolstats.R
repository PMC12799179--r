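# Effective coverage, the pool-seq FST estimator, PCA and the
# parent-distance introgression metric.

test_that("effective coverage follows n*r/(n+r) with its limits", {
  expect_equal(effective_coverage(60, 85), 60 * 85 / 145)
  expect_equal(effective_coverage(60, 60), 30)
  expect_lt(abs(effective_coverage(60, 1e9) - 60), 1e-5)
  # monotone in both arguments, bounded by the smaller of the two
  expect_true(effective_coverage(60, 90) > effective_coverage(60, 85))
  expect_true(effective_coverage(80, 85) > effective_coverage(60, 85))
  expect_lt(effective_coverage(60, 85), 60)
  expect_error(effective_coverage(1, 85), ">= 2")
})

test_that("pool sample construction validates counts", {
  s <- pool_sample("x", "F16", c(3, 0), c(10, 8), 60)
  expect_equal(s$n_e, effective_coverage(60, c(10, 8)))
  expect_error(pool_sample("x", "F16", 5, 3, 60), "alt <= total")
})

test_that("FST is near zero for pools drawn from one population", {
  set.seed(101)
  n_sites <- 1e4
  g1 <- rbinom(n_sites, 60, 0.5); g2 <- rbinom(n_sites, 60, 0.5)
  c1 <- rbinom(n_sites, 85, g1 / 60); c2 <- rbinom(n_sites, 85, g2 / 60)
  r <- pairwise_fst(pool_sample("a", "F16", c1, rep(85, n_sites), 60),
                    pool_sample("b", "F16", c2, rep(85, n_sites), 60))
  m <- mean(r$per_site$fst, na.rm = TRUE)
  se <- stats::sd(r$per_site$fst, na.rm = TRUE) /
    sqrt(sum(!is.na(r$per_site$fst)))
  expect_lt(abs(m), 3 * se)
})

test_that("a fixed difference yields FST near one", {
  n <- 1000
  a <- pool_sample("a", "F16", rep(n, 200), rep(n, 200), n)
  b <- pool_sample("b", "parent_VT", rep(0, 200), rep(n, 200), n)
  expect_gte(pairwise_fst(a, b)$global, 0.99)
})

test_that("pool FST matches the genotype-level Weir-Cockerham oracle", {
  set.seed(202)
  d <- sim_divergent_pools(4000, fst = 0.2)
  est <- pairwise_fst(d$a, d$b)$global
  wc <- wc_fst_haploid(d$p1, d$p2, 60)
  expect_lt(abs(est - 0.2) / 0.2, 0.10)   # within 10% of the target value
  expect_lt(abs(est - wc), 0.02)          # < 2% absolute bias vs the oracle
})

test_that("FST is invariant to allele-label swaps and windows bound per-site values", {
  set.seed(33)
  alt1 <- rbinom(300, 85, 0.4); alt2 <- rbinom(300, 85, 0.6)
  tot <- rep(85, 300)
  a <- pool_sample("a", "F16", alt1, tot, 60)
  b <- pool_sample("b", "parent_VT", alt2, tot, 60)
  r <- pairwise_fst(a, b)
  a_sw <- pool_sample("a", "F16", tot - alt1, tot, 60)
  b_sw <- pool_sample("b", "parent_VT", tot - alt2, tot, 60)
  expect_equal(pairwise_fst(a_sw, b_sw)$per_site$fst, r$per_site$fst)
  win <- rep(c("w1", "w2", "w3"), each = 100)
  rw <- pairwise_fst(a, b, windows = win)$by_window
  for (i in seq_len(nrow(rw))) {
    site_vals <- r$per_site$fst[win == rw$window[i]]
    site_vals <- site_vals[!is.na(site_vals)]
    expect_gte(rw$fst[i], min(site_vals))
    expect_lte(rw$fst[i], max(site_vals))
  }
  expect_error(pairwise_fst(a, pool_sample("c", "F16", 1, 10, 60)), "aligned")
})

test_that("PCA separates constructed clusters and reports PVE", {
  set.seed(44)
  base <- matrix(runif(40, 0.2, 0.8), nrow = 1)
  vt_like <- base[rep(1, 3), ] + rnorm(120, 0, 0.01)
  sk_like <- (1 - base)[rep(1, 3), ] + rnorm(120, 0, 0.01)
  mid <- (base + (1 - base))[rep(1, 2), ] / 2 + rnorm(80, 0, 0.01)
  freq <- pmin(pmax(rbind(vt_like, mid, sk_like), 0), 1)
  rownames(freq) <- c("vt1", "vt2", "vt3", "m1", "m2", "sk1", "sk2", "sk3")
  pc <- pca_global(freq)
  expect_s3_class(pc, "pca_result")
  # PC1 orders the clusters monotonically
  pc1 <- pc$scores[, 1]
  mid_val <- mean(pc1[c("m1", "m2")])
  expect_true((mean(pc1[1:3]) < mid_val && mid_val < mean(pc1[6:8])) ||
                (mean(pc1[1:3]) > mid_val && mid_val > mean(pc1[6:8])))
  # rank-1 structure -> PC1 explains nearly everything
  expect_gt(pc$pve[1], 99 * (1 - 0.01))
  expect_true(all(diff(pc$pve) <= 1e-8))
  # duplicated samples land on the same coordinates
  dup <- freq[c(1, 1, 4, 6, 7), ]
  rownames(dup) <- paste0("s", 1:5)
  pd <- pca_global(dup)
  expect_equal(unname(pd$scores[1, ]), unname(pd$scores[2, ]))
  expect_error(pca_global(freq[1:2, ]), "3 samples")
})

test_that("sliding-window PCA respects window bounds and skips thin windows", {
  set.seed(55)
  freq <- matrix(runif(8 * 30), nrow = 8,
                 dimnames = list(paste0("s", 1:8), NULL))
  pos <- c(seq(1000, 90000, length.out = 25), seq(150001, 150005, length.out = 5))
  freq[, 26:30] <- 0.5   # monomorphic: second region has no polymorphic sites
  expect_message(res <- pca_sliding(freq, pos, window_size = 1e5, step = 5e4),
                 "skipping")
  expect_true(length(res) >= 1L)
  expect_s3_class(res[[1]], "pca_result")
})

test_that("parent distance ratio encodes similarity with the documented sign", {
  sc <- matrix(c(0, 0,   10, 0,  5, 0,  9, 0,  0, 0),
               ncol = 2, byrow = TRUE)
  rownames(sc) <- c("SK", "VT", "mid", "near_vt", "on_sk")
  pc <- structure(list(scores = sc, pve = c(90, 10), window = "global"),
                  class = "pca_result")
  r <- parent_distance_ratio(pc, "VT", "SK", c("mid", "near_vt"))
  expect_equal(unname(r["mid"]), 0)
  # 90% of the way to VT: d_SK/d_VT = 9
  expect_equal(unname(r["near_vt"]), log2(9), tolerance = 1e-12)
  # swapping parent labels flips the sign
  r_sw <- parent_distance_ratio(pc, "SK", "VT", c("mid", "near_vt"))
  expect_equal(unname(r_sw), -unname(r))
  expect_warning(r0 <- parent_distance_ratio(pc, "VT", "SK", "on_sk"),
                 "sentinel")
  expect_identical(unname(r0), -Inf)
  expect_error(parent_distance_ratio(pc, "VT", "SK", "ghost"), "absent")
})
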