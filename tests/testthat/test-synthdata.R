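# Synthetic-data generators: parental pools, selected F16 pools, seasonal
# series, line panels and expression counts.

test_that("parental scenarios place focal loci and validate them", {
  wm <- window_map("2R", 1, 1e5, 1e-8)
  focal <- data.frame(window = wm$window[1], site = 3L, vt_freq = 0.598,
                      sk_freq = 1, selection_strength = 0)
  sc <- parental_scenario(wm, snps_per_window = 10L, focal = focal, seed = 7)
  expect_identical(sc$n_snps, nrow(sc$sites))
  expect_equal(sc$vt_freqs[3], 0.598)
  expect_equal(sc$sk_freqs[3], 1)
  expect_true(all(sc$vt_freqs >= 0 & sc$vt_freqs <= 1))
  # background spectrum is truncated away from fixation
  expect_true(all(sc$vt_freqs[-3] >= 0.05 & sc$vt_freqs[-3] <= 0.95))
  bad <- focal; bad$site <- 99L
  expect_error(parental_scenario(wm, 10L, bad), "outside")
  bad2 <- focal; bad2$window <- "nope"
  expect_error(parental_scenario(wm, 10L, bad2), "not in window map")
})

test_that("parental pools are noiseless at fixed sites and unbiased elsewhere", {
  wm <- window_map("2R", 1, 1e6, 1e-8)
  focal <- data.frame(window = wm$window[1], site = 1L, vt_freq = 0.05,
                      sk_freq = 1, selection_strength = 0)
  sc <- parental_scenario(wm, snps_per_window = 400L, focal = focal, seed = 3)
  sc$vt_freqs[-1] <- 0.598   # homogeneous truth for the unbiasedness check
  pools <- gen_parental_pools(sc, depth = 85, seed = 17)
  # fixed allele, no sampling variance
  expect_identical(pools$sk$alt[1], 85)
  expect_identical(pools$sk$total[1], 85)
  # mean read frequency across sites within 3 MC SE of the truth 0.598
  f <- pools$vt$alt[-1] / pools$vt$total[-1]
  se <- sqrt(0.598 * 0.402 * (1 / 60 + (1 - 1 / 60) / 85) / length(f))
  expect_lt(abs(mean(f) - 0.598), 3 * se)
  # determinism and the truth table
  pools2 <- gen_parental_pools(sc, depth = 85, seed = 17)
  expect_identical(pools$vt$alt, pools2$vt$alt)
  expect_equal(pools$truth$vt_freq, sc$vt_freqs)
  sc0 <- sc; sc0$n_snps <- 0L
  expect_error(gen_parental_pools(sc0), "no SNPs")
  expect_error(gen_parental_pools(sc, depth = 0), ">= 1")
})

test_that("neutral F16 pools track the backcross recurrence", {
  wm <- window_map("2R", 1, 1e5, 1e-8)
  sc <- parental_scenario(wm, snps_per_window = 8L, seed = 5)
  f16 <- gen_f16_pools(sc, sim_params(), n_replicates = 25L, seed = 9)
  expect_false(any(f16$labels$selected))
  expected <- expected_backcross_frequency(sc$vt_freqs, sc$sk_freqs, 8)
  m <- colMeans(f16$truth_freq)
  se <- apply(f16$truth_freq, 2, stats::sd) / sqrt(nrow(f16$truth_freq))
  expect_true(mean(abs(m - expected) < 3.5 * se) >= 0.95)
  # distinct replicates use distinct sub-seeds
  expect_false(identical(f16$pools[[1]]$alt, f16$pools[[2]]$alt))
})

test_that("viability selection pushes the tropical allele above its neutral expectation", {
  wm <- window_map("2R", 1, 1e5, 1e-8)
  focal <- data.frame(window = wm$window[1], site = 4L, vt_freq = 0.05,
                      sk_freq = 1, selection_strength = 50)
  sc <- parental_scenario(wm, snps_per_window = 8L, focal = focal, seed = 5)
  f16 <- gen_f16_pools(sc, sim_params(), n_replicates = 6L, seed = 13)
  expect_true(all(f16$labels$selected))
  neutral_exp <- expected_backcross_frequency(0.05, 1, 8)
  # selection keeps the tropical allele far above drift in every replicate
  expect_true(all(f16$truth_freq[, 4] > neutral_exp + 0.1))
})

test_that("seasonal series obey the logit-linear environmental model", {
  sc <- seasonal_scenario(beta_seasonal = 0, collections_per_year = 10L,
                          years = 2016:2017)
  s <- gen_seasonal_series(sc, seed = 5)
  expect_identical(nrow(s$samples), 20L)
  # null construction: regression of true frequency on the summary is flat
  fit <- suppressWarnings(
    summary(stats::lm(true_freq ~ env, data = s$samples)))$coefficients
  expect_lt(abs(fit["env", 1]), 3 * fit["env", 2] + 1e-12)
  expect_true(all(s$samples$true_freq == sc$baseline_freq))
  # effect scenario shifts the truth monotonically on the logit scale
  sc2 <- seasonal_scenario(beta_seasonal = -0.5)
  s2 <- gen_seasonal_series(sc2, seed = 5)
  ord <- order(s2$samples$env)
  expect_true(all(diff(s2$samples$true_freq[ord]) <= 1e-12))
  # determinism
  s3 <- gen_seasonal_series(sc2, seed = 5)
  expect_identical(s3$samples$freq, s2$samples$freq)
  # a flat environmental series is flagged as degenerate
  flat <- seasonal_scenario(env_amplitude = 0, env_sd = 0, env_ar = 0)
  expect_error(gen_seasonal_series(flat, seed = 1), "constant|inestimable")
})

test_that("line panels carry a purely epistatic survival shift", {
  sc <- panel_scenario(n_lines = 64L, epistatic_effect = 1.5,
                       embryos_per_line = 50L)
  panel <- gen_line_panel(sc, seed = 21)
  expect_identical(nrow(panel), 64L)
  cls <- genotype_class(panel$allele_2R, panel$allele_X)
  expect_setequal(unique(cls), c("tropical_tropical", "tropical_temperate",
                                 "temperate_tropical", "temperate_temperate"))
  # only the doubly-tropical class is shifted
  expect_true(all(panel$true_p[cls == "tropical_tropical"] >
                    panel$true_p[cls != "tropical_tropical"][1]))
  expect_equal(length(unique(panel$true_p[cls != "tropical_tropical"])), 1L)
  expect_true(all(panel$survived <= panel$assayed))
  expect_error(panel_scenario(embryos_per_line = 0), ">= 1")
  expect_error(panel_scenario(n_lines = 16L,
                              class_probs = c(0.01, 0.33, 0.33, 0.33)),
               "expected count")
})

test_that("expression counts respect the factorial design and offsets", {
  g <- gen_expression_counts(50, interaction_log2fc = 2, carriers = 1:10,
                             dispersion = 0.1, seed = 31)
  expect_identical(dim(g$counts), c(50L, 12L))
  expect_identical(sum(g$truth$carrier), 10L)
  g2 <- gen_expression_counts(50, interaction_log2fc = 2, carriers = 1:10,
                              dispersion = 0.1, seed = 31)
  expect_identical(g$counts, g2$counts)
  expect_error(gen_expression_counts(10, dispersion = 0), "> 0")
  expect_error(gen_expression_counts(10, backgrounds = "VT"), ">= 2")
})
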