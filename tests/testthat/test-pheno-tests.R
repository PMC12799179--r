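# Genotype classing, exact binomial intervals, the epistasis ANOVA,
# pairwise r2 and the negative-binomial interaction test.

test_that("genotype classes map the four homozygous combinations bijectively", {
  expect_identical(genotype_class("C", "T"), "tropical_tropical")
  expect_identical(genotype_class("A", "A"), "temperate_temperate")
  expect_identical(genotype_class("C", "A"), "tropical_temperate")
  expect_identical(genotype_class("A", "T"), "temperate_tropical")
  all4 <- genotype_class(c("C", "C", "A", "A"), c("T", "A", "T", "A"))
  expect_identical(length(unique(all4)), 4L)
  expect_error(genotype_class("G", "T"), "unknown allele")
})

test_that("Clopper-Pearson intervals hit their exact bounds", {
  ci <- line_binom_ci(c(0, 20, 5), c(20, 20, 20))
  expect_identical(ci$lower[1], 0)
  expect_identical(ci$upper[2], 1)
  # independent oracle: stats::binom.test implements the same exact interval
  oracle <- stats::binom.test(5, 20)$conf.int
  expect_equal(unlist(ci[3, ]), c(lower = oracle[1], upper = oracle[2]))
  expect_equal(round(as.numeric(ci[3, ]), 4), c(0.0866, 0.4910))
  expect_error(line_binom_ci(1, 0), ">= 1")
  expect_error(line_binom_ci(5, 3), "survived <= assayed")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(12)
  for (p in c(0.1, 0.3, 0.5)) {
    x <- rbinom(4000, 20, p)
    ci <- line_binom_ci(x, rep(20, 4000))
    cover <- mean(ci$lower <= p & p <= ci$upper)
    expect_gte(cover, 0.95 - 0.01)
  }
})

test_that("epistasis ANOVA detects a planted interaction and is locus-symmetric", {
  panel <- gen_line_panel(panel_scenario(n_lines = 64L, epistatic_effect = 2,
                                         embryos_per_line = 100L), seed = 41)
  a <- survival_anova(panel)
  expect_s3_class(a, "survival_anova")
  expect_lt(a$interaction$p, 0.05)
  # swapping which locus is "first" leaves the interaction test unchanged
  swapped <- panel
  swapped$allele_2R <- ifelse(panel$allele_X == "T", "C", "A")
  swapped$allele_X <- ifelse(panel$allele_2R == "C", "T", "A")
  b <- survival_anova(swapped)
  expect_equal(b$interaction$F, a$interaction$F, tolerance = 1e-10)
  expect_error(survival_anova(panel[panel$allele_2R == "C", ]),
               "2 lines per marginal genotype")
})

test_that("the covariate coding yields the study's residual degrees of freedom", {
  # 64 lines, sum-to-zero contrasts: intercept + 2R + X + interaction +
  # symbiont + two 3-level inversion factors = 9 parameters -> df (1, 55)
  panel <- gen_line_panel(panel_scenario(n_lines = 64L, embryos_per_line = 20L),
                          seed = 2)
  stopifnot(nlevels(factor(panel$In2Lt)) == 3L,
            nlevels(factor(panel$In2RNS)) == 3L)
  a <- survival_anova(panel, include_covariates = TRUE)
  expect_identical(a$interaction$df1, 1L)
  expect_identical(a$interaction$df2, 55L)
})

test_that("genotype r2 matches its analytic limits and null expectation", {
  a <- c(rep("C", 10), rep("A", 10))
  expect_equal(genotype_r2(a, a), 1)
  b <- ifelse(a == "C", "A", "C")  # complementary coding
  expect_equal(genotype_r2(a, b), 1)
  set.seed(14)
  r2s <- replicate(200, genotype_r2(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5)))
  expect_lt(mean(r2s), 3 / 1000)  # E[r2] is about 1/n under independence
  expect_gt(mean(r2s), 0.2 / 1000)
  x <- rbinom(50, 1, 0.5)
  expect_equal(genotype_r2(x, 1 - x), 1)
  expect_error(genotype_r2(rep(1, 10), rbinom(10, 1, 0.5)), "monomorphic")
})

test_that("NB interaction test flags planted interactions and honours offsets", {
  g <- gen_expression_counts(40, interaction_log2fc = 2, carriers = 1:40,
                             dispersion = 0.1, n_reps = 3L, seed = 51)
  r <- nb_interaction_test(g$counts, g$samples$background,
                           g$samples$temperature, g$samples$norm_factor)
  expect_s3_class(r, "expression_fit")
  hit <- r$padj < 0.05 & r$gene %in% g$truth$gene[g$truth$carrier]
  expect_gte(sum(hit, na.rm = TRUE) / 40, 0.8)
  # carriers' estimates sit near the planted log fold-change
  est <- r$estimate[r$gene %in% g$truth$gene[g$truth$carrier]]
  expect_equal(mean(est, na.rm = TRUE), 2 * log(2), tolerance = 0.15)
  # doubling every norm factor is absorbed by the intercept
  r2 <- nb_interaction_test(g$counts, g$samples$background,
                            g$samples$temperature, 2 * g$samples$norm_factor)
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-6)
  expect_error(nb_interaction_test(g$counts, g$samples$background,
                                   g$samples$temperature,
                                   rep(0, 12)), "positive norm factor")
})

test_that("the NB fit approaches the Poisson fit as dispersion vanishes", {
  g <- gen_expression_counts(15, interaction_log2fc = 1, carriers = 1:15,
                             dispersion = 1e-4, n_reps = 4L,
                             baseline_log_mean = c(5, 6), seed = 61)
  r <- nb_interaction_test(g$counts, g$samples$background,
                           g$samples$temperature, g$samples$norm_factor)
  d <- data.frame(bg = factor(g$samples$background,
                              levels = unique(g$samples$background)),
                  temp = factor(g$samples$temperature,
                                levels = unique(g$samples$temperature)))
  pois_est <- vapply(seq_len(15), function(i) {
    f <- stats::glm(g$counts[i, ] ~ bg * temp, family = stats::poisson(),
                    data = d)
    stats::coef(f)[[4]]
  }, numeric(1))
  ok <- r$converged
  expect_true(all(abs(r$estimate[ok] - pois_est[ok]) <=
                    0.01 * pmax(abs(pois_est[ok]), 0.1)))
})

test_that("all-zero genes are skipped with a note", {
  g <- gen_expression_counts(5, seed = 71)
  g$counts[2, ] <- 0L
  expect_message(r <- nb_interaction_test(g$counts, g$samples$background,
                                          g$samples$temperature,
                                          g$samples$norm_factor),
                 "all-zero")
  expect_false(g$truth$gene[2] %in% r$gene)
})
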