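# Shared fixture builders and independent oracles used across test files.

# small single-window spec for simulator tests
toy_window <- function(n_sites = 3L, rho = 1e-8, length_bp = 150000) {
  window_spec("2R", 1, length_bp, rho,
              sites = round(seq(length_bp * 0.05, length_bp * 0.95,
                                length.out = n_sites)))
}

# Weir-Cockerham (1984) theta for two populations of haploid samples,
# ratio of averages across sites. Independent genotype-level oracle for the
# pool-seq FST estimator: takes observed chromosome counts, not reads.
wc_fst_haploid <- function(p1, p2, n) {
  r <- 2
  nbar <- n
  pbar <- (p1 + p2) / 2
  s2 <- (n * (p1 - pbar)^2 + n * (p2 - pbar)^2) / ((r - 1) * nbar)
  nc <- (2 * n - (2 * n^2) / (2 * n)) / (r - 1)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2)
  sum(a) / sum(a + b)
}

# Balding-Nichols-style two-population frequencies with target FST, then
# pool + read sampling; returns pool_samples plus the sampled chromosome
# frequencies for the genotype-level oracle.
sim_divergent_pools <- function(n_sites, fst, n_chrom = 60L, depth = 85) {
  panc <- stats::runif(n_sites, 0.2, 0.8)
  a <- panc * (1 - fst) / fst
  b <- (1 - panc) * (1 - fst) / fst
  x1 <- stats::rbeta(n_sites, a, b)
  x2 <- stats::rbeta(n_sites, a, b)
  g1 <- stats::rbinom(n_sites, n_chrom, x1)
  g2 <- stats::rbinom(n_sites, n_chrom, x2)
  d1 <- stats::rpois(n_sites, depth)
  d2 <- stats::rpois(n_sites, depth)
  c1 <- stats::rbinom(n_sites, d1, g1 / n_chrom)
  c2 <- stats::rbinom(n_sites, d2, g2 / n_chrom)
  list(a = pool_sample("a", "F16", c1, d1, n_chrom),
       b = pool_sample("b", "parent_VT", c2, d2, n_chrom),
       p1 = g1 / n_chrom, p2 = g2 / n_chrom)
}

# Planted-introgression scenario for end-to-end scans: 8 windows of 100 kb,
# 40 SNPs each; window 3 carries 10 fixed-difference marker loci of which
# three are under viability selection when s > 0.
planted_scenario <- function(seed, s = 50) {
  wm <- window_map(arm = rep("2R", 8),
                   start = seq(1, by = 1e5, length.out = 8),
                   end = seq(1e5, by = 1e5, length.out = 8),
                   rho = rep(1e-8, 8))
  focal <- data.frame(window = wm$window[3], site = seq(4L, 40L, by = 4L),
                      vt_freq = 0.05, sk_freq = 1, selection_strength = 0)
  focal$selection_strength[c(2, 5, 8)] <- s
  parental_scenario(wm, snps_per_window = 40L, focal = focal, seed = seed)
}

# One full synthetic pipeline run; returns whether the planted window was
# called, whether it ranks first, and the count of false window calls.
planted_scan_run <- function(seed, selected = TRUE, n_envelope = 20L) {
  sc <- planted_scenario(seed, s = if (selected) 50 else 0)
  par <- gen_parental_pools(sc, seed = subseed(seed, 1))
  sim <- sim_params(n_replicates = n_envelope)
  f16 <- gen_f16_pools(sc, sim, n_replicates = 6L, seed = subseed(seed, 2))
  cfg <- run_config(f16$pools, par$vt, par$sk, sc$window_map, sim = sim,
                    seed = subseed(seed, 3))
  b <- run_pipeline(cfg)
  sel_w <- sc$window_map$window[3]
  list(called = b$calls$significant[b$calls$window == sel_w],
       n_false = sum(b$calls$significant & b$calls$window != sel_w),
       rank1 = b$calls$window[which.max(b$calls$min_stat)] == sel_w,
       bundle = b, scenario = sc)
}

# balanced null line panel (no epistasis) for calibration tests
null_panel <- function(seed, n_lines = 64L, embryos = 50L) {
  gen_line_panel(panel_scenario(n_lines = n_lines, epistatic_effect = 0,
                                embryos_per_line = embryos), seed = seed)
}
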