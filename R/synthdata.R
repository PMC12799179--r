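# Synthetic-data generators. These emit data with the statistical structure
# the downstream analyses assume -- two divergent parental pools, replicated
# F16 introgression pools with optional viability selection at focal loci,
# seasonal allele-frequency series with a logit-linear environmental effect,
# inbred line panels with a purely epistatic two-locus survival effect, and
# negative-binomial expression counts -- together with the truth tables that
# make oracle comparisons possible.

#' Describe a pair of divergent parental populations
#'
#' Lays out `snps_per_window` evenly spaced sites in each window of
#' `window_map`. Background (non-focal) allele frequencies are drawn
#' independently for each parent from a Beta(0.8, 0.8) distribution
#' truncated to `[0.05, 0.95]`, giving the intermediate-frequency SNP
#' spectrum typical of pool-seq variant filtering. Focal loci override the
#' background draw; by convention the counted (alt) allele at a focal locus
#' is the tropical (SK) allele, so a fixed difference is encoded as
#' `sk_freq = 1`.
#'
#' @param window_map a [window_map()].
#' @param snps_per_window sites simulated per window (>= 1).
#' @param focal optional data.frame with columns `window` (id from the map),
#'   `site` (index within the window, 1-based), `vt_freq`, `sk_freq`,
#'   `selection_strength` (>= 0).
#' @param seed seed for the background frequency draw.
#' @return A list of class `parental_scenario`: `n_snps`, `window_map`,
#'   `sites` (data.frame: window, arm, pos), `vt_freqs`, `sk_freqs`,
#'   `focal`.
#' @export
parental_scenario <- function(window_map, snps_per_window = 25L,
                              focal = NULL, seed = 1L) {
  stopifnot(inherits(window_map, "window_map"))
  snps_per_window <- assert_count(snps_per_window, "snps_per_window", min = 1L)
  set.seed(seed)
  sites <- do.call(rbind, lapply(seq_len(nrow(window_map)), function(i) {
    w <- window_map[i, ]
    pos <- round(seq(w$start, w$end, length.out = snps_per_window + 2L))
    pos <- unique(pos[-c(1L, length(pos))])
    data.frame(window = w$window, arm = w$arm, pos = pos,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(sites)
  rbeta_trunc <- function(k) {
    x <- stats::rbeta(k, 0.8, 0.8)
    pmin(pmax(x, 0.05), 0.95)
  }
  vt <- rbeta_trunc(n)
  sk <- rbeta_trunc(n)
  if (!is.null(focal)) {
    need <- c("window", "site", "vt_freq", "sk_freq", "selection_strength")
    if (!all(need %in% names(focal)))
      stop("focal must have columns ", paste(need, collapse = ", "))
    assert_prob(focal$vt_freq, "focal$vt_freq")
    assert_prob(focal$sk_freq, "focal$sk_freq")
    if (any(focal$selection_strength < 0))
      stop("selection_strength must be >= 0")
    for (j in seq_len(nrow(focal))) {
      in_w <- which(sites$window == focal$window[j])
      if (!length(in_w)) stop("focal window not in window map: ", focal$window[j])
      if (focal$site[j] < 1L || focal$site[j] > length(in_w))
        stop("focal site index outside its window: ", focal$window[j],
             " site ", focal$site[j])
      idx <- in_w[focal$site[j]]
      vt[idx] <- focal$vt_freq[j]
      sk[idx] <- focal$sk_freq[j]
    }
    focal$global_index <- vapply(seq_len(nrow(focal)), function(j)
      which(sites$window == focal$window[j])[focal$site[j]], integer(1))
  }
  structure(list(n_snps = n, window_map = window_map, sites = sites,
                 vt_freqs = vt, sk_freqs = sk, focal = focal, seed = seed),
            class = "parental_scenario")
}

#' Generate sequenced parental pools with pool-seq noise
#'
#' Applies the two-step binomial noise model ([poolseq_noise()]) to the true
#' parental frequencies of a scenario, at constant depth, and returns the
#' truth table alongside for oracle comparisons.
#'
#' @param scenario a [parental_scenario()].
#' @param pool_diploids diploids per sequenced pool (default 30).
#' @param depth constant read depth per site (default 85; must be >= 1).
#' @param seed master seed.
#' @return List with `vt` and `sk` ([pool_sample()] objects) and `truth`
#'   (data.frame: window, arm, pos, vt_freq, sk_freq).
#' @export
gen_parental_pools <- function(scenario, pool_diploids = 30L, depth = 85L,
                               seed = 1L) {
  stopifnot(inherits(scenario, "parental_scenario"))
  if (scenario$n_snps == 0L) stop("scenario has no SNPs")
  if (depth < 1) stop("depth must be >= 1")
  vt_draw <- poolseq_noise(scenario$vt_freqs, pool_diploids, depth,
                           seed = subseed(seed, 1L))
  sk_draw <- poolseq_noise(scenario$sk_freqs, pool_diploids, depth,
                           seed = subseed(seed, 2L))
  truth <- cbind(scenario$sites,
                 data.frame(vt_freq = scenario$vt_freqs,
                            sk_freq = scenario$sk_freqs))
  list(vt = pool_sample("VT", "parent_VT", vt_draw$alt, vt_draw$total,
                        2L * pool_diploids, arm = scenario$sites$arm,
                        pos = scenario$sites$pos),
       sk = pool_sample("SK", "parent_SK", sk_draw$alt, sk_draw$total,
                        2L * pool_diploids, arm = scenario$sites$arm,
                        pos = scenario$sites$pos),
       truth = truth)
}

# viability weights for the bottleneck: survival odds proportional to
# 1 + s * (tropical-allele dosage), multiplied over the focal sites in the
# window; the alt allele at a focal site is the tropical allele.
focal_weight_fun <- function(site_idx, s_vec) {
  force(site_idx); force(s_vec)
  function(H) {
    n_ind <- nrow(H) %/% 2L
    w <- rep(1, n_ind)
    for (k in seq_along(site_idx)) {
      dosage <- H[seq(1L, 2L * n_ind, by = 2L), site_idx[k]] +
        H[seq(2L, 2L * n_ind, by = 2L), site_idx[k]]
      w <- w * (1 + s_vec[k] * dosage)
    }
    w
  }
}

#' Generate replicated F16 introgression pools
#'
#' Runs the introgression simulator once per window per replicate, starting
#' from true F1 hybrids (`init = "f1_haplotypes"`) so that the parental
#' linkage disequilibrium of the cross is carried into the experiment and
#' selected alleles drag their windows along, as in the real design.
#' Windows containing focal loci with positive selection strength impose
#' viability selection at the even-generation bottleneck: survival weight
#' proportional to `1 + s * (tropical-allele dosage)` per focal site,
#' mimicking heat-shock selection on introgressed tropical alleles. All
#' other windows evolve neutrally under the backcross design. Truth labels
#' mark selected windows as true positives.
#'
#' @param scenario a [parental_scenario()].
#' @param sim a [sim_params()].
#' @param n_replicates number of F16 pools (default 6).
#' @param seed master seed; replicate r, window w uses
#'   `subseed(seed, r * 10000 + w)`.
#' @return List with `pools` (list of [pool_sample()]), `truth_freq`
#'   (replicates x sites matrix of final true frequencies) and `labels`
#'   (data.frame: window, selected).
#' @export
gen_f16_pools <- function(scenario, sim = sim_params(), n_replicates = 6L,
                          seed = 1L) {
  stopifnot(inherits(scenario, "parental_scenario"), inherits(sim, "sim_params"))
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  wm <- scenario$window_map
  labels <- data.frame(window = wm$window, selected = FALSE,
                       stringsAsFactors = FALSE)
  pools <- vector("list", n_replicates)
  truth_freq <- matrix(NA_real_, n_replicates, scenario$n_snps)
  for (r in seq_len(n_replicates)) {
    alt <- numeric(scenario$n_snps)
    total <- numeric(scenario$n_snps)
    for (wi in seq_len(nrow(wm))) {
      idx <- which(scenario$sites$window == wm$window[wi])
      if (!length(idx)) next
      win <- window_spec(wm$arm[wi], wm$start[wi], wm$end[wi], wm$rho[wi],
                         scenario$sites$pos[idx])
      weights <- NULL
      if (!is.null(scenario$focal)) {
        f <- scenario$focal[scenario$focal$window == wm$window[wi] &
                              scenario$focal$selection_strength > 0, , drop = FALSE]
        if (nrow(f)) {
          weights <- focal_weight_fun(f$site, f$selection_strength)
          labels$selected[wi] <- TRUE
        }
      }
      tr <- simulate_introgression(win, sim,
                                   p_vt = scenario$vt_freqs[idx],
                                   p_sk = scenario$sk_freqs[idx],
                                   mode = "neutral_introgression",
                                   init = "f1_haplotypes",
                                   seed = subseed(seed, r * 10000 + wi),
                                   survivor_weights = weights)
      alt[idx] <- tr$alt
      total[idx] <- tr$total
      truth_freq[r, idx] <- tr$freq[nrow(tr$freq), ]
    }
    pools[[r]] <- pool_sample(paste0("F16_", r), "F16", alt, total,
                              2L * sim$pool_diploids,
                              arm = scenario$sites$arm,
                              pos = scenario$sites$pos)
  }
  list(pools = pools, truth_freq = truth_freq, labels = labels)
}

#' Describe a seasonal sampling design
#'
#' @param localities locality names.
#' @param latitudes one latitude per locality.
#' @param years collection years.
#' @param collections_per_year pooled collections per locality-year.
#' @param beta_seasonal logit-scale effect of the standardised lagged
#'   environmental summary on the true allele frequency.
#' @param baseline_freq allele frequency when the summary is at its mean,
#'   strictly in (0, 1).
#' @param lag_days,statistic lag window (days) and summary statistic applied
#'   to the environmental series before each collection date.
#' @param pool_diploids,depth pooled sequencing design per collection.
#' @param env_mean,env_amplitude,env_ar,env_sd sinusoidal annual cycle plus
#'   AR(1) noise for the daily environmental series.
#' @return A list of class `seasonal_scenario`.
#' @export
seasonal_scenario <- function(localities = "VA", latitudes = 38.0,
                              years = 2016:2018, collections_per_year = 10L,
                              beta_seasonal = -0.089, baseline_freq = 0.5,
                              lag_days = 45L, statistic = "sd",
                              pool_diploids = 30L, depth = 85L,
                              env_mean = 15, env_amplitude = 12,
                              env_ar = 0.7, env_sd = 2) {
  if (!is.finite(beta_seasonal)) stop("beta_seasonal must be finite")
  assert_prob(baseline_freq, "baseline_freq", open = TRUE)
  if (length(latitudes) != length(localities))
    stop("one latitude per locality required")
  collections_per_year <- assert_count(collections_per_year,
                                       "collections_per_year", min = 1L)
  structure(list(localities = localities, latitudes = latitudes,
                 years = years, collections_per_year = collections_per_year,
                 beta_seasonal = beta_seasonal, baseline_freq = baseline_freq,
                 lag_days = as.integer(lag_days), statistic = statistic,
                 pool_diploids = as.integer(pool_diploids),
                 depth = as.integer(depth),
                 env_mean = env_mean, env_amplitude = env_amplitude,
                 env_ar = env_ar, env_sd = env_sd),
            class = "seasonal_scenario")
}

#' Generate a seasonal allele-frequency series with environmental forcing
#'
#' Simulates a daily environmental series per locality (annual sinusoid plus
#' AR(1) noise), draws collection dates through each growing season,
#' summarises the series over the scenario's lag window before each
#' collection, and sets the true allele frequency to
#' `plogis(qlogis(baseline) + beta_seasonal * z)` where `z` is the
#' standardised lag summary. Observed frequencies add two-step binomial
#' pool-seq noise.
#'
#' @param scenario a [seasonal_scenario()].
#' @param seed master seed.
#' @return List with `samples` (data.frame: id, locality, latitude, year,
#'   date, env, true_freq, freq, n_e) and `env` (data.frame: locality, date,
#'   value).
#' @export
gen_seasonal_series <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "seasonal_scenario"))
  set.seed(subseed(seed, 1L))
  first <- as.Date(paste0(min(scenario$years), "-01-01")) - scenario$lag_days
  last <- as.Date(paste0(max(scenario$years), "-12-31"))
  dates <- seq(first, last, by = "day")
  env <- do.call(rbind, lapply(scenario$localities, function(loc) {
    doy <- as.numeric(format(dates, "%j"))
    seasonal <- scenario$env_mean -
      scenario$env_amplitude * cos(2 * pi * doy / 365.25)
    noise <- if (scenario$env_sd > 0) {
      as.numeric(stats::arima.sim(
        list(ar = scenario$env_ar), n = length(dates),
        sd = scenario$env_sd * sqrt(1 - scenario$env_ar^2)))
    } else {
      numeric(length(dates))
    }
    data.frame(locality = loc, date = dates, value = seasonal + noise,
               stringsAsFactors = FALSE)
  }))

  grid <- expand.grid(locality = scenario$localities, year = scenario$years,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    loc <- grid$locality[g]; yr <- grid$year[g]
    season <- seq(as.Date(paste0(yr, "-05-01")),
                  as.Date(paste0(yr, "-11-15")), by = "day")
    cdates <- sort(sample(season, scenario$collections_per_year))
    loc_env <- env[env$locality == loc, c("date", "value")]
    summ <- vapply(cdates, function(d)
      lag_summary(loc_env, d, scenario$lag_days, scenario$statistic),
      numeric(1))
    rows[[g]] <- data.frame(locality = loc,
                            latitude = scenario$latitudes[match(loc, scenario$localities)],
                            year = yr, date = cdates, env = summ,
                            stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  z <- as.numeric(scale(samples$env))
  if (any(!is.finite(z)))
    stop("environmental summaries are constant; seasonal effect inestimable")
  samples$true_freq <- stats::plogis(stats::qlogis(scenario$baseline_freq) +
                                       scenario$beta_seasonal * z)
  draw <- poolseq_noise(samples$true_freq, scenario$pool_diploids,
                        scenario$depth, seed = subseed(seed, 2L))
  samples$freq <- draw$alt / draw$total
  samples$n_e <- effective_coverage(2L * scenario$pool_diploids, draw$total)
  samples$id <- sprintf("%s_%d_%02d", samples$locality, samples$year,
                        stats::ave(seq_len(nrow(samples)), samples$locality,
                                   samples$year, FUN = seq_along))
  list(samples = samples[, c("id", "locality", "latitude", "year", "date",
                             "env", "true_freq", "freq", "n_e")],
       env = env)
}

#' Describe a two-locus line-panel assay
#'
#' @param n_lines lines in the panel (>= 8, all four genotype classes
#'   represented).
#' @param class_probs probabilities of the four two-locus classes in the
#'   order tropical_tropical, tropical_temperate, temperate_tropical,
#'   temperate_temperate; must sum to 1 and give every class an expected
#'   count of at least 1.
#' @param base_survival embryo survival probability of the non-epistatic
#'   classes, strictly in (0, 1).
#' @param epistatic_effect additive logit shift applied only to the
#'   doubly-tropical class.
#' @param embryos_per_line embryos assayed per line (>= 1).
#' @return A list of class `panel_scenario`.
#' @export
panel_scenario <- function(n_lines = 64L,
                           class_probs = c(8, 23, 13, 22) / 66,
                           base_survival = 0.2, epistatic_effect = 1.5,
                           embryos_per_line = 20L) {
  n_lines <- assert_count(n_lines, "n_lines", min = 8L)
  if (length(class_probs) != 4L || abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must be 4 probabilities summing to 1")
  if (any(class_probs * n_lines < 1))
    stop("class_probs give a class an expected count below 1")
  assert_prob(base_survival, "base_survival", open = TRUE)
  p_epi <- stats::plogis(stats::qlogis(base_survival) + epistatic_effect)
  if (p_epi <= 0 || p_epi >= 1) stop("epistatic survival leaves (0, 1)")
  embryos_per_line <- assert_count(embryos_per_line, "embryos_per_line", min = 1L)
  structure(list(n_lines = n_lines, class_probs = class_probs,
                 base_survival = base_survival,
                 epistatic_effect = epistatic_effect,
                 embryos_per_line = embryos_per_line),
            class = "panel_scenario")
}

#' Generate an inbred line panel with a purely epistatic survival effect
#'
#' Class counts follow the scenario probabilities by largest-remainder
#' apportionment (deterministic, all four classes guaranteed), line order is
#' shuffled, and covariates (symbiont infection, two inversion genotypes)
#' are drawn independently of genotype so they carry no signal. Survival
#' counts are binomial with the class-specific probability; only the
#' doubly-tropical class (2R^C X^T) receives the epistatic logit shift.
#'
#' @param scenario a [panel_scenario()].
#' @param seed master seed.
#' @return Data.frame of `LineRecord` rows: line, allele_2R, allele_X,
#'   wolbachia, In2Lt, In2RNS, survived, assayed, plus the truth column
#'   `true_p`.
#' @export
gen_line_panel <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "panel_scenario"))
  set.seed(subseed(seed, 1L))
  n <- scenario$n_lines
  base_counts <- floor(scenario$class_probs * n)
  rem <- n - sum(base_counts)
  if (rem > 0) {
    frac <- scenario$class_probs * n - base_counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base_counts[add] <- base_counts[add] + 1L
  }
  classes <- c("tropical_tropical", "tropical_temperate",
               "temperate_tropical", "temperate_temperate")
  cls <- sample(rep(classes, times = base_counts))
  allele_2R <- ifelse(cls %in% c("tropical_tropical", "tropical_temperate"), "C", "A")
  allele_X <- ifelse(cls %in% c("tropical_tropical", "temperate_tropical"), "T", "A")
  p <- stats::plogis(stats::qlogis(scenario$base_survival) +
                       scenario$epistatic_effect * (cls == "tropical_tropical"))
  inv_geno <- c("std/std", "std/inv", "inv/inv")
  data.frame(line = sprintf("L%03d", seq_len(n)),
             allele_2R = allele_2R, allele_X = allele_X,
             wolbachia = sample(c(0L, 1L), n, replace = TRUE),
             In2Lt = sample(inv_geno, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
             In2RNS = sample(inv_geno, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
             survived = stats::rbinom(n, scenario$embryos_per_line, p),
             assayed = scenario$embryos_per_line,
             true_p = p, stringsAsFactors = FALSE)
}

#' Generate negative-binomial expression counts for a factorial design
#'
#' Counts follow a log-link negative-binomial model:
#' `log mu = baseline + background effect + temperature effect +
#' interaction + log(norm_factor)`. A chosen subset of genes carries a
#' background-by-temperature interaction of `interaction_log2fc` (applied to
#' the last background at the second temperature); all other genes are null.
#'
#' @param n_genes number of genes.
#' @param backgrounds,temps factor levels of the design (>= 2 backgrounds,
#'   exactly the first two temperature levels are contrasted).
#' @param n_reps replicates per design cell (>= 2 recommended).
#' @param interaction_log2fc log2 fold-change of the interaction for carrier
#'   genes.
#' @param carriers integer indices of genes carrying the interaction
#'   (default none).
#' @param dispersion NB dispersion (1/size), > 0.
#' @param norm_factors per-sample normalisation factors (default all 1).
#' @param baseline_log_mean range of per-gene baseline log means, drawn
#'   uniformly.
#' @param seed master seed.
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (data.frame: sample, background, temperature, norm_factor) and `truth`
#'   (data.frame: gene, carrier, interaction_log2fc).
#' @export
gen_expression_counts <- function(n_genes, backgrounds = c("VT", "F16"),
                                  temps = c("control", "heat"), n_reps = 3L,
                                  interaction_log2fc = 0, carriers = integer(0),
                                  dispersion = 0.1, norm_factors = NULL,
                                  baseline_log_mean = c(4, 8), seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  if (length(backgrounds) < 2L || length(temps) < 2L)
    stop("design needs >= 2 genetic backgrounds x 2 temperatures")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  set.seed(subseed(seed, 1L))
  design <- expand.grid(rep = seq_len(n_reps), temperature = temps,
                        background = backgrounds, stringsAsFactors = FALSE)
  n_s <- nrow(design)
  nf <- norm_factors %||% rep(1, n_s)
  if (length(nf) != n_s || any(nf <= 0))
    stop("norm_factors must be positive, one per sample")
  b0 <- stats::runif(n_genes, baseline_log_mean[1], baseline_log_mean[2])
  bg_eff <- matrix(stats::rnorm(n_genes * length(backgrounds), 0, 0.1),
                   n_genes, dimnames = list(NULL, backgrounds))
  tm_eff <- matrix(stats::rnorm(n_genes * length(temps), 0, 0.1),
                   n_genes, dimnames = list(NULL, temps))
  inter <- numeric(n_genes)
  inter[carriers] <- interaction_log2fc * log(2)
  hot_cell <- design$background == backgrounds[length(backgrounds)] &
    design$temperature == temps[2L]
  log_mu <- b0 + bg_eff[, design$background, drop = FALSE] +
    tm_eff[, design$temperature, drop = FALSE] +
    outer(inter, as.numeric(hot_cell)) +
    matrix(log(nf), n_genes, n_s, byrow = TRUE)
  counts <- matrix(stats::rnbinom(n_genes * n_s, mu = exp(log_mu),
                                  size = 1 / dispersion),
                   n_genes, n_s)
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- sprintf("s%02d", seq_len(n_s))
  list(counts = counts,
       samples = data.frame(sample = colnames(counts),
                            background = design$background,
                            temperature = design$temperature,
                            norm_factor = nf, stringsAsFactors = FALSE),
       truth = data.frame(gene = rownames(counts),
                          carrier = seq_len(n_genes) %in% carriers,
                          interaction_log2fc = ifelse(
                            seq_len(n_genes) %in% carriers,
                            interaction_log2fc, 0)))
}
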