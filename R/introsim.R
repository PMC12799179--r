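# Forward-in-time non-Wright-Fisher simulation of the selection/backcross
# introgression design, the two-step binomial pool-seq noise model, the
# closed-form expected backcross trajectory, and the neutral drift envelope.

#' Simulation design constants for the backcross-introgression experiment
#'
#' Defaults reproduce the experimental design: a recipient population held at
#' a carrying capacity of ~1500, 16 generations alternating free recombination
#' (odd generations) with an 80% mortality bottleneck followed by the
#' introduction of 300 donor-background migrants (even generations), pooled
#' sequencing of 30 diploids at a mean depth of 85x, and 100 neutral
#' replicates per recombination window for envelope construction.
#'
#' @param carrying_capacity population size the recipient regrows to each
#'   generation (individuals).
#' @param n_generations number of generations simulated (trajectories carry
#'   `n_generations + 1` records, generation 0 included).
#' @param bottleneck_fraction fraction of individuals dying at even
#'   generations, in (0, 1).
#' @param n_migrants donor (VT-background) individuals merged into the
#'   surviving pool at each even generation.
#' @param mutation_rate per-site per-gamete mutation probability.
#' @param pool_diploids diploid individuals sampled for pooled sequencing.
#' @param mean_depth mean read depth per site.
#' @param envelope_quantile quantile used for the neutral drift envelope.
#' @param n_replicates neutral replicates per window for the envelope.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(carrying_capacity = 1500L,
                       n_generations = 16L,
                       bottleneck_fraction = 0.80,
                       n_migrants = 300L,
                       mutation_rate = 1.0e-7,
                       pool_diploids = 30L,
                       mean_depth = 85,
                       envelope_quantile = 0.95,
                       n_replicates = 100L) {
  carrying_capacity <- assert_count(carrying_capacity, "carrying_capacity", min = 2L)
  n_generations <- assert_count(n_generations, "n_generations", min = 1L)
  n_migrants <- assert_count(n_migrants, "n_migrants", min = 0L)
  pool_diploids <- assert_count(pool_diploids, "pool_diploids", min = 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  if (!is.numeric(bottleneck_fraction) || bottleneck_fraction <= 0 || bottleneck_fraction >= 1)
    stop("bottleneck_fraction must lie strictly in (0, 1)")
  if (n_migrants > carrying_capacity)
    stop("n_migrants cannot exceed carrying_capacity")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must lie in [0, 1]")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  assert_prob(envelope_quantile, "envelope_quantile", open = TRUE)
  structure(list(carrying_capacity = carrying_capacity,
                 n_generations = n_generations,
                 bottleneck_fraction = bottleneck_fraction,
                 n_migrants = n_migrants,
                 mutation_rate = mutation_rate,
                 pool_diploids = pool_diploids,
                 mean_depth = mean_depth,
                 envelope_quantile = envelope_quantile,
                 n_replicates = n_replicates),
            class = "sim_params")
}

#' One recombination window simulated as a virtual chromosome
#'
#' @param arm chromosome arm name (e.g. `"2R"`).
#' @param start,end 1-based inclusive window bounds.
#' @param rho mean per-base recombination rate (crossovers per base per
#'   meiosis); per-gamete crossover counts are Poisson with mean
#'   `rho * length`.
#' @param sites 1-based positions of the simulated sites, all inside
#'   `[start, end]`.
#' @return A list of class `window_spec` with an additional `length` field
#'   (`end - start + 1`).
#' @export
window_spec <- function(arm, start, end, rho, sites) {
  stopifnot(length(arm) == 1L, length(start) == 1L, length(end) == 1L)
  if (start > end) stop("window start must be <= end")
  if (rho < 0) stop("rho must be >= 0")
  sites <- as.numeric(sites)
  if (length(sites) < 1L) stop("a window must contain at least one site")
  if (any(sites < start | sites > end)) stop("all sites must lie inside [start, end]")
  structure(list(arm = as.character(arm), start = as.numeric(start),
                 end = as.numeric(end), length = as.numeric(end - start + 1),
                 rho = as.numeric(rho), sites = sites),
            class = "window_spec")
}

#' Genome partition into recombination windows
#'
#' @param arm,start,end,rho equal-length vectors describing the windows.
#' @return A data.frame of class `window_map` with columns `window` (id),
#'   `arm`, `start`, `end`, `length`, `rho`.
#' @export
window_map <- function(arm, start, end, rho) {
  n <- length(arm)
  stopifnot(length(start) == n, length(end) == n, length(rho) == n, n >= 1L)
  if (any(start > end)) stop("window start must be <= end")
  if (any(rho < 0)) stop("rho must be >= 0")
  out <- data.frame(window = paste0(arm, ":", start, "-", end),
                    arm = as.character(arm), start = as.numeric(start),
                    end = as.numeric(end), length = as.numeric(end - start + 1),
                    rho = as.numeric(rho), stringsAsFactors = FALSE)
  if (anyDuplicated(out$window)) stop("duplicate windows in window map")
  class(out) <- c("window_map", "data.frame")
  out
}

#' Expected allele frequencies of the synthetic F1 cross
#'
#' The F1 frequency at each site is the mean of the two parental frequencies:
#' `p_F1 = (p_VT + p_SK) / 2`. Symmetric in its arguments; fixation in both
#' parents is preserved.
#'
#' @param p_vt,p_sk equal-length vectors of parental allele frequencies in
#'   `[0, 1]`.
#' @return Vector of F1 frequencies.
#' @export
synthetic_cross <- function(p_vt, p_sk) {
  if (length(p_vt) != length(p_sk)) stop("p_vt and p_sk must have equal length")
  assert_prob(p_vt, "p_vt")
  assert_prob(p_sk, "p_sk")
  (p_vt + p_sk) / 2
}

#' Two-step binomial pool-seq noise model
#'
#' Step 1 samples the chromosomes that enter the pool:
#' `x ~ Binomial(2 * pool_diploids, p) / (2 * pool_diploids)`. Step 2 samples
#' reads from the pooled chromosomes: `alt ~ Binomial(depth, x)`. The read
#' frequency `alt / depth` is unbiased for `p` with variance
#' `p (1 - p) [1/n + (1 - 1/n)/depth]`, `n = 2 * pool_diploids`.
#'
#' Vectorised over `p` (and `depth`, recycled), so repeated draws at one
#' frequency are obtained by repeating `p`.
#'
#' @param p true allele frequency (vector allowed), in `[0, 1]`.
#' @param pool_diploids diploid individuals in the pool (>= 1).
#' @param depth read depth per site (>= 0), recycled against `p`.
#' @param seed optional seed set before drawing.
#' @return A list with integer vectors `alt` and `total` (= `depth`).
#' @export
poolseq_noise <- function(p, pool_diploids, depth, seed = NULL) {
  assert_prob(p, "p")
  pool_diploids <- assert_count(pool_diploids, "pool_diploids", min = 1L)
  if (any(depth < 0)) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_chrom <- 2L * pool_diploids
  depth <- rep_len(as.integer(round(depth)), length(p))
  x <- stats::rbinom(length(p), n_chrom, p) / n_chrom
  alt <- stats::rbinom(length(p), depth, x)
  list(alt = alt, total = depth)
}

#' Closed-form expected allele frequency after repeated backcrossing
#'
#' Starting from the F1 (donor ancestry 1/2), each backcross event halves the
#' expected donor ancestry, so after `n` events the expected ancestry from
#' the non-recurrent (SK) parent is `a = (1/2)^(n + 1)` and the expected
#' allele frequency is `(1 - a) * p_vt + a * p_sk`. With the default design
#' (backcrossing at generations 2, 4, ..., 16) `n = 8`.
#'
#' @param p_vt recurrent-parent allele frequency (vectorised).
#' @param p_sk donor-parent allele frequency (vectorised).
#' @param n_backcross_events number of backcross events (>= 0).
#' @return Expected allele frequency vector.
#' @export
expected_backcross_frequency <- function(p_vt, p_sk, n_backcross_events) {
  assert_prob(p_vt, "p_vt")
  assert_prob(p_sk, "p_sk")
  n_backcross_events <- assert_count(n_backcross_events, "n_backcross_events", min = 0L)
  a <- 0.5^(n_backcross_events + 1)
  (1 - a) * p_vt + a * p_sk
}

# -- individual-based machinery ---------------------------------------------

# Draw haplotypes site-independently from a frequency vector (linkage
# equilibrium start). Returns a (2 * n_ind) x n_sites integer matrix; rows
# (2i - 1, 2i) are the two haplotypes of individual i.
random_haplotypes <- function(n_ind, p) {
  s <- length(p)
  matrix(stats::rbinom(2L * n_ind * s, 1L, rep(p, each = 2L * n_ind)),
         nrow = 2L * n_ind, ncol = s)
}

# One round of random mating with recombination: 2K gametes from uniformly
# chosen parents (with replacement), regrowing the population to K offspring.
# Crossover counts are Poisson(rho * length) per meiosis, breakpoints uniform
# over the window. Gametes with no crossover are bulk-copied; the rare
# recombinant gametes are patched individually.
reproduce_generation <- function(H, K, window, mutation_rate) {
  n_ind <- nrow(H) %/% 2L
  if (n_ind == 0L) stop("no individuals left to reproduce")
  n_gam <- 2L * K
  par <- sample.int(n_ind, n_gam, replace = TRUE)
  first <- stats::rbinom(n_gam, 1L, 0.5)           # 1 -> start on haplotype A
  G <- H[2L * par - first, , drop = FALSE]
  lambda <- window$rho * window$length
  if (lambda > 0) {
    ncx <- stats::rpois(n_gam, lambda)
    for (i in which(ncx > 0L)) {
      bp <- sort(stats::runif(ncx[i], min = window$start, max = window$end))
      swap <- findInterval(window$sites, bp) %% 2L == 1L
      if (any(swap)) {
        other <- 2L * par[i] - (1L - first[i])
        G[i, swap] <- H[other, swap]
      }
    }
  }
  if (mutation_rate > 0) {
    n_mut <- stats::rbinom(1L, length(G), mutation_rate)
    if (n_mut > 0L) {
      idx <- sample.int(length(G), n_mut)
      G[idx] <- 1L - G[idx]
    }
  }
  # consecutive gamete pairs form the K offspring (parents are iid uniform,
  # so pairing consecutive rows is random mating)
  G
}

#' Simulate the 16-generation backcross-introgression design for one window
#'
#' Individual-based diploid simulation of one recombination window treated as
#' a virtual chromosome. Generation 0 is initialised at linkage equilibrium
#' from the synthetic-cross frequencies `(p_vt + p_sk)/2` (recipient
#' population), with the donor population fixed at the `p_vt` frequency
#' vector. Odd generations perform random mating with recombination back to
#' carrying capacity. Even generations first kill a random
#' `bottleneck_fraction` of individuals, then (in `neutral_introgression`
#' mode) merge `n_migrants` donor-background individuals into the survivors,
#' and finally reproduce back to carrying capacity. `drift_only` mode skips
#' the migrant step so all change is genetic drift through the bottlenecks.
#'
#' @param window a [window_spec()].
#' @param params a [sim_params()].
#' @param p_vt,p_sk parental allele frequencies at `window$sites`.
#' @param mode `"neutral_introgression"` or `"drift_only"`.
#' @param init generation-0 haplotype structure. The default
#'   `"linkage_equilibrium"` draws every haplotype site-independently from
#'   the F1 frequency vector, the initialisation the neutral envelope
#'   assumes. `"f1_haplotypes"` builds true F1 hybrids (one gamete drawn
#'   from `p_vt`, one from `p_sk` per individual), which carries the
#'   parental linkage disequilibrium that lets selection on a focal site
#'   drag its window along -- the structure of the real cross.
#' @param seed optional seed for full determinism.
#' @param survivor_weights optional function(haplotype matrix) returning one
#'   non-negative weight per individual, used to bias which individuals
#'   survive the even-generation bottleneck (hook used by the synthetic-data
#'   generators to impose viability selection; neutral when `NULL`).
#' @param constant_depth if `TRUE`, pooled read depth is exactly
#'   `mean_depth` at every site instead of Poisson-distributed.
#' @return A list of class `trajectory_result`: `freq` (generations+1 x
#'   sites matrix of allele frequencies), `alt`/`total` pooled read counts at
#'   the final generation, `window`, `mode`, `seed`.
#' @export
simulate_introgression <- function(window, params, p_vt, p_sk,
                                   mode = c("neutral_introgression", "drift_only"),
                                   init = c("linkage_equilibrium", "f1_haplotypes"),
                                   seed = NULL,
                                   survivor_weights = NULL,
                                   constant_depth = FALSE) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  stopifnot(inherits(window, "window_spec"), inherits(params, "sim_params"))
  s <- length(window$sites)
  if (length(p_vt) != s || length(p_sk) != s)
    stop("p_vt and p_sk must have one entry per window site")
  assert_prob(p_vt, "p_vt")
  assert_prob(p_sk, "p_sk")
  if (!is.null(seed)) set.seed(seed)

  K <- params$carrying_capacity
  H <- if (init == "f1_haplotypes") {
    hv <- matrix(stats::rbinom(K * s, 1L, rep(p_vt, each = K)), nrow = K)
    hs <- matrix(stats::rbinom(K * s, 1L, rep(p_sk, each = K)), nrow = K)
    m <- matrix(0L, 2L * K, s)
    m[seq(1L, 2L * K, 2L), ] <- hv
    m[seq(2L, 2L * K, 2L), ] <- hs
    m
  } else {
    random_haplotypes(K, synthetic_cross(p_vt, p_sk))
  }
  freq <- matrix(NA_real_, nrow = params$n_generations + 1L, ncol = s)
  freq[1L, ] <- colMeans(H)

  for (g in seq_len(params$n_generations)) {
    if (g %% 2L == 0L) {
      n_ind <- nrow(H) %/% 2L
      n_surv <- n_ind - round(params$bottleneck_fraction * n_ind)
      w <- if (!is.null(survivor_weights)) survivor_weights(H) else NULL
      if (!is.null(w) && (length(w) != n_ind || any(w < 0)))
        stop("survivor_weights must return one non-negative weight per individual")
      surv <- sample.int(n_ind, n_surv, replace = FALSE, prob = w)
      H <- H[as.vector(rbind(2L * surv - 1L, 2L * surv)), , drop = FALSE]
      if (mode == "neutral_introgression" && params$n_migrants > 0L)
        H <- rbind(H, random_haplotypes(params$n_migrants, p_vt))
      if (nrow(H) == 0L) stop("survivors + migrants = 0; population extinct")
    }
    H <- reproduce_generation(H, K, window, params$mutation_rate)
    freq[g + 1L, ] <- colMeans(H)
  }

  depth <- if (constant_depth) rep(params$mean_depth, s) else
    stats::rpois(s, params$mean_depth)
  pool <- poolseq_noise(freq[nrow(freq), ], params$pool_diploids, depth)
  structure(list(freq = freq, alt = pool$alt, total = pool$total,
                 window = window, mode = mode, seed = seed),
            class = "trajectory_result")
}

#' Per-window neutral envelope threshold
#'
#' The envelope threshold for a window is the nearest-rank empirical quantile
#' (the `ceiling(q * n)`-th order statistic) of the replicate statistic
#' distribution produced by neutral simulation.
#'
#' @param values per-window replicate statistics: a named list of numeric
#'   vectors, or a matrix with one row per window (rownames = window ids).
#' @param quantile envelope quantile, default 0.95.
#' @return Named numeric vector of thresholds, one per window.
#' @export
build_envelope <- function(values, quantile = 0.95) {
  assert_prob(quantile, "quantile", open = TRUE)
  if (is.matrix(values))
    values <- stats::setNames(split(values, row(values)), rownames(values))
  if (!is.list(values) || length(values) == 0L)
    stop("values must be a non-empty list or matrix of replicate statistics")
  vapply(values, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2L) stop("each window needs >= 2 replicate values")
    sort(v)[ceiling(quantile * n)]
  }, numeric(1))
}
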