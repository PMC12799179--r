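---
title: "Mapping adaptive introgression from pooled sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping adaptive introgression from pooled sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The experimental design this package models

`introscan` implements the computational core of an advanced
introgression-mapping experiment in *Drosophila*: a tropical donor line is
repeatedly crossed into a temperate recipient background over 16
generations, alternating free recombination (odd generations) with an 80%
mortality selection bottleneck followed by backcrossing to the recipient
(even generations). At the end, replicate populations are genotyped by
pooled sequencing (30 diploids, ~85x depth). Genomic regions where the F16
pools retain donor ancestry beyond what drift alone can explain are
candidate loci for the selected trait (here, embryonic heat tolerance).
Downstream, candidate SNPs are cross-examined in wild population panels for
latitudinal clines and seasonal allele-frequency cycles, and validated with
two-locus phenotype tests on inbred line panels and candidate-gene
expression contrasts.

## The non-Wright–Fisher backcross simulator

`simulate_introgression()` is an individual-based diploid forward
simulation of one recombination window treated as a virtual chromosome.
The population is held at a carrying capacity of `K = 1500`. Generation 0
is initialised from the synthetic-cross frequency vector

\[ p_{F1} = \tfrac12\,(p_{VT} + p_{SK}), \]

the expectation for an F1 between parents with allele frequencies
\(p_{VT}\) and \(p_{SK}\). At odd generations the population mates randomly
(pairs drawn uniformly with replacement, no explicit sexes) back to
carrying capacity; recombination draws a Poisson number of crossovers per
meiosis with mean `rho * length` and uniform breakpoints. At even
generations a random 80% of individuals die, 300 donor-background migrants
are merged into the survivors (`neutral_introgression` mode), and the
merged pool reproduces back to `K`. With `K = 1500` the post-bottleneck
survivors (300) and the migrants (300) contribute equally, so each of the
8 even-generation events halves the expected donor ancestry. That gives
the closed-form oracle implemented in `expected_backcross_frequency()`:

\[ E[p_{F16}] = (1 - a)\,p_{VT} + a\,p_{SK}, \qquad a = (1/2)^{n+1}, \]

with \(n = 8\) backcross events. For the focal SNP with recipient frequency
0.598 against a fixed donor, the expectation is
`r round(expected_backcross_frequency(0.598, 0, 8), 5)`, a drift-free shift
of only ~0.0012 — which is why an observed shift of ~0.4 is evidence of
selection, not design.

Deliberate simplifications, each chosen as the minimal model consistent
with the design:

* **Linkage-equilibrium start (default).** Generation-0 haplotypes are
  drawn site-independently from \(p_{F1}\), matching a simulator
  initialised from frequency vectors. This is the correct null for the
  drift envelope. The synthetic F16 *generator* instead uses
  `init = "f1_haplotypes"` (one gamete from each parent per individual),
  because the real cross starts from intact parental chromosomes and it is
  precisely that linkage disequilibrium which lets selection at a focal
  site drag its window along. Using LE for the envelope and F1 haplotypes
  for the "real" synthetic data mirrors the asymmetry between the real
  experiment and its neutral null.
* **Deterministic regrowth to `K`** each generation; census noise around
  the carrying capacity is ignored.
* **Hermaphroditic random mating** with replacement (selfing allowed);
  the design specifies only a carrying capacity.
* **Mutation** at `1e-7` per site per gamete as independent Bernoulli
  flips; over 16 generations this is negligible, and it is retained only
  for completeness.
* **All windows are simulated as autosomal diploid**, and pools are 60
  chromosomes everywhere; no X-specific correction is applied.
* **Read depth** is Poisson(`mean_depth`) per site by default;
  `constant_depth = TRUE` forces exact depth for oracle tests.

## The pool-seq noise model

`poolseq_noise()` applies the two-step binomial cascade: first the
chromosomes entering the pool, `Binomial(2 n_d, p) / (2 n_d)` with
`n_d = 30` diploids, then the reads, `Binomial(depth, .)` using the
first-step frequency. Read frequencies are unbiased for `p` with variance
\(p(1-p)\,[1/n + (1 - 1/n)/R]\) for `n` chromosomes and depth `R` — the
identity the test suite verifies at \(10^5\) draws. The matching
information measure is the effective coverage
\(n_e = nR/(n+R)\) (`effective_coverage()`), which both the FST estimator
and the seasonal GLM use as the per-sample weight.

## FST, PCA and the parent-distance metric

`pairwise_fst()` is an identity-probability moment estimator built for
read counts. Per site the unbiased within-pool heterozygosity corrects for
reads hitting the same pool chromosome (probability \(1/n\)) and for
finite pool size; the between-pool term uses read-frequency cross
products; the per-site ratio is Hudson-type, and windows aggregate as
ratios of summed numerators to summed denominators. The estimator is
validated against a genotype-level Weir–Cockerham oracle on simulated
two-population data (target FST 0.2): agreement is required within 10% of
the target and within 0.02 absolute of the oracle. Sites with no
between-pool diversity are undefined and excluded from window sums.

PCA (`pca_global()`, `pca_sliding()`) centres but does not variance-scale
the sample-by-site frequency matrix, since allele frequencies share a
scale; sliding windows are half-open 0.1 Mb windows stepped by 50 kb, and
windows with fewer than 2 polymorphic sites are skipped with a message.
`parent_distance_ratio()` summarises each F16 pool as
\(\log_2(d_{SK}/d_{VT})\) in the PC1–PC2 plane; positive values mean the
pool sits closer to the recipient (VT) parent. A pool coincident with a
parent yields a signed infinite sentinel that is warned about and must be
excluded from means.

## Outlier calling against the drift envelope

The scan statistic is deliberately rank-based: `flag_top_quantile()` flags
the `ceiling(q n)` largest FST values genome-wide (ties broken by stable
site order), so any strictly monotone transform of FST gives identical
results — this is how "rank-normalised" values are interpreted here, since
the downstream binomial enrichment depends only on ranks.
`window_enrichment()` computes the exact upper-tail binomial p for
observing `x` flagged SNPs among `k` under a 1% null. The neutral envelope
(`build_envelope()`) is the nearest-rank 95% quantile of the per-window
flag count across neutral-introgression replicates, with flags derived
from the *simulated* genome-wide distribution so the null calibration is
internal. A window is called (`call_significant_windows()`) only when
every experimental replicate exceeds its envelope threshold — the
all-replicates AND rule, which keeps the family-wise false-call rate far
below the per-replicate 5%.

`fet_scan()` aggregates all F16 pools into a synthetic pool (element-wise
summed counts) and tests each site's 2x2 read-count table against the
recipient parent with a two-sided Fisher's exact test (sidedness is not
dictated by the design; two-sided is the direction-agnostic choice).
Sites with pooled minor allele frequency below 0.05 are excluded.
Benjamini–Hochberg q-values and the Bonferroni threshold `alpha/m` are
both reported; with a million tests at `alpha = 0.01` the latter is 1e-8.

## Seasonality and clinality

`lag_summary()` summarises a daily environmental series over the
`lag_days` values ending on (and including) the collection date — the
"0 to L days prior" window, so a 45-day lag uses exactly 45 values and a
series with any gap inside the window errors rather than silently
shortening. `seasonal_glm()` fits a binomial GLM whose trials are the
rounded effective coverage (round-half-even; binomial fitting needs
integers and rounding `freq * n_e` preserves the mean), with year and
locality as null-model factors and the z-scored environmental summary as
the added term; the reported p is the 1-df likelihood-ratio test.
Standardising the covariate makes coefficients comparable across
variables and lags and makes the fit invariant to affine rescaling of the
raw series. `permutation_rank()` shuffles the summary within locality —
preserving the factor structure while breaking the
environment–frequency link — and counts strictly beaten permutations, so
ties do not inflate the rank. `colocalize()` intersects site keys under
strict (`<`) thresholds: q < 0.05 for the external clinal set and
p < 0.004 for the external seasonal set, the thresholds used by those
datasets' authors.

## Line panels and expression

`survival_anova()` models per-line survival *proportions* (unweighted by
assay size; a weighted variant sits behind `weighted = TRUE`) with
sum-to-zero contrasts and Type-III tests, the appropriate choice for the
unbalanced genotype-class counts of a natural panel. With 64 lines, a
binary symbiont covariate and two three-level inversion factors, the
interaction test has df (1, 55). `line_binom_ci()` is the exact
Clopper–Pearson interval. `nb_interaction_test()` fits gene-specific
negative-binomial GLMs with `log(norm_factor)` offsets and Wald tests on
every background-by-temperature interaction coefficient, BH-adjusted
across genes within each term. The NB2 dispersion is estimated per gene
by degrees-of-freedom-corrected Pearson moment matching (the Pearson
chi-square is solved to equal the residual df, alternating with the mean
fit), and the Wald statistic is referred to a t distribution on the
residual df. Both choices matter: unpenalised ML dispersion at RNA-seq
replicate numbers (12 samples, 4 mean parameters) is biased low and makes
the normal-reference Wald test strongly anti-conservative (about 14% of
null genes below p = 0.05 in our calibration experiments), whereas the
df-corrected estimator with the t reference is calibrated (null p-values
uniform by KS) while retaining over 90% power at a log2 fold-change of 2
with dispersion 0.1 and 3 replicates per cell. No shrinkage across genes
is applied because the models are deliberately gene-specific.

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the analyses assume:
divergent parental pools with an intermediate-frequency background
spectrum (Beta(0.8, 0.8) truncated to [0.05, 0.95], mimicking what variant
filtering leaves), fixed-difference focal loci, viability selection at the
even-generation bottleneck proportional to `1 + s x (tropical dosage)` (a
genotype-level stand-in for phenotypic heat-shock selection),
logit-linear seasonal forcing with sinusoid-plus-AR(1) weather, purely
epistatic line panels, and negative-binomial expression counts. They do
**not** emulate real *D. melanogaster* linkage structure, inversions,
demography, or read-level artefacts; passing tests therefore demonstrate
that the statistical machinery is correct and calibrated, not that any
particular biological conclusion transfers to real data.

Default generator settings follow the experimental design wherever it
states them (six F16 replicates, 30-diploid pools at 85x, K = 1500, 80%
bottleneck, 300 migrants, 100 neutral replicates per window). Where it
does not, defaults are fixed once at field-typical values: 20 embryos per
assay plate (a 5x4 grid), genotype-class proportions 8:23:13:22 as
observed in the reference panel, baseline survival 0.2 under an 80%
mortality heat shock, three collection years of 10 samples each for the
seasonal series.

## Numerical choices and degenerate inputs

* Envelope quantiles are nearest-rank (`ceiling(q n)`-th order statistic);
  no interpolation.
* Top-quantile ties break by stable site order so flag counts are exact.
* Successes for the binomial GLM use round-half-even.
* Monomorphic sites are excluded from PCA and FST; sites with zero
  between-pool diversity return `NA` FST.
* Degenerate fits (constant covariate, separation, empty design cells,
  all-zero genes) error or are flagged explicitly — never silently
  dropped into results.
* Sub-seeds derive from the master seed as
  `(seed + 1000003 * counter) mod 2147483629` (`subseed()`), making every
  replicate independent yet bit-reproducible.

## Problem sizes used by the test suite

The validation experiments run at desk scale, chosen once: martingale and
recurrence checks use 500 replicates of the full 1500-individual
simulator; noise-model identities use \(10^5\) draws; the end-to-end
recovery experiment uses 50 planted and 60 neutral pipeline runs on an
8-window genome with a 20-replicate envelope; calibration experiments use
100–500 simulated panels, series or genes. The published experiment's
full scale (608 windows x 100 replicates) is bookkeeping-checked exactly
but not re-simulated in routine testing.

## Known limitations

* The backcross recurrence assumes survivors and migrants contribute
  equally, exact only when `round((1 - bottleneck) K) = n_migrants` as in
  the default design.
* The FST estimator's algebra is validated by oracle agreement, not by
  matching any specific published implementation's internals.
* The ANOVA covariate coding that yields df (1, 55) assumes two
  three-level inversion factors and a binary symbiont status; other
  codings change the residual df.
* Expression dispersion is estimated per gene without shrinkage; with
  fewer than 3 replicates per cell the per-gene estimate is unstable and
  power drops sharply.
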