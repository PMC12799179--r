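# Outlier scans for candidate introgression targets: genome-wide
# top-quantile flagging of FST values, per-window binomial enrichment,
# envelope-calibrated window calls, the synthetic-pool Fisher's exact SNP
# scan, and multiplicity control.

#' Flag the top quantile of a statistic genome-wide
#'
#' Flags the `ceiling(q * n)` largest defined values. Ties at the cutoff are
#' broken by stable site order (earlier sites win), so the flag count is
#' exact. Depends only on ranks: any strictly monotone transform of the
#' values yields identical flags.
#'
#' @param values numeric vector (NA allowed; never flagged). At least 100
#'   defined values are required.
#' @param q upper-tail quantile to flag, default 0.01.
#' @return Logical vector of flags aligned with `values`.
#' @export
flag_top_quantile <- function(values, q = 0.01) {
  assert_prob(q, "q", open = TRUE)
  defined <- which(!is.na(values))
  n <- length(defined)
  if (n < 100L) stop("need >= 100 defined values to flag a top quantile")
  m <- ceiling(q * n)
  ord <- defined[order(values[defined], decreasing = TRUE)]  # stable for ties
  flags <- logical(length(values))
  flags[ord[seq_len(m)]] <- TRUE
  flags
}

#' Per-window binomial enrichment of flagged SNPs
#'
#' Null hypothesis: a fraction `null_rate` of the SNPs in any window are
#' flagged (e.g. 1% of SNPs fall in the genome-wide top 1%). For a window
#' with `k` SNPs of which `x` are flagged, the upper-tail p-value is
#' `P[Binomial(k, null_rate) >= x]`.
#'
#' @param flags logical vector of per-site flags (from
#'   [flag_top_quantile()]).
#' @param windows window assignment for each site (factor or character).
#' @param null_rate null per-SNP flag probability, default 0.01.
#' @return Data.frame of class `window_enrichment`: `window`, `k` (SNPs),
#'   `x` (flagged), `p` (upper-tail binomial p). Empty windows are skipped
#'   with a message.
#' @export
window_enrichment <- function(flags, windows, null_rate = 0.01) {
  if (length(flags) != length(windows)) stop("flags and windows must align")
  assert_prob(null_rate, "null_rate", open = TRUE)
  f <- factor(windows)
  empty <- setdiff(levels(f), levels(droplevels(f)))
  if (length(empty))
    message("window_enrichment: skipping empty windows: ",
            paste(empty, collapse = ", "))
  k <- as.vector(table(f))
  x <- as.vector(tapply(flags, f, sum, default = 0L))
  keep <- k > 0L
  out <- data.frame(window = levels(f)[keep], k = k[keep], x = x[keep],
                    p = stats::pbinom(x[keep] - 1L, k[keep], null_rate,
                                      lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("window_enrichment", "data.frame")
  out
}

#' Call windows whose statistic exceeds the neutral envelope in every
#' replicate
#'
#' A window is significant only when the observed statistic exceeds its
#' neutral-envelope threshold in all replicates (the all-replicates AND
#' rule), the conservative criterion under which every experimental
#' replicate must outperform the simulated drift distribution.
#'
#' @param stats matrix of observed per-window statistics, rows = windows
#'   (rownames are window ids), columns = experimental replicates.
#' @param envelope named threshold vector from [build_envelope()].
#' @return Data.frame: `window`, `n_replicates`, `n_exceed` (replicates
#'   above threshold), `min_stat`, `threshold`, `significant`.
#' @export
call_significant_windows <- function(stats, envelope) {
  stats <- as.matrix(stats)
  if (is.null(rownames(stats))) stop("stats must carry window ids as rownames")
  missing <- setdiff(rownames(stats), names(envelope))
  if (length(missing)) stop("windows missing from envelope: ",
                            paste(missing, collapse = ", "))
  thr <- envelope[rownames(stats)]
  exceed <- sweep(stats, 1L, thr, `>`)
  data.frame(window = rownames(stats),
             n_replicates = ncol(stats),
             n_exceed = rowSums(exceed),
             min_stat = apply(stats, 1L, min),
             threshold = as.numeric(thr),
             significant = rowSums(exceed) == ncol(stats),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' SNP-wise Fisher's exact scan of a synthetic pool against a parent
#'
#' Aggregates all F16 pools element-wise into a single "synthetic pool"
#' (summed alternate and total read counts) to maximise power, then tests
#' each site with a two-sided Fisher's exact test on the 2x2 table
#' `[[alt_syn, ref_syn], [alt_vt, ref_vt]]`. Sites whose pooled minor allele
#' frequency (synthetic + parent reads combined) falls below `min_maf`, or
#' with zero total reads in either pool, are excluded.
#'
#' @param f16 list of F16 [pool_sample()] objects with aligned sites.
#' @param vt the parental [pool_sample()].
#' @param min_maf minor-allele-frequency cutoff, default 0.05; sites below
#'   it are excluded.
#' @param alpha family-wise level for the Bonferroni flag, default 0.01.
#' @return Data.frame of class `fet_result`, one row per tested site:
#'   `site` (index into the input), `alt_syn`, `tot_syn`, `alt_vt`,
#'   `tot_vt`, `p`, `q` (Benjamini-Hochberg), `bonferroni` (significant at
#'   `alpha` after Bonferroni correction over the tested sites).
#' @export
fet_scan <- function(f16, vt, min_maf = 0.05, alpha = 0.01) {
  if (!is.list(f16) || length(f16) < 1L) stop("need at least one F16 pool")
  stopifnot(all(vapply(f16, inherits, logical(1), "pool_sample")),
            inherits(vt, "pool_sample"))
  s <- length(vt$alt)
  if (any(vapply(f16, function(x) length(x$alt), integer(1)) != s))
    stop("all pools must cover the same aligned sites")
  alt_syn <- Reduce(`+`, lapply(f16, `[[`, "alt"))
  tot_syn <- Reduce(`+`, lapply(f16, `[[`, "total"))
  alt_vt <- vt$alt; tot_vt <- vt$total

  zero <- tot_syn == 0 | tot_vt == 0
  if (any(zero))
    message("fet_scan: skipping ", sum(zero), " site(s) with zero coverage")
  pooled <- (alt_syn + alt_vt) / (tot_syn + tot_vt)
  maf <- pmin(pooled, 1 - pooled)
  keep <- which(!zero & maf >= min_maf)
  if (!length(keep)) stop("no sites pass the coverage and MAF filters")

  p <- vapply(keep, function(i) {
    stats::fisher.test(matrix(c(alt_syn[i], tot_syn[i] - alt_syn[i],
                                alt_vt[i], tot_vt[i] - alt_vt[i]),
                              nrow = 2L, byrow = TRUE))$p.value
  }, numeric(1))
  m <- length(p)
  out <- data.frame(site = keep,
                    alt_syn = alt_syn[keep], tot_syn = tot_syn[keep],
                    alt_vt = alt_vt[keep], tot_vt = tot_vt[keep],
                    p = p, q = stats::p.adjust(p, method = "BH"),
                    bonferroni = p < alpha / m,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fet_result", "data.frame")
  out
}

#' Multiple-testing adjustment for a p-value vector
#'
#' `method = "bh"` returns Benjamini-Hochberg step-up q-values; `method =
#' "bonferroni"` returns the family-wise threshold `alpha / m` together with
#' the rejection flags (with one million tests at `alpha = 0.01` the
#' threshold is `1e-8`).
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @param alpha level used for the Bonferroni threshold, default 0.05.
#' @return For `"bh"`, a numeric q-value vector; for `"bonferroni"`, a list
#'   with `threshold` and logical `reject`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  thr <- alpha / length(p)
  list(threshold = thr, reject = p < thr)
}
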