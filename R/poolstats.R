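# Pool-seq summary statistics: effective coverage, pairwise FST from read
# counts, global and sliding-window PCA, and the parent-similarity distance
# ratio used to classify F16 genomic backgrounds.

#' Effective coverage of a pooled sample
#'
#' Reads sample pool chromosomes with replacement, so the information in `r`
#' reads from a pool of `n` chromosomes is equivalent to
#' `n_e = n r / (n + r)` independently sampled chromosomes. Monotone
#' increasing in both arguments and bounded by `min(n, r)`.
#'
#' @param n chromosomes in the pool (>= 2), vectorised.
#' @param r read depth (>= 1), vectorised.
#' @return Effective coverage `n_e`.
#' @export
effective_coverage <- function(n, r) {
  if (any(n < 2)) stop("pool chromosome count n must be >= 2")
  if (any(r < 1)) stop("read depth r must be >= 1")
  n * r / (n + r)
}

#' Construct a pooled sequencing sample
#'
#' @param id sample identifier.
#' @param role one of `"parent_VT"`, `"parent_SK"`, `"F16"`, `"wild"`.
#' @param alt,total per-site alternate and total read counts.
#' @param n_chrom chromosomes in the pool (e.g. 60 for 30 diploids).
#' @param arm,pos optional per-site coordinates (1-based).
#' @return A list of class `pool_sample`; `n_e` holds the per-site effective
#'   coverage.
#' @export
pool_sample <- function(id, role = c("F16", "parent_VT", "parent_SK", "wild"),
                        alt, total, n_chrom, arm = NULL, pos = NULL) {
  role <- match.arg(role)
  if (length(alt) != length(total)) stop("alt and total must have equal length")
  if (any(alt < 0 | alt > total)) stop("need 0 <= alt <= total at every site")
  n_chrom <- assert_count(n_chrom, "n_chrom", min = 2L)
  if (!is.null(pos) && length(pos) != length(alt))
    stop("pos must align with the count vectors")
  ne <- ifelse(total >= 1, effective_coverage(n_chrom, pmax(total, 1)), 0)
  ne[total < 1] <- 0
  structure(list(id = as.character(id), role = role,
                 alt = as.numeric(alt), total = as.numeric(total),
                 n_chrom = n_chrom, n_e = ne,
                 arm = if (is.null(arm)) NULL else as.character(rep_len(arm, length(alt))),
                 pos = if (is.null(pos)) NULL else as.numeric(pos)),
            class = "pool_sample")
}

# Unbiased per-site identity components for a pool: Dw estimates the
# population heterozygosity 2p(1-p) after correcting for (i) read pairs hit
# the same pool chromosome with probability 1/n and (ii) finite pool size.
pool_heterozygosity <- function(alt, total, n_chrom) {
  dw <- 2 * alt * (total - alt) / (total * (total - 1)) *
    n_chrom / (n_chrom - 1)
  dw[total < 2] <- NA_real_
  dw
}

#' Pairwise pool-seq FST between two samples
#'
#' Identity-probability moment estimator. Per site, `Dw` is the unbiased
#' within-pool heterozygosity (read pairs corrected for with-replacement
#' sampling of the `n` pool chromosomes) and `Db` the between-pool
#' heterozygosity from read-frequency cross products; the per-site estimator
#' is `(Db - (Dw_a + Dw_b)/2) / Db`, a Hudson-type ratio. Sites with no
#' variation in either pool (`Db = 0`) or depth below 2 in a pool are
#' undefined (`NA`) and excluded from window sums. Window- or genome-level
#' values are ratios of summed numerators to summed denominators
#' ("ratio of averages").
#'
#' @param sample_a,sample_b [pool_sample()] objects with aligned sites.
#' @param windows optional factor/character vector assigning each site to a
#'   window; when given, per-window ratio-of-averages FST is returned too.
#' @return List with `per_site` (data.frame: `num`, `den`, `fst`), `global`
#'   (ratio-of-averages over all defined sites) and, if `windows` was given,
#'   `by_window` (data.frame: `window`, `n_sites`, `fst`).
#' @export
pairwise_fst <- function(sample_a, sample_b, windows = NULL) {
  stopifnot(inherits(sample_a, "pool_sample"), inherits(sample_b, "pool_sample"))
  if (length(sample_a$alt) != length(sample_b$alt))
    stop("samples must cover the same aligned sites")
  ca <- sample_a$alt; ra <- sample_a$total
  cb <- sample_b$alt; rb <- sample_b$total
  dwa <- pool_heterozygosity(ca, ra, sample_a$n_chrom)
  dwb <- pool_heterozygosity(cb, rb, sample_b$n_chrom)
  db <- (ca * (rb - cb) + cb * (ra - ca)) / (ra * rb)
  db[ra < 1 | rb < 1] <- NA_real_
  num <- db - (dwa + dwb) / 2
  den <- db
  fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  per_site <- data.frame(num = num, den = den, fst = fst)
  defined <- !is.na(fst)
  if (!any(defined)) stop("FST undefined at every site")
  global <- sum(num[defined]) / sum(den[defined])
  out <- list(per_site = per_site, global = global)
  if (!is.null(windows)) {
    if (length(windows) != length(ca)) stop("windows must align with the sites")
    w <- split(which(defined), factor(windows[defined]))
    out$by_window <- data.frame(
      window = names(w),
      n_sites = lengths(w),
      fst = vapply(w, function(i) sum(num[i]) / sum(den[i]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Principal component analysis of a sample-by-site frequency matrix
#'
#' Columns are centred but not variance-scaled (allele frequencies share a
#' scale). Sites monomorphic across all samples are dropped.
#'
#' @param freq matrix of allele frequencies, samples in rows (rownames are
#'   sample ids), sites in columns.
#' @param window_id label stored in the result (default `"global"`).
#' @return A list of class `pca_result`: `scores` (samples x PCs), `pve`
#'   (percent variance explained per PC), `window`, `n_sites`.
#' @export
pca_global <- function(freq, window_id = "global") {
  freq <- as.matrix(freq)
  if (nrow(freq) < 3L) stop("PCA needs at least 3 samples")
  poly <- apply(freq, 2L, function(x) stats::var(x) > 0)
  poly[is.na(poly)] <- FALSE
  if (sum(poly) < 2L) stop("PCA needs at least 2 polymorphic sites")
  pc <- stats::prcomp(freq[, poly, drop = FALSE], center = TRUE, scale. = FALSE)
  pve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, pve = pve, window = window_id,
                 n_sites = sum(poly)),
            class = "pca_result")
}

#' Sliding-window PCA along a chromosome arm
#'
#' Windows are half-open `[start, start + window_size)` on 1-based
#' coordinates, stepped by `step` from position 1; the last partial window is
#' retained. Windows with fewer than `min_sites` polymorphic sites are
#' skipped with a message.
#'
#' @param freq samples x sites allele-frequency matrix.
#' @param pos 1-based site positions (one per column of `freq`).
#' @param window_size,step window width and step in bases (defaults 0.1 Mb
#'   and 50 kb).
#' @param min_sites minimum polymorphic sites per window (default 2).
#' @return A list of `pca_result` objects named by window.
#' @export
pca_sliding <- function(freq, pos, window_size = 1e5, step = 5e4, min_sites = 2L) {
  freq <- as.matrix(freq)
  if (length(pos) != ncol(freq)) stop("pos must have one entry per site column")
  if (nrow(freq) < 3L) stop("PCA needs at least 3 samples")
  starts <- seq(1, max(pos), by = step)
  out <- list()
  for (s in starts) {
    in_win <- pos >= s & pos < s + window_size
    if (!any(in_win)) next
    sub <- freq[, in_win, drop = FALSE]
    n_poly <- sum(apply(sub, 2L, function(x) isTRUE(stats::var(x) > 0)))
    id <- sprintf("%d-%d", as.integer(s), as.integer(s + window_size - 1))
    if (n_poly < min_sites) {
      message("pca_sliding: skipping window ", id, " (", n_poly,
              " polymorphic sites < ", min_sites, ")")
      next
    }
    out[[id]] <- pca_global(sub, window_id = id)
  }
  out
}

#' Parent-similarity distance ratio in PC space
#'
#' For each F16 sample, computes the Euclidean distances in the PC1-PC2
#' plane to the SK and VT parents and returns `log2(d_SK / d_VT)`. Positive
#' values indicate higher similarity to the VT parent, negative values
#' higher similarity to the SK parent. An F16 coincident with a parent
#' yields a signed infinite sentinel with a warning; such values should be
#' excluded from means.
#'
#' @param coords a `pca_result` from [pca_global()] or [pca_sliding()].
#' @param parent_vt,parent_sk row ids of the two parents in the scores.
#' @param f16 character vector of F16 row ids.
#' @return Named numeric vector of `log2(d_SK/d_VT)` values.
#' @export
parent_distance_ratio <- function(coords, parent_vt, parent_sk, f16) {
  stopifnot(inherits(coords, "pca_result"))
  sc <- coords$scores[, 1:2, drop = FALSE]
  ids <- rownames(sc)
  missing <- setdiff(c(parent_vt, parent_sk, f16), ids)
  if (length(missing)) stop("samples absent from PCA scores: ",
                            paste(missing, collapse = ", "))
  d <- function(a, b) sqrt(sum((sc[a, ] - sc[b, ])^2))
  out <- vapply(f16, function(s) {
    dv <- d(s, parent_vt); ds <- d(s, parent_sk)
    if (dv == 0 || ds == 0) {
      warning("F16 sample ", s, " coincides with a parent; returning a ",
              "signed infinite sentinel", call. = FALSE)
      return(if (ds == 0) -Inf else Inf)
    }
    log2(ds / dv)
  }, numeric(1))
  names(out) <- f16
  out
}
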