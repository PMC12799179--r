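# File readers/writers for pool counts (sync and minimal VCF dialects),
# run configuration, and the end-to-end pipeline that chains simulation,
# FST scanning, envelope calibration, window calls and the FET scan.
# Coordinates are 1-based inclusive throughout.

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Write pool samples as a sync-style count table
#'
#' popoolation2-style dialect: tab-separated `chrom pos ref` followed by one
#' `A:T:C:G:N:del` count string per sample. Reference counts are placed in
#' the `ref` base slot and alternate counts in the `alt` base slot.
#'
#' @param samples list of [pool_sample()] objects with aligned sites and
#'   `arm`/`pos` coordinates.
#' @param path output file.
#' @param ref,alt reference and alternate bases used to encode the counts
#'   (defaults `"A"` and `"T"`).
#' @return `path`, invisibly.
#' @export
write_sync <- function(samples, path, ref = "A", alt = "T") {
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "pool_sample")))
  s1 <- samples[[1L]]
  if (is.null(s1$arm) || is.null(s1$pos))
    stop("samples need arm and pos coordinates to be written as sync")
  if (ref == alt || !all(c(ref, alt) %in% SYNC_BASES[1:4]))
    stop("ref and alt must be distinct nucleotides")
  n_sites <- length(s1$alt)
  cols <- lapply(samples, function(s) {
    counts <- matrix(0L, 6L, n_sites)
    counts[match(ref, SYNC_BASES), ] <- as.integer(s$total - s$alt)
    counts[match(alt, SYNC_BASES), ] <- as.integer(s$alt)
    apply(counts, 2L, paste, collapse = ":")
  })
  lines <- do.call(paste, c(list(s1$arm, s1$pos, ref), cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write pool samples as a minimal VCF with allele-depth fields
#'
#' One biallelic record per site with `FORMAT = AD:DP` (`AD` holds
#' `ref,alt` read counts, `DP` the total).
#'
#' @inheritParams write_sync
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(samples, path, ref = "A", alt = "T") {
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "pool_sample")))
  s1 <- samples[[1L]]
  if (is.null(s1$arm) || is.null(s1$pos))
    stop("samples need arm and pos coordinates to be written as VCF")
  ids <- vapply(samples, `[[`, character(1), "id")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  geno <- lapply(samples, function(s)
    sprintf("%d,%d:%d", as.integer(s$total - s$alt), as.integer(s$alt),
            as.integer(s$total)))
  lines <- do.call(paste, c(list(s1$arm, s1$pos, ".", ref, alt, ".", "PASS",
                                 ".", "AD:DP"), geno, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

parse_sync_lines <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L || nf[1L] < 4L)
    stop("malformed sync file ", path, ": line ",
         which(nf != max(nf, 4L))[1L] %||% 1L,
         " has an inconsistent field count")
  m <- do.call(rbind, fields)
  n_samples <- ncol(m) - 3L
  counts <- array(NA_integer_, c(nrow(m), n_samples, 6L))
  for (j in seq_len(n_samples)) {
    sp <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    bad <- which(lengths(sp) != 6L)
    if (length(bad))
      stop("malformed sync count string in ", path, " at line ", bad[1L])
    counts[, j, ] <- matrix(as.integer(unlist(sp)), ncol = 6L, byrow = TRUE)
  }
  if (anyNA(counts)) stop("non-integer counts in sync file ", path)
  list(arm = m[, 1L], pos = as.numeric(m[, 2L]), ref = toupper(m[, 3L]),
       counts = counts)
}

#' Read pooled allele counts from a sync or minimal VCF file
#'
#' Returns biallelic sites only: the alternate allele is the most frequent
#' non-reference allele summed across all samples jointly (consistent
#' site-wise polarisation); additional non-reference alleles at
#' multi-allelic sites are dropped with a logged note, and `total` is the
#' `ref + alt` read count. For VCF input, per-sample `AD` fields are
#' required.
#'
#' @param path input file.
#' @param format `"sync"` or `"vcf"`.
#' @param n_chrom pool chromosome count assigned to every sample (sync and
#'   VCF files do not carry it), default 60.
#' @param role role assigned to the returned samples (default `"wild"`).
#' @return List with `samples` (list of [pool_sample()]) and `sites`
#'   (data.frame: arm, pos, ref, alt).
#' @export
read_pool_counts <- function(path, format = c("sync", "vcf"), n_chrom = 60L,
                             role = "wild") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "sync") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty sync file: ", path)
    parsed <- parse_sync_lines(lines, path)
    ref_idx <- match(parsed$ref, SYNC_BASES)
    if (anyNA(ref_idx)) stop("unknown reference base in ", path)
    n_sites <- length(parsed$pos)
    n_samples <- dim(parsed$counts)[2L]
    tot_by_base <- apply(parsed$counts, c(1L, 3L), sum)  # site x base
    nonref <- tot_by_base
    nonref[cbind(seq_len(n_sites), ref_idx)] <- -1L
    alt_idx <- max.col(nonref, ties.method = "first")
    multi <- rowSums(nonref > 0) > 1L
    if (any(multi))
      message("read_pool_counts: ", sum(multi),
              " multi-allelic site(s) reduced to the two most frequent alleles")
    samples <- lapply(seq_len(n_samples), function(j) {
      ref_c <- parsed$counts[cbind(seq_len(n_sites), j, ref_idx)]
      alt_c <- parsed$counts[cbind(seq_len(n_sites), j, alt_idx)]
      pool_sample(paste0("pool", j), role, alt_c, ref_c + alt_c, n_chrom,
                  arm = parsed$arm, pos = parsed$pos)
    })
    sites <- data.frame(arm = parsed$arm, pos = parsed$pos,
                        ref = parsed$ref, alt = SYNC_BASES[alt_idx],
                        stringsAsFactors = FALSE)
    return(list(samples = samples, sites = sites))
  }
  # minimal VCF dialect
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("VCF lacks per-sample AD fields: ", path)
  missing_samp <- colnames(ad)[colSums(is.na(ad)) > 0]
  if (length(missing_samp))
    stop("missing AD fields for sample(s): ",
         paste(missing_samp, collapse = ", "))
  arm <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  samples <- lapply(seq_len(ncol(ad)), function(j) {
    parts <- strsplit(ad[, j], ",", fixed = TRUE)
    ref_c <- as.numeric(vapply(parts, `[`, character(1), 1L))
    alt_c <- as.numeric(vapply(parts, `[`, character(1), 2L))
    pool_sample(colnames(ad)[j], role, alt_c, ref_c + alt_c, n_chrom,
                arm = arm, pos = pos)
  })
  sites <- data.frame(arm = arm, pos = pos, ref = fix[, "REF"],
                      alt = fix[, "ALT"], stringsAsFactors = FALSE)
  list(samples = samples, sites = sites)
}

#' Configuration for an end-to-end introgression scan
#'
#' Validates all thresholds before any compute.
#'
#' @param f16 list of F16 [pool_sample()] objects.
#' @param vt,sk parental [pool_sample()] objects (aligned sites).
#' @param window_map a [window_map()].
#' @param sim a [sim_params()]; `sim$n_replicates` neutral replicates per
#'   window build the envelope at `sim$envelope_quantile`.
#' @param top_quantile genome-wide FST flag quantile, in (0, 1).
#' @param alpha family-wise level for the FET Bonferroni flag, in (0, 1).
#' @param min_maf FET minor-allele-frequency cutoff, in [0, 0.5].
#' @param seed master seed; every random stage derives sub-seeds from it.
#' @param outdir optional output directory for TSV artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(f16, vt, sk, window_map, sim = sim_params(),
                       top_quantile = 0.01, alpha = 0.01, min_maf = 0.05,
                       seed = 1L, outdir = NULL) {
  stopifnot(is.list(f16), length(f16) >= 1L,
            all(vapply(f16, inherits, logical(1), "pool_sample")),
            inherits(vt, "pool_sample"), inherits(sk, "pool_sample"),
            inherits(window_map, "window_map"), inherits(sim, "sim_params"))
  if (!is.numeric(top_quantile) || top_quantile <= 0 || top_quantile >= 1)
    stop("top_quantile must lie strictly in (0, 1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5]")
  seed <- assert_count(seed, "seed", min = 0L)
  if (is.null(vt$arm) || is.null(vt$pos))
    stop("pool samples need arm/pos coordinates for window assignment")
  structure(list(f16 = f16, vt = vt, sk = sk, window_map = window_map,
                 sim = sim, top_quantile = top_quantile, alpha = alpha,
                 min_maf = min_maf, seed = seed, outdir = outdir),
            class = "run_config")
}

# cheap deterministic content hash (djb2) of the configuration scalars
config_hash <- function(config) {
  key <- paste(config$seed, config$top_quantile, config$alpha, config$min_maf,
               config$sim$n_replicates, config$sim$envelope_quantile,
               length(config$f16), nrow(config$window_map),
               paste(config$vt$alt, collapse = ","), sep = "|")
  h <- 5381
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

assign_windows <- function(arm, pos, wm) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(wm))) {
    hit <- arm == wm$arm[i] & pos >= wm$start[i] & pos <= wm$end[i]
    out[hit] <- wm$window[i]
  }
  out
}

window_flag_counts <- function(flags, windows, window_ids) {
  vapply(window_ids, function(w) sum(flags[windows == w], na.rm = TRUE),
         numeric(1))
}

#' Run the full introgression scan pipeline
#'
#' Executes, in order: per-replicate FST against the VT parent; genome-wide
#' top-quantile flagging per replicate; per-window flag counts and binomial
#' enrichment; neutral-introgression envelope simulation (parental
#' frequencies estimated from the parental pool counts); envelope-based
#' window calls under the all-replicates rule; the synthetic-pool FET scan
#' with BH and Bonferroni adjustment. Every artifact carries the seed and a
#' configuration hash; a rerun with an identical configuration reproduces
#' the bundle exactly.
#'
#' @param config a [run_config()].
#' @return A list of class `scan_bundle`: `seed`, `hash`, `sites`,
#'   `fst_by_rep`, `flag_counts` (windows x replicates), `enrichment`,
#'   `sim_counts`, `envelope`, `calls`, `fet`, `log` (per-stage row
#'   counts). If `config$outdir` is set, TSV artifacts are written as each
#'   stage completes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wm <- config$window_map
  vt <- config$vt; sk <- config$sk; f16 <- config$f16
  hash <- config_hash(config)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  log <- list(seed = config$seed, hash = hash)
  emit <- function(df, name) {
    if (!is.null(outdir))
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  windows <- assign_windows(vt$arm, vt$pos, wm)
  in_map <- !is.na(windows)
  if (!any(in_map)) stop("no sites fall inside the window map")
  wids <- wm$window[wm$window %in% windows]
  sites <- data.frame(arm = vt$arm, pos = vt$pos, window = windows,
                      stringsAsFactors = FALSE)
  log$n_sites <- nrow(sites); log$n_windows <- length(wids)

  # stage: fst ------------------------------------------------------------
  fst_by_rep <- stage("fst", lapply(f16, function(s) pairwise_fst(s, vt)))
  fst_mat <- vapply(fst_by_rep, function(x) x$per_site$fst,
                    numeric(nrow(sites)))
  emit(cbind(sites, stats::setNames(as.data.frame(fst_mat),
                                    paste0("fst_rep", seq_along(f16)))), "fst")

  # stage: flags + enrichment ---------------------------------------------
  flag_mat <- stage("flags", apply(fst_mat, 2L, flag_top_quantile,
                                   q = config$top_quantile))
  counts <- stage("enrichment", vapply(seq_along(f16), function(j)
    window_flag_counts(flag_mat[, j] & in_map, windows, wids),
    numeric(length(wids))))
  counts <- matrix(counts, nrow = length(wids),
                   dimnames = list(wids, paste0("rep", seq_along(f16))))
  enrich <- stage("enrichment", lapply(seq_along(f16), function(j) {
    keep <- in_map & !is.na(fst_mat[, j])
    cbind(rep = j, window_enrichment(flag_mat[keep, j], windows[keep],
                                     null_rate = config$top_quantile))
  }))
  enrich <- do.call(rbind, enrich)
  emit(enrich, "enrichment")
  log$n_flags_per_rep <- colSums(flag_mat)

  # stage: envelope --------------------------------------------------------
  sim_counts <- stage("envelope", {
    p_vt_hat <- pmin(pmax(vt$alt / pmax(vt$total, 1), 0), 1)
    p_sk_hat <- pmin(pmax(sk$alt / pmax(sk$total, 1), 0), 1)
    n_rep <- config$sim$n_replicates
    m <- matrix(NA_real_, length(wids), n_rep, dimnames = list(wids, NULL))
    for (r in seq_len(n_rep)) {
      sim_fst <- rep(NA_real_, nrow(sites))
      for (w in wids) {
        idx <- which(windows == w & in_map)
        wrow <- wm[wm$window == w, ]
        win <- window_spec(wrow$arm, wrow$start, wrow$end, wrow$rho,
                           vt$pos[idx])
        tr <- simulate_introgression(win, config$sim, p_vt_hat[idx],
                                     p_sk_hat[idx],
                                     mode = "neutral_introgression",
                                     seed = subseed(config$seed,
                                                    r * 100000 + match(w, wids)))
        sim_pool <- pool_sample("sim", "F16", tr$alt, tr$total,
                                2L * config$sim$pool_diploids)
        sub_vt <- pool_sample("VT", "parent_VT", vt$alt[idx], vt$total[idx],
                              vt$n_chrom)
        sim_fst[idx] <- pairwise_fst(sim_pool, sub_vt)$per_site$fst
      }
      sim_flags <- flag_top_quantile(sim_fst, q = config$top_quantile)
      m[, r] <- window_flag_counts(sim_flags, windows, wids)
    }
    m
  })
  envelope <- build_envelope(sim_counts, config$sim$envelope_quantile)
  emit(data.frame(window = names(envelope), threshold = envelope),
       "envelope")

  # stage: calls ------------------------------------------------------------
  calls <- stage("calls", call_significant_windows(counts, envelope))
  emit(calls, "calls")
  log$n_called <- sum(calls$significant)

  # stage: fet + adjust -----------------------------------------------------
  fet <- stage("fet", fet_scan(f16, vt, min_maf = config$min_maf,
                               alpha = config$alpha))
  fet$arm <- vt$arm[fet$site]
  fet$pos <- vt$pos[fet$site]
  emit(fet, "fet")
  log$n_fet_sites <- nrow(fet)
  log$n_fet_bonferroni <- sum(fet$bonferroni)

  if (!is.null(outdir))
    writeLines(c(paste("seed:", config$seed), paste("hash:", hash),
                 paste("sites:", log$n_sites),
                 paste("windows:", log$n_windows),
                 paste("called:", log$n_called),
                 paste("fet_sites:", log$n_fet_sites)),
               file.path(outdir, "run_log.txt"))

  structure(list(seed = config$seed, hash = hash, sites = sites,
                 fst_by_rep = fst_by_rep, flag_counts = counts,
                 enrichment = enrich, sim_counts = sim_counts,
                 envelope = envelope, calls = calls, fet = fet, log = log),
            class = "scan_bundle")
}
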