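# Two-locus phenotype statistics for inbred line panels: genotype classing,
# exact binomial confidence intervals, the epistasis ANOVA, pairwise r2
# between candidate loci, and the gene-specific negative-binomial
# interaction test for expression.

#' Classify lines by their two-locus genotype
#'
#' At the 2R locus the `C` allele is tropical and `A` temperate; at the X
#' locus `T` is tropical and `A` temperate. The class name gives the 2R
#' origin first.
#'
#' @param allele_2R vector of `"C"`/`"A"` alleles.
#' @param allele_X vector of `"T"`/`"A"` alleles.
#' @return Character vector with values `tropical_tropical`,
#'   `tropical_temperate`, `temperate_tropical`, `temperate_temperate`.
#' @export
genotype_class <- function(allele_2R, allele_X) {
  if (length(allele_2R) != length(allele_X)) stop("allele vectors must align")
  if (!all(allele_2R %in% c("C", "A")))
    stop("unknown allele symbol at 2R (expected C or A)")
  if (!all(allele_X %in% c("T", "A")))
    stop("unknown allele symbol at X (expected T or A)")
  paste(ifelse(allele_2R == "C", "tropical", "temperate"),
        ifelse(allele_X == "T", "tropical", "temperate"), sep = "_")
}

#' Exact (Clopper-Pearson) binomial confidence interval per line
#'
#' @param survived,assayed per-line counts, `0 <= survived <= assayed`,
#'   `assayed >= 1` (vectorised).
#' @param level confidence level, default 0.95.
#' @return Data.frame with columns `lower`, `upper`.
#' @export
line_binom_ci <- function(survived, assayed, level = 0.95) {
  if (length(survived) != length(assayed)) stop("inputs must align")
  if (any(assayed < 1)) stop("assayed must be >= 1")
  if (any(survived < 0 | survived > assayed))
    stop("need 0 <= survived <= assayed")
  assert_prob(level, "level", open = TRUE)
  a <- (1 - level) / 2
  lower <- ifelse(survived == 0, 0,
                  stats::qbeta(a, survived, assayed - survived + 1))
  upper <- ifelse(survived == assayed, 1,
                  stats::qbeta(1 - a, survived + 1, assayed - survived))
  data.frame(lower = lower, upper = upper)
}

#' Two-way epistasis ANOVA on line-panel survival proportions
#'
#' Linear model on per-line survival proportions with main effects of the
#' 2R and X genotypes, their interaction, and (optionally) covariates for
#' symbiont infection and the two inversion genotypes. The interaction is
#' tested with a Type-III F test (sum-to-zero contrasts), appropriate for
#' the unbalanced class counts of a natural panel.
#'
#' @param panel data.frame with columns `allele_2R`, `allele_X`, `survived`,
#'   `assayed`, and (if `include_covariates`) `wolbachia`, `In2Lt`,
#'   `In2RNS`.
#' @param include_covariates include the covariate terms (default TRUE when
#'   the columns are present).
#' @param weighted weight lines by the number of embryos assayed (default
#'   FALSE: unweighted proportions).
#' @return A list of class `survival_anova`: `interaction` (list `F`,
#'   `df1`, `df2`, `p`), `table` (full Type-III ANOVA table as a
#'   data.frame), `fit`.
#' @export
survival_anova <- function(panel,
                           include_covariates = all(c("wolbachia", "In2Lt", "In2RNS") %in% names(panel)),
                           weighted = FALSE) {
  need <- c("allele_2R", "allele_X", "survived", "assayed")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "))
  d <- data.frame(prop = panel$survived / panel$assayed,
                  g2R = factor(panel$allele_2R, levels = c("A", "C")),
                  gX = factor(panel$allele_X, levels = c("A", "T")))
  if (any(table(d$g2R) < 2L) || any(table(d$gX) < 2L))
    stop("need >= 2 lines per marginal genotype")
  rhs <- "g2R * gX"
  ctr <- list(g2R = "contr.sum", gX = "contr.sum")
  if (include_covariates) {
    d$wolbachia <- factor(panel$wolbachia)
    d$In2Lt <- factor(panel$In2Lt)
    d$In2RNS <- factor(panel$In2RNS)
    cov_terms <- c("wolbachia", "In2Lt", "In2RNS")
    cov_terms <- cov_terms[vapply(cov_terms, function(t) nlevels(d[[t]]) > 1L,
                                  logical(1))]
    if (length(cov_terms)) {
      rhs <- paste(rhs, "+", paste(cov_terms, collapse = " + "))
      for (t in cov_terms) ctr[[t]] <- "contr.sum"
    }
  }
  w <- if (weighted) panel$assayed else NULL
  fit <- stats::lm(stats::as.formula(paste("prop ~", rhs)), data = d,
                   weights = w, contrasts = ctr)
  if (any(is.na(stats::coef(fit))))
    stop("aliased terms (empty design cells); the interaction is not estimable")
  tab <- car::Anova(fit, type = 3)
  tdf <- data.frame(term = rownames(tab), sum_sq = tab[["Sum Sq"]],
                    df = as.integer(tab[["Df"]]), F = tab[["F value"]],
                    p = tab[["Pr(>F)"]], row.names = NULL,
                    stringsAsFactors = FALSE)
  i <- which(tdf$term == "g2R:gX")
  res <- which(tdf$term == "Residuals")
  structure(list(interaction = list(F = tdf$F[i], df1 = tdf$df[i],
                                    df2 = tdf$df[res], p = tdf$p[i]),
                 table = tdf, fit = fit),
            class = "survival_anova")
}

#' Squared correlation of allele dosages between two loci
#'
#' @param a,b equal-length biallelic genotype vectors (numeric dosages, or
#'   factors/characters coerced to 0/1).
#' @return `r^2`, the squared Pearson correlation of dosages.
#' @export
genotype_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  to_dosage <- function(x) {
    if (is.numeric(x)) return(x)
    f <- factor(x)
    if (nlevels(f) > 2L) stop("genotype vector is not biallelic")
    as.numeric(f) - 1
  }
  a <- to_dosage(a); b <- to_dosage(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("monomorphic genotype vector; r2 undefined")
  stats::cor(a, b)^2
}

# NB2 dispersion alpha (var = mu + alpha mu^2) by degrees-of-freedom
# corrected Pearson moment matching: solve
# sum((y - mu)^2 / (mu + alpha mu^2)) = n - p. The df correction is what
# keeps the downstream Wald test calibrated at RNA-seq replicate numbers,
# where unpenalised ML dispersion is biased low and anti-conservative.
pearson_alpha <- function(y, mu, resid_df) {
  f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - resid_df
  if (f(0) <= 0) return(0)
  if (f(1e6) > 0) return(1e6)
  stats::uniroot(f, c(0, 1e6))$root
}

#' Gene-specific negative-binomial interaction test for expression counts
#'
#' Fits, per gene, a negative-binomial GLM with a log link,
#' `counts ~ background * temperature + offset(log(norm_factor))`. The NB2
#' dispersion is estimated per gene by degrees-of-freedom-corrected Pearson
#' moment matching, alternating with the mean fit; Wald statistics for every
#' background-by-temperature interaction coefficient are referred to a t
#' distribution on the residual degrees of freedom (both choices keep the
#' test calibrated at typical replicate numbers). P-values are
#' Benjamini-Hochberg adjusted across genes within each interaction term.
#'
#' @param counts genes x samples matrix of raw counts (rownames = gene
#'   ids).
#' @param background,temperature factors (or vectors) of length
#'   `ncol(counts)`.
#' @param norm_factors positive per-sample normalisation factors entering
#'   the model as offsets `log(norm_factor)`.
#' @return Data.frame of class `expression_fit`, one row per gene x
#'   interaction term: `gene`, `term`, `estimate` (log scale), `se`, `wald`
#'   (t statistic), `p`, `padj`, `dispersion` (estimated NB2 alpha),
#'   `converged`. All-zero genes are skipped with a message;
#'   non-convergent genes are reported with `converged = FALSE` and NA
#'   statistics.
#' @export
nb_interaction_test <- function(counts, background, temperature, norm_factors) {
  counts <- as.matrix(counts)
  n_s <- ncol(counts)
  if (length(background) != n_s || length(temperature) != n_s)
    stop("background and temperature must have one entry per sample")
  if (length(norm_factors) != n_s || any(norm_factors <= 0))
    stop("every sample needs a positive norm factor")
  # factor levels follow order of appearance so the first background and
  # first temperature are the reference cell
  d <- data.frame(
    bg = if (is.factor(background)) background else
      factor(background, levels = unique(background)),
    temp = if (is.factor(temperature)) temperature else
      factor(temperature, levels = unique(temperature)))
  if (nlevels(d$bg) < 2L || nlevels(d$temp) < 2L)
    stop("design needs >= 2 backgrounds and >= 2 temperatures")
  off <- log(norm_factors)
  mm <- stats::model.matrix(~ bg * temp, d)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is singular")
  int_cols <- grep(":", colnames(mm), value = TRUE)
  resid_df <- n_s - ncol(mm)
  if (resid_df < 1L) stop("design leaves no residual degrees of freedom")

  all_zero <- rowSums(counts) == 0
  if (any(all_zero))
    message("nb_interaction_test: skipping ", sum(all_zero), " all-zero gene(s)")
  genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))

  na_row <- function(g, alpha = NA_real_)
    data.frame(gene = g, term = int_cols, estimate = NA_real_,
               se = NA_real_, wald = NA_real_, p = NA_real_,
               dispersion = alpha, converged = FALSE,
               stringsAsFactors = FALSE)

  rows <- lapply(which(!all_zero), function(g) {
    y <- counts[g, ]
    dat <- cbind(d, y = y, off = off)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ bg * temp + offset(off),
                                  family = stats::poisson(), data = dat)),
      error = function(e) NULL)
    if (is.null(fit)) return(na_row(genes[g]))
    alpha <- 0
    for (it in 1:3) {
      alpha <- pearson_alpha(y, stats::fitted(fit), resid_df)
      fam <- if (alpha < 1e-8) stats::poisson() else
        MASS::negative.binomial(1 / alpha)
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ bg * temp + offset(off),
                                    family = fam, data = dat)),
        error = function(e) NULL)
      if (is.null(fit)) return(na_row(genes[g], alpha))
    }
    if (!fit$converged) return(na_row(genes[g], alpha))
    co <- summary(fit)$coefficients
    tval <- co[int_cols, 1] / co[int_cols, 2]
    data.frame(gene = genes[g], term = int_cols,
               estimate = co[int_cols, 1], se = co[int_cols, 2],
               wald = tval,
               p = 2 * stats::pt(-abs(tval), df = resid_df),
               dispersion = alpha, converged = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- NA_real_
  for (t in unique(out$term)) {
    i <- out$term == t & !is.na(out$p)
    out$padj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  class(out) <- c("expression_fit", "data.frame")
  out
}
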