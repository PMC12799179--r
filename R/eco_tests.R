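# Clinality and seasonality tests for focal SNPs across wild pooled
# samples: lagged environmental summarisation, binomial GLMs weighted by
# effective coverage, likelihood-ratio tests against year/locality null
# models, permutation nulls, and colocalization with external SNP sets.

#' Summarise a daily environmental series over a lag window
#'
#' Computes a statistic over the `lag_days` daily values ending on (and
#' including) the collection date, i.e. the "0 to `lag_days` days prior"
#' window. Every day in the window must be present in the series.
#'
#' @param env data.frame with columns `date` (Date or ISO-8601 string) and
#'   `value`, one row per day.
#' @param date collection date.
#' @param lag_days window length in days (commonly 15, 30, 45, 60, 75, 90).
#' @param statistic one of `"mean"`, `"sd"` (sample standard deviation),
#'   `"max"`, `"min"`.
#' @return The summary value.
#' @export
lag_summary <- function(env, date, lag_days,
                        statistic = c("mean", "sd", "max", "min")) {
  statistic <- match.arg(statistic)
  lag_days <- assert_count(lag_days, "lag_days", min = 1L)
  date <- as.Date(date)
  env_dates <- as.Date(env$date)
  window <- seq(date - lag_days + 1L, date, by = "day")
  idx <- match(window, env_dates)
  if (anyNA(idx))
    stop("environmental series has ", sum(is.na(idx)),
         " missing day(s) inside the lag window ending ", format(date))
  v <- env$value[idx]
  switch(statistic, mean = mean(v), sd = stats::sd(v), max = max(v), min = min(v))
}

#' Test for clinality of an allele frequency along latitude
#'
#' @param frequencies allele frequencies per sample.
#' @param latitudes latitude per sample.
#' @return List with `r` (Pearson correlation) and `p` (two-sided).
#' @export
clinal_test <- function(frequencies, latitudes) {
  if (length(frequencies) != length(latitudes)) stop("inputs must align")
  if (length(frequencies) < 3L) stop("need at least 3 samples")
  if (stats::sd(frequencies) == 0 || stats::sd(latitudes) == 0)
    stop("zero-variance input; correlation undefined")
  ct <- stats::cor.test(latitudes, frequencies, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# build the binomial response: successes = round(freq * n_e) (round-half-even),
# failures = round(n_e) - successes
binomial_response <- function(freq, n_e) {
  assert_prob(freq, "freq")
  if (any(n_e <= 0)) stop("every sample needs a positive effective coverage")
  succ <- round(freq * n_e)
  fail <- round(n_e) - succ
  fail[fail < 0] <- 0
  cbind(succ = succ, fail = fail)
}

#' Binomial GLM test for seasonality of an allele frequency
#'
#' Fits a binomial GLM whose response is the allele frequency weighted by
#' the pool's effective coverage (successes `round(freq * n_e)` out of
#' `round(n_e)` trials). The null model contains year and locality as
#' factors; the full model adds the standardised environmental summary. The
#' seasonal signal is the 1-df likelihood-ratio test between the two.
#' Single-level factors (one locality, or one year) are dropped
#' automatically.
#'
#' @param samples data.frame with columns `freq`, `n_e`, `year`, `locality`
#'   and the environmental summary named by `env_col`.
#' @param env_col name of the environmental summary column (default
#'   `"env"`).
#' @return A list of class `seasonal_fit`: `beta` (coefficient of the
#'   standardised summary), `se`, `lrt_stat`, `lrt_p`, `n`, `env_col`,
#'   `fit_full`, `fit_null`.
#' @export
seasonal_glm <- function(samples, env_col = "env") {
  need <- c("freq", "n_e", "year", "locality", env_col)
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  env <- samples[[env_col]]
  if (length(unique(env)) < 2L)
    stop("environmental covariate is constant; seasonal term inestimable")
  y <- binomial_response(samples$freq, samples$n_e)
  d <- data.frame(succ = y[, "succ"], fail = y[, "fail"],
                  year = factor(samples$year),
                  locality = factor(samples$locality),
                  env_z = as.numeric(scale(env)))
  terms <- c("year", "locality")
  terms <- terms[vapply(terms, function(t) nlevels(d[[t]]) > 1L, logical(1))]
  rhs_null <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f_null <- stats::as.formula(paste("cbind(succ, fail) ~", rhs_null))
  f_full <- stats::as.formula(paste("cbind(succ, fail) ~", rhs_null, "+ env_z"))
  fit_null <- stats::glm(f_null, family = stats::binomial(), data = d)
  fit_full <- stats::glm(f_full, family = stats::binomial(), data = d)
  if (!fit_full$converged || !fit_null$converged)
    stop("seasonal GLM failed to converge (degenerate or separated fit)")
  co <- summary(fit_full)$coefficients
  if (!"env_z" %in% rownames(co) || is.na(co["env_z", 1]))
    stop("environmental term inestimable in the full model")
  lrt <- as.numeric(2 * (stats::logLik(fit_full) - stats::logLik(fit_null)))
  structure(list(beta = co["env_z", 1], se = co["env_z", 2],
                 lrt_stat = lrt,
                 lrt_p = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
                 n = nrow(d), env_col = env_col,
                 fit_full = fit_full, fit_null = fit_null),
            class = "seasonal_fit")
}

#' Permutation rank of the observed seasonal signal
#'
#' Refits the seasonal GLM after permuting the environmental summary across
#' samples within each locality (preserving the year and locality factor
#' structure) and reports the proportion of permuted likelihood-ratio
#' statistics strictly below the observed one. Ties count as not beaten.
#'
#' @param samples as in [seasonal_glm()].
#' @param env_col environmental summary column name.
#' @param n_perm number of permutations (default 100, reported on a
#'   1/`n_perm` grid).
#' @param seed RNG seed.
#' @return List with `proportion` (fraction of permutations beaten),
#'   `observed` (LRT statistic), `perm_stats`, `n_failed`.
#' @export
permutation_rank <- function(samples, env_col = "env", n_perm = 100L,
                             seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm", min = 1L)
  obs <- seasonal_glm(samples, env_col)$lrt_stat
  set.seed(seed)
  loc <- factor(samples$locality)
  perm_stats <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    perm <- samples
    for (l in levels(loc)) {
      i <- which(loc == l)
      perm[[env_col]][i] <- samples[[env_col]][sample(i)]
    }
    perm_stats[b] <- tryCatch(seasonal_glm(perm, env_col)$lrt_stat,
                              error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(perm_stats))
  if (n_failed)
    warning(n_failed, " permutation fit(s) failed and were excluded")
  ok <- perm_stats[!is.na(perm_stats)]
  if (!length(ok)) stop("all permutation fits failed")
  list(proportion = mean(ok < obs), observed = obs,
       perm_stats = perm_stats, n_failed = n_failed)
}

#' Colocalize scan hits with external clinal and seasonal SNP sets
#'
#' Site-keyed intersection (1-based, arm-qualified coordinates) of the scan
#' results with an external clinal set carrying q-values and an external
#' seasonal set carrying p-values. Thresholds are strict (`<`): boundary
#' values are excluded.
#'
#' @param scan data.frame of scan hits with columns `arm`, `pos`.
#' @param clinal data.frame with columns `arm`, `pos`, `q`.
#' @param seasonal data.frame with columns `arm`, `pos`, `p`.
#' @param clinal_q clinal significance threshold (default 0.05).
#' @param seasonal_p seasonal significance threshold (default 0.004).
#' @return Data.frame keyed by the scan sites with logical columns
#'   `in_clinal`, `in_seasonal`, `triple` (significant in all three).
#' @export
colocalize <- function(scan, clinal, seasonal,
                       clinal_q = 0.05, seasonal_p = 0.004) {
  for (nm in c("scan", "clinal", "seasonal")) {
    s <- get(nm)
    if (!all(c("arm", "pos") %in% names(s)))
      stop(nm, " set needs arm and pos columns")
    if (anyDuplicated(site_key(s$arm, s$pos)))
      stop("duplicate site keys in the ", nm, " set")
  }
  if (!"q" %in% names(clinal)) stop("clinal set needs a q column")
  if (!"p" %in% names(seasonal)) stop("seasonal set needs a p column")
  key <- site_key(scan$arm, scan$pos)
  ckey <- site_key(clinal$arm, clinal$pos)[clinal$q < clinal_q]
  skey <- site_key(seasonal$arm, seasonal$pos)[seasonal$p < seasonal_p]
  out <- data.frame(arm = scan$arm, pos = scan$pos,
                    in_clinal = key %in% ckey,
                    in_seasonal = key %in% skey,
                    stringsAsFactors = FALSE)
  out$triple <- out$in_clinal & out$in_seasonal
  out
}
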