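#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed
#'
#' Replicates and pipeline stages each receive their own RNG stream derived
#' from the master seed by a fixed counter scheme:
#' `(seed + 1000003 * counter) mod 2147483629`. The modulus is the largest
#' prime below 2^31 so sub-seeds always fit in an R integer; the multiplier
#' is a prime large enough that consecutive counters land far apart.
#'
#' @param seed master seed (single integer).
#' @param counter non-negative integer counter (replicate index, stage index).
#' @return A single integer usable with [set.seed()].
#' @export
subseed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  as.integer((as.double(seed) + 1000003 * as.double(counter)) %% 2147483629)
}

assert_prob <- function(x, name = deparse(substitute(x)), open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop(name, " must be numeric without NA", call. = FALSE)
  if (open) {
    if (any(x <= 0 | x >= 1)) stop(name, " must lie strictly in (0, 1)", call. = FALSE)
  } else if (any(x < 0 | x > 1)) stop(name, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

# deterministic key for (arm, pos) site identifiers
site_key <- function(arm, pos) paste(arm, pos, sep = ":")
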