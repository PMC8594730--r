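#' Round half away from zero
#'
#' Integer rounding used for percentage reporting in endpoint tables, where
#' 12.5 is reported as 13 (base R's `round()` rounds half to even and would
#' give 12).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(12.5)   # 13
#' round_half_up(0.125, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# 0-based half-open <-> 1-based inclusive conversions; used only at file
# boundaries (internal coordinates are always 0-based half-open).
to_zero_based <- function(pos_1based) pos_1based - 1L
to_one_based <- function(start_0based) start_0based + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# nearest-rank percentile (no interpolation): smallest value with at least
# q% of the data at or below it
nearest_rank <- function(x, q) {
  stopifnot(q > 0, q <= 100)
  xs <- sort(x)
  n <- length(xs)
  # epsilon guards the ceiling against floating-point noise in q*n/100
  idx <- ceiling(q * n / 100 - 1e-9)
  xs[min(n, max(1L, idx))]
}

#' Empirical permutation p-value
#'
#' Fraction of null statistics at least as extreme (i.e. `>=`) as the
#' observed statistic: `p = k / N` with `k = #\{null >= observed\}`. Note the
#' estimator can be exactly 0; `add_one = TRUE` gives the alternative
#' `(k + 1) / (N + 1)` estimator which cannot.
#'
#' @param null_stats Numeric vector of statistics from permuted datasets.
#' @param observed Observed statistic.
#' @param add_one Use the (k+1)/(N+1) estimator instead of k/N.
#' @return A single p-value in \[0, 1\].
#' @export
#' @examples
#' empirical_pvalue(c(0, 1, 2, 5), 2)  # 2/4
empirical_pvalue <- function(null_stats, observed, add_one = FALSE) {
  stopifnot(length(observed) == 1L, length(null_stats) >= 1L)
  k <- sum(null_stats >= observed)
  n <- length(null_stats)
  if (add_one) (k + 1) / (n + 1) else k / n
}
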