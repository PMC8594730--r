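#' Stringency presets for DMS calling
#'
#' `COV10_Met20` is the stringent setting (10 reads per sample, q <= 0.01,
#' absolute methylation difference >= 20 percentage points); `COV10_Met10`
#' relaxes the difference gate to 10 points. Custom thresholds are allowed
#' via the arguments.
#'
#' @param name Preset name, or anything else for a custom preset.
#' @param min_reads,q_max,min_diff Override the preset's thresholds
#'   (`min_diff` in percentage points).
#' @return A `stringency_preset` list with `name, min_reads, q_max, min_diff`.
#' @export
stringency_preset <- function(name = c("COV10_Met20", "COV10_Met10", "custom"),
                              min_reads = NULL, q_max = NULL, min_diff = NULL) {
  name <- if (is.character(name) && length(name) == 1 &&
              !name %in% c("COV10_Met20", "COV10_Met10")) "custom"
          else match.arg(name)
  base <- switch(name,
                 COV10_Met20 = list(min_reads = 10, q_max = 0.01, min_diff = 20),
                 COV10_Met10 = list(min_reads = 10, q_max = 0.01, min_diff = 10),
                 custom = list(min_reads = 10, q_max = 0.01, min_diff = 20))
  out <- list(name = name,
              min_reads = min_reads %||% base$min_reads,
              q_max = q_max %||% base$q_max,
              min_diff = min_diff %||% base$min_diff)
  stopifnot(out$q_max >= 0, out$q_max <= 1, out$min_diff >= 0)
  structure(out, class = "stringency_preset")
}

#' Benjamini–Hochberg q-values
#'
#' Step-up false discovery rate adjustment over the non-`NA` entries
#' (q = min over the tail of m * p / rank, capped at 1); `NA` p-values stay
#' `NA` and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return q-values, same length and order as `p`.
#' @export
adjust_q <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# direction labels from the calling thresholds; at min_diff = 0 a strict sign
# requirement keeps hyper/hypo disjoint when meth_diff == 0
dms_direction <- function(meth_diff, q_value, preset) {
  sig <- !is.na(q_value) & q_value <= preset$q_max
  out <- rep("ns", length(meth_diff))
  out[sig & meth_diff >= preset$min_diff & meth_diff > 0] <- "hyper"
  out[sig & meth_diff <= -preset$min_diff & meth_diff < 0] <- "hypo"
  factor(out, levels = c("hyper", "hypo", "ns"))
}

#' Test one tile for differential methylation
#'
#' Two tests are available on the per-sample (methylated, unmethylated)
#' counts of a single tile:
#' * `"logistic_lrt"` — likelihood-ratio test of a binomial logistic
#'   regression of methylated vs unmethylated counts on group membership
#'   (with a group-only covariate this equals the G-test on the group-pooled
#'   2x2 table);
#' * `"fisher_pooled"` — two-sided Fisher exact test on the group-pooled
#'   2x2 table.
#'
#' The methylation difference is `100 * (sum(M_case)/sum(Cov_case) -
#' sum(M_control)/sum(Cov_control))` (coverage-weighted pooled proportions);
#' `diff_method = "mean"` uses the difference of mean per-sample percentages
#' instead.
#'
#' @param case_m,case_u Methylated / unmethylated counts per case sample.
#' @param control_m,control_u Same for control samples.
#' @param method `"logistic_lrt"` (default) or `"fisher_pooled"`.
#' @param diff_method `"pooled"` (default) or `"mean"`.
#' @return A list with `meth_diff` (percent) and `p_value` (`NA` when a group
#'   has zero total coverage).
#' @export
test_tile <- function(case_m, case_u, control_m, control_u,
                      method = c("logistic_lrt", "fisher_pooled"),
                      diff_method = c("pooled", "mean")) {
  method <- match.arg(method)
  diff_method <- match.arg(diff_method)
  m1 <- sum(case_m); c1 <- sum(case_m + case_u)
  m2 <- sum(control_m); c2 <- sum(control_m + control_u)
  p <- if (method == "logistic_lrt") lrt_pooled_p(m1, c1, m2, c2)
       else fisher_pooled_p(m1, c1, m2, c2)
  diff <- if (diff_method == "pooled") {
    100 * (m1 / c1 - m2 / c2)
  } else {
    100 * (mean(case_m / (case_m + case_u)) -
           mean(control_m / (control_m + control_u)))
  }
  list(meth_diff = diff, p_value = p)
}

#' Per-tile differential methylation between exposed and control samples
#'
#' Runs [test_tile()]'s test across all tiles of a (typically united and
#' tiled) long count tibble for the samples of one generation, then adds BH
#' q-values. Tiles where the test is undefined (zero coverage in a group)
#' are reported with `p_value = NA` and excluded from the adjustment.
#'
#' @param counts Long count tibble (site- or tile-unit) for one generation.
#' @param design Data frame with `sample_id` and `group`
#'   (`control`/`exposed`) covering the samples in `counts`.
#' @param method,diff_method See [test_tile()].
#' @return A tibble with one row per tile: `chrom, start, end, n_cpg` (if
#'   present), `meth_case, meth_control, meth_diff, p_value, q_value`.
#' @export
diff_methylation <- function(counts, design,
                             method = c("logistic_lrt", "fisher_pooled"),
                             diff_method = c("pooled", "mean")) {
  method <- match.arg(method)
  diff_method <- match.arg(diff_method)
  design <- dplyr::mutate(design, sample_id = as.character(.data$sample_id),
                          group = as.character(.data$group))
  x <- dplyr::inner_join(counts,
                         dplyr::select(design, "sample_id", "group"),
                         by = "sample_id")
  if (nrow(x) < nrow(counts)) {
    stopf("diff_methylation: %d count rows have samples absent from the design",
          nrow(counts) - nrow(x))
  }
  grp <- dplyr::summarise(
    dplyr::group_by(x, .data$chrom, .data$start, .data$end, .data$group),
    m = sum(.data$methylated), cov = sum(.data$coverage),
    frac = mean(.data$methylated / .data$coverage),
    n_cpg = if ("n_cpg" %in% names(x)) .data$n_cpg[1] else NA_integer_,
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(grp,
                             names_from = "group",
                             values_from = c("m", "cov", "frac"),
                             values_fill = list(m = 0, cov = 0))
  for (col in c("m_exposed", "cov_exposed", "m_control", "cov_control")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  p <- if (method == "logistic_lrt") {
    lrt_pooled_p(wide$m_exposed, wide$cov_exposed,
                 wide$m_control, wide$cov_control)
  } else {
    fisher_pooled_p(wide$m_exposed, wide$cov_exposed,
                    wide$m_control, wide$cov_control)
  }
  if (diff_method == "pooled") {
    mc <- 100 * wide$m_exposed / wide$cov_exposed
    mk <- 100 * wide$m_control / wide$cov_control
  } else {
    mc <- 100 * wide$frac_exposed
    mk <- 100 * wide$frac_control
  }
  out <- tibble::tibble(
    chrom = wide$chrom, start = wide$start, end = wide$end,
    n_cpg = wide$n_cpg,
    meth_case = mc, meth_control = mk, meth_diff = mc - mk, p_value = p
  )
  out$q_value <- adjust_q(out$p_value)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Call differentially methylated sites
#'
#' Applies a stringency preset to per-tile statistics: a tile is `hyper` if
#' `q_value <= q_max` and `meth_diff >= +min_diff`, `hypo` if
#' `q_value <= q_max` and `meth_diff <= -min_diff`, otherwise `ns`.
#'
#' @param records Tibble from [diff_methylation()] (needs `meth_diff` and
#'   `q_value`).
#' @param preset A [stringency_preset()].
#' @return `records` with a `direction` factor column added.
#' @export
call_dms <- function(records, preset = stringency_preset("COV10_Met20")) {
  records$direction <- dms_direction(records$meth_diff, records$q_value, preset)
  records
}

#' Tabulate DMS calls
#'
#' @param dms A called DMS tibble (from [call_dms()]).
#' @return Tibble with counts of hyper, hypo and ns tiles.
#' @export
dms_summary <- function(dms) {
  dplyr::count(dms, .data$direction, .drop = FALSE, name = "n")
}
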