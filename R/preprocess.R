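#' Coverage filtering and tiling configuration
#'
#' The standard RRBS processing settings: sites with read depth above a
#' sample's 99.9th coverage percentile are discarded (PCR-duplicate guard),
#' sites must then reach 10 reads in every sample of a generation, and
#' surviving CpGs are aggregated into non-overlapping 100-bp tiles holding at
#' least 1 CpG.
#'
#' @param min_reads_per_sample Minimum coverage required in every sample.
#' @param max_coverage_percentile Sites with coverage strictly above this
#'   nearest-rank percentile are removed; 100 disables the cap.
#' @param percentile_scope `"per_sample"` (default; each sample's own
#'   percentile, as methylKit does) or `"global"` (one percentile over all
#'   samples' coverages).
#' @param tile_window,tile_step Tile width and step in bp; equal by default
#'   (non-overlapping tiles anchored at position 0 of each chromosome).
#' @param min_cpg_per_tile Tiles with fewer member CpGs are dropped.
#' @param recheck_tile_coverage Re-apply the `min_reads_per_sample` floor to
#'   tile-level (summed) coverage after aggregation.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_reads_per_sample = 10,
                          max_coverage_percentile = 99.9,
                          percentile_scope = c("per_sample", "global"),
                          tile_window = 100,
                          tile_step = tile_window,
                          min_cpg_per_tile = 1,
                          recheck_tile_coverage = TRUE) {
  percentile_scope <- match.arg(percentile_scope)
  stopifnot(max_coverage_percentile > 0, max_coverage_percentile <= 100,
            tile_step <= tile_window, tile_window >= 1,
            min_reads_per_sample >= 0, min_cpg_per_tile >= 1)
  structure(list(min_reads_per_sample = min_reads_per_sample,
                 max_coverage_percentile = max_coverage_percentile,
                 percentile_scope = percentile_scope,
                 tile_window = as.integer(tile_window),
                 tile_step = as.integer(tile_step),
                 min_cpg_per_tile = as.integer(min_cpg_per_tile),
                 recheck_tile_coverage = recheck_tile_coverage),
            class = "filter_config")
}

#' Discard sites above the high-coverage percentile
#'
#' Removes, per sample, sites whose coverage is strictly above the
#' nearest-rank `max_coverage_percentile` of that sample's coverage vector
#' (or of the pooled vector with `percentile_scope = "global"`). This is the
#' first filtering step, applied before any per-generation uniting.
#'
#' @param counts Long count tibble (any number of samples).
#' @param cfg A [filter_config()].
#' @return The filtered tibble; the per-sample removal report is attached as
#'   attribute `"filter_report"` (also retrievable with
#'   [coverage_filter_report()]).
#' @export
filter_coverage <- function(counts, cfg = filter_config()) {
  samples <- unique(counts$sample_id)
  if (length(samples) == 0 || nrow(counts) == 0) {
    stopf("filter_coverage: no records")
  }
  empty <- setdiff(samples, unique(counts$sample_id[counts$coverage >= 0]))
  if (length(empty)) stopf("empty sample: %s", paste(empty, collapse = ", "))
  if (cfg$max_coverage_percentile >= 100) {
    thr <- stats::setNames(rep(Inf, length(samples)), samples)
  } else if (cfg$percentile_scope == "global") {
    t0 <- nearest_rank(counts$coverage, cfg$max_coverage_percentile)
    thr <- stats::setNames(rep(t0, length(samples)), samples)
  } else {
    thr <- purrr::map_dbl(
      split(counts$coverage, counts$sample_id)[samples],
      nearest_rank, q = cfg$max_coverage_percentile
    )
  }
  keep <- counts$coverage <= thr[counts$sample_id]
  out <- counts[keep, ]
  report <- tibble::tibble(
    sample_id = samples,
    threshold = unname(thr[samples]),
    n_in = as.integer(table(factor(counts$sample_id, samples))),
    n_removed = as.integer(table(factor(counts$sample_id[!keep], samples)))
  )
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the removal report attached by [filter_coverage()]
#' @param counts A tibble returned by [filter_coverage()].
#' @return Tibble with per-sample coverage threshold and removal counts.
#' @export
coverage_filter_report <- function(counts) attr(counts, "filter_report")

#' Unite samples on jointly covered sites
#'
#' Keeps only sites with coverage of at least `min_reads_per_sample` in
#' EVERY sample present in `counts` — the "10 reads per sample" criterion is
#' per sample, not on the mean. Call this per generation (all samples of one
#' generation together).
#'
#' @param counts Long count tibble, typically one generation's samples.
#' @param cfg A [filter_config()].
#' @return Long tibble restricted to the united site set, sorted by
#'   coordinate within sample.
#' @export
unite_samples <- function(counts, cfg = filter_config()) {
  samples <- unique(counts$sample_id)
  n <- length(samples)
  key <- site_key(counts$chrom, counts$start, counts$end)
  ok_cov <- counts$coverage >= cfg$min_reads_per_sample
  per_site <- rowsum(cbind(present = rep(1L, nrow(counts)),
                           pass = as.integer(ok_cov)), key)
  keep_keys <- rownames(per_site)[per_site[, "present"] == n &
                                  per_site[, "pass"] == n]
  out <- counts[key %in% keep_keys, ]
  if (nrow(out) == 0) {
    stopf("unite_samples: no site passes coverage >= %g in all %d samples",
          cfg$min_reads_per_sample, n)
  }
  dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start)
}

# tile index of a position for non-overlapping windows anchored at 0
tile_of <- function(start, window) as.integer(start %/% window)

#' Aggregate united CpG counts into fixed tiles
#'
#' Sums methylated and unmethylated counts over the CpGs falling in each
#' window of `tile_window` bp anchored at position 0 of each chromosome
#' (with `tile_step < tile_window`, windows overlap and a CpG contributes to
#' every window containing it). Tiles with fewer than `min_cpg_per_tile`
#' member CpGs are dropped; with `recheck_tile_coverage` the
#' `min_reads_per_sample` floor is re-applied to tile totals.
#'
#' @param counts United long count tibble (see [unite_samples()]).
#' @param cfg A [filter_config()].
#' @return Long tile tibble with `sample_id, chrom, start, end, n_cpg,
#'   methylated, unmethylated, coverage`; coordinates are the 0-based
#'   half-open window bounds.
#' @export
tile_counts <- function(counts, cfg = filter_config()) {
  w <- cfg$tile_window; s <- cfg$tile_step
  if (s == w) {
    expanded <- dplyr::mutate(counts, tile_start = tile_of(.data$start, w) * w)
  } else {
    # a CpG at p lies in window k*s .. k*s+w for k in [ceil((p-w+1)/s), floor(p/s)]
    expanded <- dplyr::mutate(
      counts,
      k_lo = pmax(0L, as.integer(ceiling((.data$start - w + 1) / s))),
      k_hi = as.integer(.data$start %/% s)
    )
    expanded <- tidyr::unnest(
      dplyr::mutate(expanded,
                    tile_start = purrr::map2(.data$k_lo, .data$k_hi,
                                             function(a, b) seq(a, b) * s)),
      "tile_start"
    )
  }
  tiles <- dplyr::summarise(
    dplyr::group_by(expanded, .data$sample_id, .data$chrom, .data$tile_start),
    n_cpg = dplyr::n(),
    methylated = sum(.data$methylated),
    unmethylated = sum(.data$unmethylated),
    .groups = "drop"
  )
  tiles <- dplyr::mutate(tiles,
                         start = as.integer(.data$tile_start),
                         end = as.integer(.data$tile_start + w),
                         coverage = .data$methylated + .data$unmethylated)
  tiles <- dplyr::select(tiles, "sample_id", "chrom", "start", "end",
                         "n_cpg", "methylated", "unmethylated", "coverage")
  # a united input guarantees each tile appears in all samples with the same
  # CpG membership; apply the tile-level gates jointly across samples
  key <- site_key(tiles$chrom, tiles$start, tiles$end)
  drop <- tiles$n_cpg < cfg$min_cpg_per_tile
  if (cfg$recheck_tile_coverage) {
    drop <- drop | tiles$coverage < cfg$min_reads_per_sample
  }
  bad_keys <- unique(key[drop])
  out <- tiles[!key %in% bad_keys, ]
  if (nrow(out) == 0) warnf("tile_counts: no tile survived the filters")
  dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start)
}
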