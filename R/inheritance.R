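#' Direction-consistent conserved DMS across a generation chain
#'
#' A tile is conserved along a chain (e.g. F1–F2, or F1–F2–F3) if it is
#' called with the SAME direction in every generation of the chain.
#' Coordinates must match exactly — all generations must have been tiled with
#' the same filter configuration (mixed units raise an error). The number of
#' jointly-testable coordinates (tiles tested, at any call, in every
#' generation of the chain) is reported alongside so sparsity is visible.
#'
#' @param dms_by_generation Named list of called DMS tibbles (from
#'   [call_dms()]), one per generation.
#' @param chain Character vector of generation names, in order.
#' @param direction `"hyper"` or `"hypo"`.
#' @return A tibble of conserved records (coordinates plus per-generation
#'   `meth_diff_<gen>` columns) with attributes `count`, `chain`,
#'   `direction` and `n_jointly_testable`.
#' @export
conserved_sites <- function(dms_by_generation, chain,
                            direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  missing <- setdiff(chain, names(dms_by_generation))
  if (length(missing)) stopf("chain generation(s) absent: %s",
                             paste(missing, collapse = ", "))
  dms <- dms_by_generation[chain]
  widths <- unlist(lapply(dms, function(d) unique(d$end - d$start)))
  if (length(unique(widths)) > 1) {
    stopf("mixed units across generations (tile widths: %s)",
          paste(sort(unique(widths)), collapse = ", "))
  }
  keys <- lapply(dms, function(d) site_key(d$chrom, d$start, d$end))
  testable <- Reduce(intersect, keys)
  sets <- purrr::map2(dms, keys, function(d, k) k[d$direction == direction])
  conserved <- Reduce(intersect, sets)

  first <- dms[[1]]
  out <- first[keys[[1]] %in% conserved,
               c("chrom", "start", "end")]
  for (g in chain) {
    d <- dms[[g]]
    out[[paste0("meth_diff_", g)]] <-
      d$meth_diff[match(site_key(out$chrom, out$start, out$end), keys[[g]])]
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  attr(out, "count") <- nrow(out)
  attr(out, "chain") <- chain
  attr(out, "direction") <- direction
  attr(out, "n_jointly_testable") <- length(testable)
  out
}

#' Venn region counts of DMS sets across generations
#'
#' Partitions the union of each direction's DMS coordinates by the exact
#' membership pattern across generations (the regions of a Venn diagram).
#' Region counts sum to the union size and are consistent with
#' [conserved_sites()] by construction.
#'
#' @param dms_by_generation Named list of called DMS tibbles.
#' @param generations Generations to include (default: all in the list).
#' @return Tibble with `direction`, one logical column per generation, and
#'   `n` — the number of coordinates with exactly that membership pattern.
#' @export
venn_counts <- function(dms_by_generation,
                        generations = names(dms_by_generation)) {
  out <- purrr::map_dfr(c("hyper", "hypo"), function(dirn) {
    sets <- lapply(dms_by_generation[generations], function(d) {
      site_key(d$chrom, d$start, d$end)[d$direction == dirn]
    })
    universe <- unique(unlist(sets))
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
    if (length(universe) == 0) {
      membership <- matrix(logical(0), ncol = length(generations))
    }
    colnames(membership) <- generations
    patt <- tidyr::expand_grid(!!!stats::setNames(
      rep(list(c(TRUE, FALSE)), length(generations)), generations))
    patt <- patt[rowSums(as.matrix(patt)) > 0, ]
    patt$n <- apply(patt, 1, function(p) {
      sum(apply(membership, 1, function(m) all(m == p)))
    })
    patt$direction <- dirn
    patt
  })
  dplyr::select(out, "direction", dplyr::all_of(generations), "n")
}
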