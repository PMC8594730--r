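#' Permutation plan for the inheritance test
#'
#' @param n_permutations Number of label permutations (the study default is
#'   3962).
#' @param mode `"across_generations"` (default): all samples are pooled and
#'   re-dealt into the original (generation, group) cell sizes;
#'   `"within_generation"`: group labels are shuffled among each generation's
#'   samples independently. Both preserve cell sizes.
#' @param seed Integer seed for the permutation stream.
#' @param statistic_chains List of generation chains whose conserved-DMS
#'   counts are the test statistics.
#' @param exhaustive If `TRUE` (only with `mode = "within_generation"`),
#'   enumerate every distinct assignment exactly once instead of sampling;
#'   `n_permutations` is ignored. Errors if the group has more than
#'   `max_exhaustive` elements.
#' @param max_exhaustive Safety cap for exhaustive enumeration.
#' @param add_one Use the (k+1)/(N+1) p-value estimator (default `FALSE`,
#'   i.e. p = k/N, which can be exactly 0).
#' @return A `permutation_plan` list.
#' @export
permutation_plan <- function(n_permutations = 3962,
                             mode = c("across_generations", "within_generation"),
                             seed = 1L,
                             statistic_chains = list(c("F1", "F2"),
                                                     c("F1", "F2", "F3")),
                             exhaustive = FALSE,
                             max_exhaustive = 10000,
                             add_one = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 1)
  if (exhaustive && mode != "within_generation") {
    stopf("exhaustive enumeration is implemented for within_generation mode")
  }
  structure(list(n_permutations = as.integer(n_permutations), mode = mode,
                 seed = as.integer(seed), statistic_chains = statistic_chains,
                 exhaustive = exhaustive, max_exhaustive = max_exhaustive,
                 add_one = add_one),
            class = "permutation_plan")
}

#' Permute a generation/group design
#'
#' Returns a new design with the same samples and the same cell sizes but
#' permuted assignments. `"within_generation"` shuffles group labels among
#' each generation's samples independently; `"across_generations"` pools all
#' samples and re-deals them into the original (generation, group) cells.
#'
#' @param design Tibble with `sample_id, generation, group`.
#' @param mode See [permutation_plan()].
#' @return A permuted design tibble (same columns).
#' @export
permute_design <- function(design,
                           mode = c("across_generations", "within_generation")) {
  mode <- match.arg(mode)
  cells <- table(design$generation, design$group)
  if (any(cells < 2)) stopf("degenerate design: a cell has < 2 samples")
  out <- design
  if (mode == "within_generation") {
    for (g in unique(design$generation)) {
      i <- which(design$generation == g)
      out$group[i] <- design$group[sample(i)]
    }
  } else {
    perm <- sample(nrow(design))
    out$generation <- design$generation[perm]
    out$group <- design$group[perm]
    # equivalently: samples re-dealt into the original cell-size layout
  }
  out
}

# all distinct within-generation assignments (product of per-generation
# choose(n_cell, n_exposed) label placements)
enumerate_designs <- function(design, max_n = 10000) {
  gens <- unique(as.character(design$generation))
  per_gen <- lapply(gens, function(g) {
    i <- which(design$generation == g)
    k <- sum(design$group[i] == "exposed")
    utils::combn(i, k, simplify = FALSE)
  })
  total <- prod(lengths(per_gen))
  if (total > max_n) stopf("exhaustive enumeration too large (%g designs)", total)
  grid <- expand.grid(lapply(per_gen, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    out <- design
    out$group <- factor("control", levels = levels(factor(design$group,
                        levels = c("control", "exposed"))))
    for (j in seq_along(gens)) {
      out$group[per_gen[[j]][[grid[r, j]]]] <- "exposed"
    }
    out
  })
}

#' Permutation test for inherited methylation change
#'
#' The significance engine for transgenerational conservation: for each of
#' `n_permutations` permuted case/control assignments, the ENTIRE detection
#' procedure — per-generation uniting on jointly covered sites, 100-bp
#' tiling, the differential methylation test, BH adjustment, DMS calling and
#' direction-consistent conservation along each chain — is re-executed, and
#' the empirical p-value per (chain, direction) is the fraction of
#' permutations whose conserved count is at least as large as the observed
#' one (p = k/N; the observed assignment is not counted among the N). A
#' permutation on which detection collapses (no testable tile) contributes a
#' conserved count of 0.
#'
#' @param counts Long count tibble over ALL samples (all generations).
#' @param sheet Sample sheet tibble (`sample_id, generation, group`).
#' @param filter_cfg A [filter_config()].
#' @param preset A [stringency_preset()].
#' @param plan A [permutation_plan()].
#' @param method,diff_method Passed to the per-tile test (see [test_tile()]).
#' @return A `perm_inherit` object: list with `observed` (named counts),
#'   `null_counts` (matrix, one row per permutation), `p_value` (named),
#'   `plan`, and a running-estimate `trace`. Supports [tidy()], [glance()]
#'   and [ggplot2::autoplot()].
#' @export
run_permutation_test <- function(counts, sheet,
                                 filter_cfg = filter_config(),
                                 preset = stringency_preset("COV10_Met20"),
                                 plan = permutation_plan(),
                                 method = "logistic_lrt",
                                 diff_method = "pooled") {
  design <- dplyr::select(sheet, "sample_id", "generation", "group")
  engine <- build_meth_engine(counts, sheet, filter_cfg)
  chains <- plan$statistic_chains

  observed <- engine_conserved_counts(
    engine_detect(engine, design, preset, method, diff_method), chains)

  null_counts <- withr::with_seed(plan$seed, {
    designs <- if (plan$exhaustive) {
      enumerate_designs(design, plan$max_exhaustive)
    } else {
      lapply(seq_len(plan$n_permutations), function(i) {
        permute_design(design, plan$mode)
      })
    }
    t(vapply(designs, function(d) {
      engine_conserved_counts(
        engine_detect(engine, d, preset, method, diff_method), chains)
    }, observed))
  })

  n <- nrow(null_counts)
  extreme <- sweep(null_counts, 2, observed, `>=`)
  k <- colSums(extreme)
  p <- if (plan$add_one) (k + 1) / (n + 1) else k / n
  trace <- apply(extreme, 2, function(e) {
    if (plan$add_one) (cumsum(e) + 1) / (seq_len(n) + 1)
    else cumsum(e) / seq_len(n)
  })

  structure(list(observed = observed, null_counts = null_counts,
                 p_value = p, trace = trace, plan = plan,
                 n_permutations = n, preset = preset),
            class = "perm_inherit")
}

#' @export
print.perm_inherit <- function(x, ...) {
  cat(sprintf("<perm_inherit> %d permutations (%s)\n",
              x$n_permutations, x$plan$mode))
  print(tidy.perm_inherit(x))
  invisible(x)
}

#' Convergence diagnostics for a permutation test
#'
#' Reports the running empirical p estimate at checkpoints and the maximum
#' absolute change of each estimate over the last 20% of permutations; an
#' estimate still moving by more than `tol` is flagged as not converged.
#' Fewer than 100 permutations is reported as not evaluable.
#'
#' @param result A `perm_inherit` object.
#' @param tol Maximum tolerated change of the running estimate over the last
#'   20% of permutations.
#' @param n_checkpoints Number of checkpoints reported.
#' @return A list with `status` (`"converged"`, `"not_converged"` or
#'   `"not_evaluable"`), `max_change` per statistic, and a checkpoint tibble.
#' @export
convergence <- function(result, tol = 0.005, n_checkpoints = 20) {
  stopifnot(inherits(result, "perm_inherit"))
  n <- result$n_permutations
  if (n < 100) {
    return(list(status = "not_evaluable", max_change = NULL,
                checkpoints = NULL, tol = tol))
  }
  idx <- unique(round(seq(1, n, length.out = n_checkpoints)))
  cp <- tibble::as_tibble(result$trace[idx, , drop = FALSE])
  cp$permutation <- idx
  tail_idx <- seq(ceiling(0.8 * n), n)
  max_change <- apply(result$trace[tail_idx, , drop = FALSE], 2,
                      function(v) max(abs(v - v[length(v)])))
  status <- if (all(max_change <= tol)) "converged" else "not_converged"
  list(status = status, max_change = max_change,
       checkpoints = tidyr::pivot_longer(cp, -"permutation",
                                         names_to = "statistic",
                                         values_to = "running_p"),
       tol = tol)
}

#' Evaluate DMS calls against a simulated truth table
#'
#' Maps each injected site to the tile containing it and checks whether that
#' tile was called with the truth direction. Sensitivity is the fraction of
#' injected sites (active in the requested generation) whose tile is called
#' in the truth direction; direction accuracy is computed among injected
#' sites whose tile received any call.
#'
#' @param dms Called DMS tibble for one generation (tile unit).
#' @param truth Truth tibble from [simulate_dataset()].
#' @param generation Generation to evaluate (uses the `active_<gen>` column).
#' @param tile_window Tile width used in detection.
#' @return A list with `n_active`, `n_detected`, `sensitivity`,
#'   `direction_accuracy` and the per-site evaluation tibble.
#' @export
evaluate_calls <- function(dms, truth, generation = "F1", tile_window = 100) {
  act_col <- paste0("active_", generation)
  stopifnot(act_col %in% names(truth))
  tr <- truth[truth[[act_col]], ]
  if (nrow(tr) == 0) {
    return(list(n_active = 0L, n_detected = 0L, sensitivity = NA_real_,
                direction_accuracy = NA_real_, detail = tibble::tibble()))
  }
  tr$tile_start <- (tr$start %/% tile_window) * tile_window
  key_t <- site_key(tr$chrom, tr$tile_start, tr$tile_start + tile_window)
  key_d <- site_key(dms$chrom, dms$start, dms$end)
  called <- as.character(dms$direction)[match(key_t, key_d)]
  detail <- tibble::tibble(chrom = tr$chrom, start = tr$start,
                           truth_direction = tr$direction,
                           called_direction = called)
  any_call <- !is.na(called) & called != "ns"
  hit <- any_call & called == tr$direction
  list(n_active = nrow(tr),
       n_detected = sum(hit),
       sensitivity = mean(hit),
       direction_accuracy = if (any(any_call)) {
         mean(called[any_call] == tr$direction[any_call])
       } else NA_real_,
       detail = detail)
}
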