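#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation-test result
#'
#' One row per (chain, direction) statistic with the observed conserved
#' count, the null-distribution mean, and the empirical p-value.
#'
#' @param x A `perm_inherit` object from [run_permutation_test()].
#' @param ... Unused.
#' @return A tibble with `chain, direction, observed, null_mean, p_value`.
#' @exportS3Method generics::tidy
tidy.perm_inherit <- function(x, ...) {
  nm <- names(x$observed)
  parts <- strsplit(nm, "|", fixed = TRUE)
  tibble::tibble(
    chain = purrr::map_chr(parts, 1),
    direction = purrr::map_chr(parts, 2),
    observed = unname(x$observed),
    null_mean = unname(colMeans(x$null_counts)),
    p_value = unname(x$p_value)
  )
}

#' Glance at a permutation-test result
#'
#' @inheritParams tidy.perm_inherit
#' @return One-row tibble with `n_permutations, mode, min_p, converged`.
#' @exportS3Method generics::glance
glance.perm_inherit <- function(x, ...) {
  conv <- convergence(x)
  tibble::tibble(
    n_permutations = x$n_permutations,
    mode = x$plan$mode,
    min_p = min(x$p_value),
    converged = conv$status
  )
}
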