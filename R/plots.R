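#' Plot the permutation null distributions
#'
#' Histogram of the null conserved-DMS counts per (chain, direction) with the
#' observed count marked; the empirical p-value is the mass at or right of
#' the line.
#'
#' @param object A `perm_inherit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_inherit <- function(object, ...) {
  nulls <- tibble::as_tibble(object$null_counts)
  nulls <- tidyr::pivot_longer(nulls, dplyr::everything(),
                               names_to = "statistic", values_to = "count")
  obs <- tibble::tibble(statistic = names(object$observed),
                        observed = unname(object$observed),
                        p_value = unname(object$p_value))
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_text(
      data = obs, colour = "firebrick", hjust = -0.1, vjust = 1.5,
      ggplot2::aes(x = .data$observed, y = Inf,
                   label = sprintf("p = %.3g", .data$p_value))
    ) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "conserved DMS count under permutation", y = "permutations")
}

#' Bar chart of the genomic category distribution of DMS
#'
#' @param annotated Output of [annotate_sites()] on called DMS.
#' @return A ggplot object (fractions per category, split by direction when
#'   available).
#' @export
plot_category_distribution <- function(annotated) {
  dist <- category_distribution(annotated)
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$category,
                                          y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of DMS") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("direction" %in% names(dist)) p <- p + ggplot2::facet_wrap(~direction)
  p
}

#' Volcano plot of per-tile differential methylation
#'
#' @param dms Called DMS tibble (from [call_dms()]).
#' @param preset The [stringency_preset()] used (drawn as guide lines).
#' @return A ggplot object.
#' @export
plot_volcano <- function(dms, preset = stringency_preset("COV10_Met20")) {
  ggplot2::ggplot(dms, ggplot2::aes(x = .data$meth_diff,
                                    y = -log10(pmax(.data$q_value, 1e-16)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(preset$q_max), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * preset$min_diff, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(hyper = "firebrick",
                                            hypo = "navy", ns = "grey70")) +
    ggplot2::labs(x = "methylation difference (exposed - control, %)",
                  y = "-log10 q")
}
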