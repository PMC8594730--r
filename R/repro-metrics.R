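#' Reproductive endpoint formulas
#'
#' Closed-form endpoints of a rodent multigeneration reproductive study, as
#' pure functions:
#'
#' * `conception_rate(pregnant, total)` — 100 * pregnant / total females.
#' * `fertility_rate(viable, corpora_lutea)` — 100 * viable fetuses at
#'   GD 19.5 / corpora lutea.
#' * `preimplantation_loss(corpora_lutea, implantations)` —
#'   100 * (CL - IS) / CL.
#' * `neonatal_mortality(live_births, implantation_sites)` —
#'   100 - 100 * live / implantations (birth to PND 2).
#' * `postnatal_mortality(dead, total)` — 100 * dead / total pups
#'   (PND 2 to PND 21).
#' * `dfi(red, green)` — DNA fragmentation index, red / (red + green)
#'   fluorescence from the sperm chromatin structure assay.
#' * `daily_spermatid_production(mean_count)` —
#'   ((count / 0.00004 µL secondary-square volume) * 100.5 mL suspension)
#'   / 6.10 days of the spermatogenic cycle.
#' * `relative_weight(organ, reference)` — e.g. placenta / fetus weight.
#'
#' All rates are percentages in \[0, 100\]; `dfi` is a fraction in \[0, 1\];
#' spermatid production is linear in the hemacytometer count. All functions
#' are vectorised.
#'
#' @param pregnant,total,viable,corpora_lutea,implantations,live_births,implantation_sites,dead
#'   Non-negative counts.
#' @param red,green Fluorescence intensities (arbitrary units).
#' @param mean_count Mean hemacytometer spermatid-head count.
#' @param organ,reference Weights in grams.
#' @return Numeric vector of the endpoint values.
#' @name repro_metrics
NULL

check_pos <- function(x, what) {
  if (any(x <= 0)) stopf("%s must be > 0", what)
  invisible(x)
}

#' @rdname repro_metrics
#' @export
conception_rate <- function(pregnant, total) {
  check_pos(total, "total females")
  stopifnot(all(pregnant >= 0), all(pregnant <= total))
  100 * pregnant / total
}

#' @rdname repro_metrics
#' @export
fertility_rate <- function(viable, corpora_lutea) {
  check_pos(corpora_lutea, "corpora lutea")
  stopifnot(all(viable >= 0))
  100 * viable / corpora_lutea
}

#' @rdname repro_metrics
#' @export
preimplantation_loss <- function(corpora_lutea, implantations) {
  check_pos(corpora_lutea, "corpora lutea")
  stopifnot(all(implantations >= 0), all(implantations <= corpora_lutea))
  100 * (corpora_lutea - implantations) / corpora_lutea
}

#' @rdname repro_metrics
#' @export
neonatal_mortality <- function(live_births, implantation_sites) {
  check_pos(implantation_sites, "implantation sites")
  stopifnot(all(live_births >= 0))
  100 - 100 * live_births / implantation_sites
}

#' @rdname repro_metrics
#' @export
postnatal_mortality <- function(dead, total) {
  check_pos(total, "total pups")
  stopifnot(all(dead >= 0), all(dead <= total))
  100 * dead / total
}

#' @rdname repro_metrics
#' @export
dfi <- function(red, green) {
  stopifnot(all(red >= 0), all(green >= 0))
  check_pos(red + green, "red + green fluorescence")
  red / (red + green)
}

#' @rdname repro_metrics
#' @export
daily_spermatid_production <- function(mean_count) {
  stopifnot(all(mean_count >= 0))
  ((mean_count / 0.00004) * 100.5) / 6.10
}

#' @rdname repro_metrics
#' @export
relative_weight <- function(organ, reference) {
  check_pos(reference, "reference weight")
  stopifnot(all(organ >= 0))
  organ / reference
}

#' Compute all litter endpoints on a table
#'
#' Data-frame-first wrapper over the endpoint formulas: takes one row per
#' litter and appends every endpoint computable from the available columns
#' (`corpora_lutea`, `implantation_sites`, `viable_fetuses`, `live_births`,
#' `dead_pnd2_to_21`, `pups_total`, `placenta_weight`, `fetus_weight`).
#'
#' @param litters Data frame of litter records.
#' @return `litters` as a tibble with the endpoint columns added
#'   (`fertility_rate_pct`, `preimplantation_loss_pct`,
#'   `neonatal_mortality_pct`, `postnatal_mortality_pct`,
#'   `relative_placenta_weight`), each only when its inputs are present.
#' @export
litter_metrics <- function(litters) {
  x <- tibble::as_tibble(litters)
  has <- function(...) all(c(...) %in% names(x))
  if (has("viable_fetuses", "corpora_lutea")) {
    x$fertility_rate_pct <- fertility_rate(x$viable_fetuses, x$corpora_lutea)
  }
  if (has("corpora_lutea", "implantation_sites")) {
    x$preimplantation_loss_pct <-
      preimplantation_loss(x$corpora_lutea, x$implantation_sites)
  }
  if (has("live_births", "implantation_sites")) {
    x$neonatal_mortality_pct <-
      neonatal_mortality(x$live_births, x$implantation_sites)
  }
  if (has("dead_pnd2_to_21", "pups_total")) {
    x$postnatal_mortality_pct <-
      postnatal_mortality(x$dead_pnd2_to_21, x$pups_total)
  }
  if (has("placenta_weight", "fetus_weight")) {
    x$relative_placenta_weight <-
      relative_weight(x$placenta_weight, x$fetus_weight)
  }
  x
}
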