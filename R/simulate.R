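#' Simulation configuration for multi-generation RRBS counts
#'
#' Defines the study design and noise model emulated by [simulate_dataset()]:
#' a three-generation paternal-line design with 6 exposed and 6 control sperm
#' samples per generation, a bimodal sperm-methylome baseline, negative
#' binomial sequencing depth and beta-binomial replicate overdispersion.
#' Differential methylation is injected in the exposed group of F1 at
#' `n_dms` sites; a fraction of those effects persists into F2 and F3
#' (nested by default), which defines the ground-truth inheritance structure.
#'
#' @param n_sites Number of simulated CpG sites.
#' @param chrom Chromosome name used for all sites.
#' @param chrom_length Chromosome length in bp; CpG positions are drawn
#'   uniformly without replacement. Defaults to `50 * n_sites` (one CpG per
#'   50 bp on average, i.e. about 2 CpGs per 100-bp region).
#' @param region_width Coherence scale of the methylome in bp: the baseline
#'   level and any injected effect are shared by all CpGs of a region
#'   (neighbouring CpGs co-vary in real methylomes — the premise of
#'   tiling-window analysis). Matches the default analysis tile width.
#' @param n_per_cell Samples per (generation, group) cell; the study design
#'   is 6.
#' @param generations Ordered generation labels.
#' @param baseline_shape Two `c(shape1, shape2)` pairs for the low- and
#'   high-methylation beta components of the bimodal baseline.
#' @param mix_high Mixing weight of the high-methylation component.
#' @param coverage_mean,coverage_size Negative binomial mean and size
#'   (dispersion) of per-site per-sample read depth.
#' @param phi Beta-binomial overdispersion in \[0, 1): per-sample methylation
#'   levels are drawn from Beta with mean = the site's group mean and
#'   `shape1 + shape2 = (1 - phi) / phi`; `phi = 0` gives plain binomial
#'   counts.
#' @param n_dms Number of injected differentially methylated sites (each one
#'   occupies a distinct region; all CpGs of that region carry the shift).
#' @param effect_delta Absolute methylation-proportion shift applied to the
#'   exposed group at injected sites (per-site direction is hyper or hypo).
#'   A shift of 0 injects nothing: the truth table is returned empty.
#' @param inherit_frac_F2,inherit_frac_F3 Fractions of the F1-injected sites
#'   whose effect persists in F2 and F3; must satisfy
#'   `inherit_frac_F3 <= inherit_frac_F2`.
#' @param nested If `TRUE` (default) the F3-active set is drawn inside the
#'   F2-active set; if `FALSE` the two sets are drawn independently from the
#'   F1 set.
#' @param prop_clip Proportions are clipped to `[prop_clip, 1 - prop_clip]`
#'   after shifting, avoiding degenerate all-0/all-1 sites.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 2000,
                       chrom = "chr1",
                       chrom_length = 50L * n_sites,
                       region_width = 100,
                       n_per_cell = 6,
                       generations = c("F1", "F2", "F3"),
                       baseline_shape = list(low = c(1, 10), high = c(10, 1)),
                       mix_high = 0.5,
                       coverage_mean = 30,
                       coverage_size = 20,
                       phi = 0.05,
                       n_dms = 0,
                       effect_delta = 0.25,
                       inherit_frac_F2 = 0.5,
                       inherit_frac_F3 = 0.25,
                       nested = TRUE,
                       prop_clip = 0.02,
                       seed = 1L) {
  stopifnot(n_sites >= 1, n_dms >= 0, n_per_cell >= 1,
            phi >= 0, phi < 1, abs(effect_delta) <= 1,
            inherit_frac_F2 >= 0, inherit_frac_F2 <= 1,
            inherit_frac_F3 >= 0, inherit_frac_F3 <= inherit_frac_F2,
            chrom_length >= n_sites)
  if (n_dms > n_sites) stopf("n_dms (%d) exceeds n_sites (%d)", n_dms, n_sites)
  stopifnot(region_width >= 1)
  structure(
    list(n_sites = as.integer(n_sites), chrom = chrom,
         chrom_length = as.integer(chrom_length),
         region_width = as.integer(region_width),
         n_per_cell = as.integer(n_per_cell), generations = generations,
         baseline_shape = baseline_shape, mix_high = mix_high,
         coverage_mean = coverage_mean, coverage_size = coverage_size,
         phi = phi, n_dms = as.integer(n_dms), effect_delta = effect_delta,
         inherit_frac_F2 = inherit_frac_F2, inherit_frac_F3 = inherit_frac_F3,
         nested = nested, prop_clip = prop_clip, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a multi-generation RRBS count dataset with known truth
#'
#' Draws a bimodal baseline methylome, injects exposure effects at `n_dms`
#' sites in F1 with nested persistence into F2/F3, and generates negative
#' binomial coverage with beta-binomial methylated counts for every sample of
#' a 6-vs-6 three-generation design. The returned truth table records, for
#' every injected site, its direction and the generations in which the effect
#' is active — the ground truth that detection, conservation and permutation
#' results are evaluated against.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements
#'   * `counts`: long count tibble over all samples (see [read_count_file()]),
#'   * `sheet`: the sample sheet tibble,
#'   * `truth`: tibble of injected sites with `chrom, start, end, direction`
#'     and one logical `active_<generation>` column per generation,
#'   * `config`: the configuration used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

#' Simulate a null dataset (no injected effects)
#'
#' [simulate_dataset()] with `n_dms` forced to 0: both groups share the same
#' site means in every generation, so any DMS called downstream is a false
#' positive and permutation p-values should be null-calibrated.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()]; `truth` has zero rows.
#' @export
simulate_null <- function(config = sim_config()) {
  config$n_dms <- 0L
  simulate_dataset(config)
}

simulate_dataset_impl <- function(cfg) {
  gens <- cfg$generations
  n_gen <- length(gens)

  pos <- sort(sample.int(cfg$chrom_length, cfg$n_sites)) - 1L  # 0-based
  ns <- cfg$n_sites

  # the methylome is coherent at the region scale: baseline level (and any
  # injected shift) is shared by all CpGs of a region_width window
  region <- pos %/% cfg$region_width
  rid <- match(region, unique(region))
  n_reg <- max(rid)

  # bimodal baseline per region, clipped away from 0/1
  is_high <- stats::runif(n_reg) < cfg$mix_high
  pi_reg <- ifelse(is_high,
                   stats::rbeta(n_reg, cfg$baseline_shape$high[1], cfg$baseline_shape$high[2]),
                   stats::rbeta(n_reg, cfg$baseline_shape$low[1], cfg$baseline_shape$low[2]))
  pi_reg <- pmin(pmax(pi_reg, cfg$prop_clip), 1 - cfg$prop_clip)
  pi0 <- pi_reg[rid]

  # injected DMS: one region each; direction forced away from a boundary the
  # shift would clip through, random otherwise, so the realized group-mean
  # difference always has the truth direction's sign
  truth <- tibble::tibble(site = integer(), direction = character())
  active <- matrix(FALSE, nrow = ns, ncol = n_gen,
                   dimnames = list(NULL, gens))
  dirn_site <- rep(NA_character_, ns)
  inject <- cfg$n_dms > 0 && cfg$effect_delta != 0
  if (inject) {
    if (cfg$n_dms > n_reg) {
      stopf("n_dms (%d) exceeds the %d occupied regions", cfg$n_dms, n_reg)
    }
    dms_reg <- sort(sample.int(n_reg, cfg$n_dms))
    delta <- abs(cfg$effect_delta)
    can_up <- pi_reg[dms_reg] + delta <= 1 - cfg$prop_clip
    can_dn <- pi_reg[dms_reg] - delta >= cfg$prop_clip
    dirn <- ifelse(can_up & can_dn,
                   ifelse(stats::runif(cfg$n_dms) < 0.5, "hyper", "hypo"),
                   ifelse(can_up, "hyper", "hypo"))
    act_reg <- matrix(FALSE, cfg$n_dms, n_gen)
    act_reg[, 1] <- TRUE
    if (n_gen >= 2) {
      f2 <- stats::runif(cfg$n_dms) < cfg$inherit_frac_F2
      act_reg[, 2] <- f2
      if (n_gen >= 3) {
        if (cfg$nested) {
          # nested: F3-active drawn inside F2-active
          p3 <- if (cfg$inherit_frac_F2 > 0) {
            cfg$inherit_frac_F3 / cfg$inherit_frac_F2
          } else 0
          act_reg[, 3] <- f2 & stats::runif(cfg$n_dms) < p3
        } else {
          act_reg[, 3] <- stats::runif(cfg$n_dms) < cfg$inherit_frac_F3
        }
      }
    }
    # expand region-level truth to member sites; the truth table reports one
    # record per injected region at its first CpG
    site_of_reg <- match(dms_reg, rid)
    for (j in seq_len(cfg$n_dms)) {
      members <- which(rid == dms_reg[j])
      active[members, ] <- rep(act_reg[j, ], each = length(members))
      dirn_site[members] <- dirn[j]
    }
    truth <- tibble::tibble(site = site_of_reg, direction = dirn)
  }

  sheet <- tidyr::expand_grid(generation = gens,
                              group = c("control", "exposed"),
                              rep = seq_len(cfg$n_per_cell))
  sheet$sample_id <- sprintf("%s_%s_%d", sheet$generation,
                             ifelse(sheet$group == "exposed", "exp", "ctl"),
                             sheet$rep)
  sheet <- sheet[, c("sample_id", "generation", "group")]
  sheet$file_path <- NA_character_

  shift_site <- ifelse(is.na(dirn_site), 0,
                       ifelse(dirn_site == "hyper", 1, -1)) * abs(cfg$effect_delta)

  counts <- purrr::pmap_dfr(sheet, function(sample_id, generation, group, ...) {
    mu <- pi0
    if (group == "exposed" && inject) {
      on <- active[, generation]
      mu[on] <- pmin(pmax(pi0[on] + shift_site[on], cfg$prop_clip),
                     1 - cfg$prop_clip)
    }
    cov <- stats::rnbinom(ns, size = cfg$coverage_size, mu = cfg$coverage_mean)
    p <- if (cfg$phi > 0) {
      nu <- (1 - cfg$phi) / cfg$phi
      stats::rbeta(ns, mu * nu, (1 - mu) * nu)
    } else mu
    m <- stats::rbinom(ns, cov, p)
    tibble::tibble(sample_id = sample_id, chrom = cfg$chrom,
                   start = pos, end = pos + 1L, strand = "unknown",
                   methylated = m, unmethylated = cov - m, coverage = cov)
  })

  truth_tbl <- tibble::tibble(
    chrom = cfg$chrom,
    start = pos[truth$site],
    end = pos[truth$site] + 1L,
    direction = truth$direction
  )
  for (g in gens) {
    truth_tbl[[paste0("active_", g)]] <- active[truth$site, g]
  }

  structure(list(counts = counts,
                 sheet = validate_sample_sheet(sheet, generations = gens),
                 truth = truth_tbl, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sites x %d samples (%s), %d injected DMS\n",
              x$config$n_sites, nrow(x$sheet),
              paste(x$config$generations, collapse = "/"),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one bismark-coverage count file per sample, a sample sheet CSV
#' (with `file_path` filled in) and the truth table as TSV — the same
#' dialects that [read_count_file()] and [read_sample_sheet()] consume.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The sheet path, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$sheet
  sheet$file_path <- file.path(dir, paste0(sheet$sample_id, ".cov"))
  for (i in seq_len(nrow(sheet))) {
    write_count_file(
      dplyr::filter(sim$counts, .data$sample_id == sheet$sample_id[i]),
      sheet$file_path[i]
    )
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  sheet_path <- file.path(dir, "samples.csv")
  readr::write_csv(sheet, sheet_path, progress = FALSE)
  invisible(sheet_path)
}
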