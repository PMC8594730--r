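# Internal vectorised detection engine.
#
# The permutation test re-runs the whole detection procedure
# (unite -> tile -> test -> adjust -> call -> conserve) thousands of times, so
# the per-CpG data are held once as site x sample matrices and each
# re-analysis is a handful of vectorised matrix operations. The tibble-level
# functions (unite_samples(), tile_counts(), diff_methylation()) express the
# same procedure one stage at a time; agreement between the two routes is
# asserted in the test suite.

build_meth_engine <- function(counts, sheet, cfg = filter_config()) {
  counts <- filter_coverage(counts, cfg)
  samples <- as.character(sheet$sample_id)

  key <- site_key(counts$chrom, counts$start, counts$end)
  ukey <- !duplicated(key)
  sites <- tibble::tibble(chrom = counts$chrom[ukey],
                          start = counts$start[ukey],
                          key = key[ukey])
  sites <- dplyr::arrange(sites, .data$chrom, .data$start)
  row_of <- match(key, sites$key)
  col_of <- match(counts$sample_id, samples)
  if (anyNA(col_of)) stopf("counts contain samples absent from the sheet")

  n <- nrow(sites)
  M <- matrix(NA_real_, n, length(samples))
  Cov <- matrix(NA_real_, n, length(samples))
  idx <- cbind(row_of, col_of)
  M[idx] <- counts$methylated
  Cov[idx] <- counts$coverage

  w <- cfg$tile_window
  tkey <- paste(sites$chrom, sites$start %/% w, sep = ":")
  tf <- factor(tkey, levels = unique(tkey))
  list(
    sites = sites, M = M, Cov = Cov, samples = samples,
    tile_id = as.integer(tf),
    tile_chrom = sites$chrom[!duplicated(tf)],
    tile_start = as.integer((sites$start %/% w)[!duplicated(tf)] * w),
    tile_window = w, cfg = cfg
  )
}

# likelihood-ratio p for a binomial GLM with a group-only covariate; the
# fitted proportions are the group-pooled proportions, so the LR statistic
# reduces to the G-statistic of the pooled 2x2 table
lrt_pooled_p <- function(m1, c1, m2, c2) {
  xlx <- function(m, c, p) {
    out <- numeric(length(m))
    pos <- !is.na(p) & p > 0 & p < 1
    out[pos] <- m[pos] * log(p[pos]) + (c[pos] - m[pos]) * log1p(-p[pos])
    out
  }
  p1 <- m1 / c1; p2 <- m2 / c2
  p0 <- (m1 + m2) / (c1 + c2)
  stat <- 2 * (xlx(m1, c1, p1) + xlx(m2, c2, p2) - xlx(m1 + m2, c1 + c2, p0))
  p <- stats::pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
  p[c1 == 0 | c2 == 0] <- NA_real_
  p
}

fisher_pooled_p <- function(m1, c1, m2, c2) {
  purrr::pmap_dbl(list(m1, c1, m2, c2), function(a, ca, b, cb) {
    if (is.na(ca) || is.na(cb) || ca == 0 || cb == 0) return(NA_real_)
    stats::fisher.test(matrix(c(a, ca - a, b, cb - b), nrow = 2))$p.value
  })
}

# one generation's detection on the matrix representation; cols_case /
# cols_ctrl index engine$samples. Returns per-tile stats on the global tile
# id space (zero tested tiles -> zero-row tibble, never an error: a collapsed
# permutation is recorded as count 0).
engine_test_generation <- function(engine, cols_case, cols_ctrl,
                                   method = "logistic_lrt",
                                   diff_method = "pooled") {
  cfg <- engine$cfg
  cols <- c(cols_case, cols_ctrl)
  cv <- engine$Cov[, cols, drop = FALSE]
  ok <- !is.na(cv) & cv >= cfg$min_reads_per_sample
  mask <- rowSums(ok) == length(cols)
  empty <- tibble::tibble(tile = integer(), meth_case = numeric(),
                          meth_control = numeric(), meth_diff = numeric(),
                          p_value = numeric())
  if (!any(mask)) return(empty)

  tid <- engine$tile_id[mask]
  TM <- rowsum(engine$M[mask, cols, drop = FALSE], tid)
  TC <- rowsum(cv[mask, , drop = FALSE], tid)
  ncpg <- rowsum(rep(1L, sum(mask)), tid)[, 1]
  tiles <- as.integer(rownames(TM))

  keep <- ncpg >= cfg$min_cpg_per_tile
  if (cfg$recheck_tile_coverage) {
    keep <- keep & rowSums(TC >= cfg$min_reads_per_sample) == length(cols)
  }
  if (!any(keep)) return(empty)
  TM <- TM[keep, , drop = FALSE]; TC <- TC[keep, , drop = FALSE]
  tiles <- tiles[keep]

  ica <- seq_along(cols_case)
  ico <- length(cols_case) + seq_along(cols_ctrl)
  m1 <- rowSums(TM[, ica, drop = FALSE]); c1 <- rowSums(TC[, ica, drop = FALSE])
  m2 <- rowSums(TM[, ico, drop = FALSE]); c2 <- rowSums(TC[, ico, drop = FALSE])

  p <- switch(method,
              logistic_lrt = lrt_pooled_p(m1, c1, m2, c2),
              fisher_pooled = fisher_pooled_p(m1, c1, m2, c2),
              stopf("unknown test method: %s", method))
  if (diff_method == "pooled") {
    mc <- 100 * m1 / c1
    mk <- 100 * m2 / c2
  } else {
    mc <- 100 * rowMeans(TM[, ica, drop = FALSE] / TC[, ica, drop = FALSE])
    mk <- 100 * rowMeans(TM[, ico, drop = FALSE] / TC[, ico, drop = FALSE])
  }
  tibble::tibble(tile = tiles, meth_case = unname(mc),
                 meth_control = unname(mk), meth_diff = unname(mc - mk),
                 p_value = unname(p))
}

# full detection for one design assignment; returns a list per generation of
# called per-tile tibbles (with q_value and direction)
engine_detect <- function(engine, design, preset = stringency_preset(),
                          method = "logistic_lrt", diff_method = "pooled") {
  gens <- levels(factor(design$generation))
  res <- lapply(gens, function(g) {
    d <- design[design$generation == g, ]
    cols_case <- match(d$sample_id[d$group == "exposed"], engine$samples)
    cols_ctrl <- match(d$sample_id[d$group == "control"], engine$samples)
    tt <- engine_test_generation(engine, cols_case, cols_ctrl,
                                 method = method, diff_method = diff_method)
    tt$q_value <- adjust_q(tt$p_value)
    tt$direction <- dms_direction(tt$meth_diff, tt$q_value, preset)
    tt
  })
  names(res) <- gens
  res
}

# conserved-count statistics for the given chains; returns a named numeric
# like c("F1.F2|hyper" = ..., "F1.F2|hypo" = ...)
engine_conserved_counts <- function(detected, chains) {
  out <- numeric(0)
  for (chain in chains) {
    for (dirn in c("hyper", "hypo")) {
      sets <- lapply(chain, function(g) {
        d <- detected[[g]]
        d$tile[d$direction == dirn]
      })
      n <- length(Reduce(intersect, sets))
      out[paste0(paste(chain, collapse = "."), "|", dirn)] <- n
    }
  }
  out
}
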