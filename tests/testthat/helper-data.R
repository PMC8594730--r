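# fixture builders and independent oracles shared across test files

# quick long-count-tibble constructor; positions are 0-based site starts
make_counts <- function(sample_id, chrom = "chr1", start, methylated,
                        unmethylated) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, start = as.integer(start),
    end = as.integer(start + 1L), strand = "unknown",
    methylated = as.integer(methylated),
    unmethylated = as.integer(unmethylated),
    coverage = as.integer(methylated + unmethylated)
  )
}

# a design tibble for n exposed + n control samples in each given generation
make_design <- function(generations = "F1", n = 6) {
  d <- tidyr::expand_grid(generation = generations,
                          group = c("control", "exposed"),
                          rep = seq_len(n))
  tibble::tibble(
    sample_id = sprintf("%s_%s_%d", d$generation,
                        substr(d$group, 1, 3), d$rep),
    generation = d$generation, group = d$group
  )
}

# independent two-sided Fisher p by exhaustive hypergeometric enumeration:
# sum of P(table) over all tables with the observed margins whose probability
# is <= the observed one (with the customary relative epsilon for ties)
oracle_fisher_two_sided <- function(m1, u1, m2, u2) {
  c1 <- m1 + u1; c2 <- m2 + u2; k <- m1 + m2
  lo <- max(0, k - c2); hi <- min(k, c1)
  support <- lo:hi
  d <- stats::dhyper(support, c1, c2, k)
  sum(d[d <= d[support == m1] * (1 + 1e-7)])
}

# hand Benjamini-Hochberg step-up: q_i = min_{j >= rank(i)} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# small deterministic multi-sample count fixture with every site covered in
# every sample (coverage >= cov_min), for unite/tile tests
dense_fixture <- function(n_sites = 50, samples = paste0("s", 1:4),
                          cov_min = 12, seed = 42) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(n_sites * 40, n_sites)) - 1L
    purrr::map_dfr(samples, function(s) {
      cov <- cov_min + stats::rpois(n_sites, 8)
      m <- stats::rbinom(n_sites, cov, 0.4)
      make_counts(s, start = pos, methylated = m, unmethylated = cov - m)
    })
  })
}
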