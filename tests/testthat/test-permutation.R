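# a small two-generation dataset where every sample is identical: detection
# finds nothing under any labelling
identical_sample_dataset <- function(n_sites = 60) {
  sheet <- make_design(c("F1", "F2"), 3)
  pos <- seq(0, by = 40, length.out = n_sites)
  counts <- purrr::map_dfr(sheet$sample_id, function(s) {
    make_counts(s, start = pos, methylated = 6L, unmethylated = 14L)
  })
  list(counts = counts, sheet = sheet)
}

test_that("permuted designs preserve the cell sizes in both modes", {
  design <- make_design(c("F1", "F2", "F3"), 6)
  withr::local_seed(3)
  for (i in 1:20) {
    w <- permute_design(design, "within_generation")
    expect_equal(w$sample_id, design$sample_id)
    expect_equal(w$generation, design$generation)   # generations untouched
    tab <- table(w$generation, w$group)
    expect_true(all(tab == 6L))

    a <- permute_design(design, "across_generations")
    expect_equal(sort(a$sample_id), sort(design$sample_id))
    tab2 <- table(a$generation, a$group)
    expect_true(all(tab2 == 6L))
  }
  degenerate <- design[design$group == "control" | design$generation != "F2", ]
  expect_error(permute_design(degenerate), "degenerate")
})

test_that("across-generation re-dealing is uniform over admissible cells", {
  # 2/2 x 2 design; under uniform re-dealing every 2-subset of the 8 samples
  # is equally likely to land in the (F1, exposed) cell
  design <- make_design(c("F1", "F2"), 2)
  withr::local_seed(29)
  draws <- replicate(10000, {
    p <- permute_design(design, "across_generations")
    paste(sort(p$sample_id[p$generation == "F1" & p$group == "exposed"]),
          collapse = "+")
  })
  counts <- table(draws)
  expect_equal(length(counts), choose(8, 2))
  chi <- sum((counts - 10000 / 28)^2 / (10000 / 28))
  expect_lt(chi, qchisq(0.999, df = 27))
})

test_that("empirical p-values follow the k/N convention", {
  expect_equal(empirical_pvalue(c(0, 1, 2, 5), 2), 0.5)
  expect_equal(empirical_pvalue(rep(0, 10), 1), 0)
  expect_equal(empirical_pvalue(rep(0, 10), 0), 1)
  expect_equal(empirical_pvalue(c(0, 1, 2, 5), 2, add_one = TRUE), 0.6)
})

test_that("the permutation test is reproducible under a fixed seed", {
  sim <- simulate_dataset(sim_config(n_sites = 300, n_dms = 20, seed = 71,
                                     generations = c("F1", "F2")))
  plan <- permutation_plan(n_permutations = 30, seed = 5,
                           statistic_chains = list(c("F1", "F2")))
  a <- run_permutation_test(sim$counts, sim$sheet, plan = plan)
  b <- run_permutation_test(sim$counts, sim$sheet, plan = plan)
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$p_value, b$p_value)
})

test_that("p-values are invariant to relabelling sample ids", {
  sim <- simulate_dataset(sim_config(n_sites = 250, n_dms = 15, seed = 73,
                                     generations = c("F1", "F2")))
  plan <- permutation_plan(n_permutations = 25, seed = 9,
                           statistic_chains = list(c("F1", "F2")))
  a <- run_permutation_test(sim$counts, sim$sheet, plan = plan)
  ren <- stats::setNames(paste0("animal_", seq_len(nrow(sim$sheet))),
                         sim$sheet$sample_id)
  counts2 <- dplyr::mutate(sim$counts, sample_id = unname(ren[sample_id]))
  sheet2 <- dplyr::mutate(sim$sheet, sample_id = unname(ren[sample_id]))
  b <- run_permutation_test(counts2, sheet2, plan = plan)
  expect_identical(a$p_value, b$p_value)
})

test_that("identical samples force p = 1 and a flat convergence trace", {
  d <- identical_sample_dataset()
  plan <- permutation_plan(n_permutations = 120, seed = 2,
                           statistic_chains = list(c("F1", "F2")))
  res <- run_permutation_test(d$counts, d$sheet, plan = plan)
  expect_true(all(res$observed == 0))
  expect_true(all(res$null_counts == 0))
  expect_true(all(res$p_value == 1))
  conv <- convergence(res)
  expect_equal(conv$status, "converged")
  expect_true(all(conv$max_change == 0))
  # the trace ends at the reported p-value
  expect_equal(res$trace[nrow(res$trace), ], res$p_value)
})

test_that("fewer than 100 permutations is flagged not evaluable", {
  d <- identical_sample_dataset(30)
  res <- run_permutation_test(d$counts, d$sheet,
                              plan = permutation_plan(50, seed = 1,
                                statistic_chains = list(c("F1", "F2"))))
  expect_equal(convergence(res)$status, "not_evaluable")
})

test_that("exhaustive enumeration reproduces the exact permutation p", {
  # one generation, 3 exposed vs 3 control: the group has C(6,3) = 20
  # distinct assignments; the exact p is computed by an independent
  # stage-by-stage re-analysis of each assignment
  sim <- simulate_dataset(sim_config(n_sites = 80, n_dms = 8, seed = 81,
                                     n_per_cell = 3, generations = "F1",
                                     effect_delta = 0.35))
  preset <- stringency_preset("custom", q_max = 0.2, min_diff = 5)
  plan <- permutation_plan(mode = "within_generation", seed = 4,
                           statistic_chains = list("F1"), exhaustive = TRUE)
  res <- run_permutation_test(sim$counts, sim$sheet, filter_config(), preset,
                              plan)
  expect_equal(res$n_permutations, 20L)

  cfg <- filter_config()
  tiles <- tile_counts(unite_samples(filter_coverage(sim$counts, cfg), cfg),
                       cfg)
  count_for <- function(exposed_ids) {
    des <- dplyr::mutate(sim$sheet, group = ifelse(
      sample_id %in% exposed_ids, "exposed", "control"))
    dms <- call_dms(diff_methylation(tiles, des), preset)
    c(hyper = sum(dms$direction == "hyper"),
      hypo = sum(dms$direction == "hypo"))
  }
  combos <- utils::combn(sim$sheet$sample_id, 3, simplify = FALSE)
  null <- t(vapply(combos, count_for, c(hyper = 0, hypo = 0)))
  obs <- count_for(sim$sheet$sample_id[sim$sheet$group == "exposed"])
  expect_equal(unname(res$observed["F1|hyper"]), unname(obs["hyper"]))
  expect_equal(unname(res$p_value["F1|hyper"]),
               mean(null[, "hyper"] >= obs["hyper"]))
  expect_equal(unname(res$p_value["F1|hypo"]),
               mean(null[, "hypo"] >= obs["hypo"]))
})

test_that("collapsed permutations are recorded as zero counts, not dropped", {
  # min_reads higher than any coverage: every analysis collapses
  d <- identical_sample_dataset(20)
  res <- run_permutation_test(
    d$counts, d$sheet, filter_config(min_reads_per_sample = 100),
    plan = permutation_plan(15, seed = 3,
                            statistic_chains = list(c("F1", "F2")))
  )
  expect_equal(nrow(res$null_counts), 15L)
  expect_true(all(res$null_counts == 0))
  expect_true(all(res$p_value == 1))
})

test_that("tidy, glance and autoplot expose the result", {
  sim <- simulate_dataset(sim_config(n_sites = 200, n_dms = 10, seed = 91,
                                     generations = c("F1", "F2")))
  res <- run_permutation_test(sim$counts, sim$sheet,
                              plan = permutation_plan(20, seed = 6,
                                statistic_chains = list(c("F1", "F2"))))
  td <- generics::tidy(res)
  expect_equal(nrow(td), 2L)
  expect_named(td, c("chain", "direction", "observed", "null_mean", "p_value"))
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
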