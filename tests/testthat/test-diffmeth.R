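test_that("identical groups give zero difference and p = 1", {
  r <- test_tile(case_m = c(5, 3), case_u = c(5, 7),
                 control_m = c(5, 3), control_u = c(5, 7),
                 method = "fisher_pooled")
  expect_equal(r$meth_diff, 0)
  expect_equal(r$p_value, 1)
})

test_that("pooled Fisher p equals the hypergeometric enumeration oracle", {
  r <- test_tile(9, 1, 1, 9, method = "fisher_pooled")
  expect_equal(r$p_value, oracle_fisher_two_sided(9, 1, 1, 9), tolerance = 1e-9)
  # a batch of random tables
  withr::local_seed(12)
  for (i in 1:25) {
    m1 <- sample(0:12, 1); u1 <- sample(0:12, 1)
    m2 <- sample(0:12, 1); u2 <- sample(0:12, 1)
    if (m1 + u1 == 0 || m2 + u2 == 0) next
    got <- test_tile(m1, u1, m2, u2, method = "fisher_pooled")$p_value
    expect_equal(got, oracle_fisher_two_sided(m1, u1, m2, u2),
                 tolerance = 1e-9)
  }
})

test_that("swapping case and control negates the difference, not the p", {
  withr::local_seed(4)
  cm <- rbinom(6, 30, 0.6); cu <- 30 - cm
  km <- rbinom(6, 30, 0.3); ku <- 30 - km
  a <- test_tile(cm, cu, km, ku)
  b <- test_tile(km, ku, cm, cu)
  expect_equal(a$meth_diff, -b$meth_diff)
  expect_equal(a$p_value, b$p_value)
})

test_that("the closed-form logistic LRT matches a glm likelihood-ratio test", {
  withr::local_seed(23)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    cov1 <- sample(10:40, n1, replace = TRUE)
    cov2 <- sample(10:40, n2, replace = TRUE)
    m1 <- rbinom(n1, cov1, runif(1, 0.1, 0.9))
    m2 <- rbinom(n2, cov2, runif(1, 0.1, 0.9))
    got <- test_tile(m1, cov1 - m1, m2, cov2 - m2)$p_value
    grp <- factor(rep(c("case", "ctrl"), c(n1, n2)))
    fit <- stats::glm(cbind(c(m1, m2), c(cov1 - m1, cov2 - m2)) ~ grp,
                      family = stats::binomial())
    p_glm <- stats::pchisq(fit$null.deviance - fit$deviance, 1,
                           lower.tail = FALSE)
    expect_equal(got, p_glm, tolerance = 1e-6)
  }
})

test_that("a group with zero total coverage yields an NA p-value", {
  r <- test_tile(0, 0, 3, 7)
  expect_true(is.na(r$p_value))
})

test_that("BH q-values reproduce hand-computed step-up values", {
  expect_equal(adjust_q(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_q(0.2), 0.2)
  expect_equal(adjust_q(rep(1, 5)), rep(1, 5))
  withr::local_seed(6)
  p <- runif(50)
  expect_equal(adjust_q(p), oracle_bh(p))
  # NAs are excluded from m and preserved in place
  p_na <- c(0.01, NA, 0.04)
  q <- adjust_q(p_na)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(p_na[c(1, 3)]))
  expect_equal(adjust_q(numeric(0)), numeric(0))
})

test_that("q-values are monotone in p and never smaller than p", {
  withr::local_seed(61)
  p <- runif(200)
  q <- adjust_q(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("stringency presets gate calls on both q and difference", {
  fix <- tibble::tibble(
    chrom = "chr1", start = (0:5) * 100L, end = (1:6) * 100L,
    meth_diff = c(25, 15, 40, -25, -15, 5),
    q_value = c(0.005, 0.005, 0.02, 0.005, 0.005, 0.005)
  )
  met20 <- call_dms(fix, stringency_preset("COV10_Met20"))
  expect_equal(as.character(met20$direction),
               c("hyper", "ns", "ns", "hypo", "ns", "ns"))
  met10 <- call_dms(fix, stringency_preset("COV10_Met10"))
  expect_equal(as.character(met10$direction),
               c("hyper", "hyper", "ns", "hypo", "hypo", "ns"))
})

test_that("logistic and Fisher calls agree on strongly separated tiles", {
  withr::local_seed(77)
  for (i in 1:10) {
    p_case <- runif(1, 0.65, 0.9)
    cov <- sample(30:50, 12, replace = TRUE)
    m_case <- rbinom(6, cov[1:6], p_case)
    m_ctrl <- rbinom(6, cov[7:12], p_case - 0.45)
    a <- test_tile(m_case, cov[1:6] - m_case, m_ctrl, cov[7:12] - m_ctrl,
                   method = "logistic_lrt")
    b <- test_tile(m_case, cov[1:6] - m_case, m_ctrl, cov[7:12] - m_ctrl,
                   method = "fisher_pooled")
    expect_equal(sign(a$meth_diff), sign(b$meth_diff))
    expect_lt(a$p_value, 0.01)
    expect_lt(b$p_value, 0.01)
  }
})

test_that("pooled and mean-of-samples differences disagree when coverage varies", {
  case_m <- c(9, 1); case_u <- c(1, 9)     # pooled 50%, mean of (90%, 10%) = 50%
  ctrl_m <- c(8, 0); ctrl_u <- c(32, 10)   # pooled 16%, mean of (20%, 0%) = 10%
  pooled <- test_tile(case_m, case_u, ctrl_m, ctrl_u, diff_method = "pooled")
  meanly <- test_tile(case_m, case_u, ctrl_m, ctrl_u, diff_method = "mean")
  expect_equal(pooled$meth_diff, 100 * (10 / 20 - 8 / 50))
  expect_equal(meanly$meth_diff, 100 * (0.5 - 0.1))
})

test_that("diff_methylation on tiles matches the per-tile test_tile route", {
  sim <- simulate_dataset(sim_config(n_sites = 300, n_dms = 20, seed = 15))
  cfg <- filter_config()
  ids <- sim$sheet$sample_id[sim$sheet$generation == "F1"]
  counts <- dplyr::filter(sim$counts, .data$sample_id %in% ids)
  tiles <- tile_counts(unite_samples(filter_coverage(counts, cfg), cfg), cfg)
  res <- diff_methylation(tiles, sim$sheet)

  # re-test three tiles individually
  des <- sim$sheet[match(unique(tiles$sample_id), sim$sheet$sample_id), ]
  withr::local_seed(1)
  for (i in sample(nrow(res), 3)) {
    tl <- dplyr::filter(tiles, .data$start == res$start[i],
                        .data$chrom == res$chrom[i])
    tl <- dplyr::inner_join(tl, des[c("sample_id", "group")], by = "sample_id")
    one <- test_tile(tl$methylated[tl$group == "exposed"],
                     tl$unmethylated[tl$group == "exposed"],
                     tl$methylated[tl$group == "control"],
                     tl$unmethylated[tl$group == "control"])
    expect_equal(res$meth_diff[i], one$meth_diff)
    expect_equal(res$p_value[i], one$p_value)
  }
})

test_that("the matrix engine agrees with the tibble pipeline stage by stage", {
  sim <- simulate_dataset(sim_config(n_sites = 500, n_dms = 30, seed = 19))
  cfg <- filter_config()
  preset <- stringency_preset("COV10_Met20")
  engine <- methylegacy:::build_meth_engine(sim$counts, sim$sheet, cfg)
  det <- methylegacy:::engine_detect(engine, sim$sheet, preset)
  for (g in c("F1", "F2", "F3")) {
    ids <- sim$sheet$sample_id[sim$sheet$generation == g]
    counts <- dplyr::filter(sim$counts, .data$sample_id %in% ids)
    tiles <- tile_counts(unite_samples(filter_coverage(counts, cfg), cfg), cfg)
    ref <- call_dms(diff_methylation(tiles, sim$sheet), preset)
    eng <- det[[g]]
    eng_start <- engine$tile_start[eng$tile]
    ord <- order(eng_start)
    expect_equal(eng_start[ord], ref$start)
    expect_equal(eng$meth_diff[ord], ref$meth_diff)
    expect_equal(eng$p_value[ord], ref$p_value)
    expect_equal(eng$q_value[ord], ref$q_value)
    expect_equal(as.character(eng$direction[ord]), as.character(ref$direction))
  }
})
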