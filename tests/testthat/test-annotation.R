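# hand-built toy model: one gene per strand with known TSS positions
toy_model <- function() {
  methylegacy:::new_gene_model(tibble::tibble(
    gene_id = c("gPlus", "gMinus"),
    transcript_id = c("tPlus", "tMinus"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(10000L, 30000L),
    end = c(12000L, 32000L),
    exon_starts = list(c(10000L, 11000L), c(30000L, 31500L)),
    exon_ends = list(c(10400L, 12000L), c(30500L, 32000L)),
    utr5_starts = list(10000L, 31900L),
    utr5_ends = list(10100L, 32000L),
    utr3_starts = list(11800L, 30000L),
    utr3_ends = list(12000L, 30100L)
  ))
}

test_that("promoter windows are strand-aware [-2 kb, +100 bp] around the TSS", {
  idx <- build_feature_index(toy_model())
  prom <- idx$categories$promoter
  # + strand gene, TSS at 0-based 10000 -> [8000, 10100)
  plus <- prom[S4Vectors::mcols(prom)$gene_id == "gPlus"]
  expect_equal(GenomicRanges::start(plus), 8001L)   # 1-based GRanges
  expect_equal(GenomicRanges::end(plus), 10100L)
  # - strand gene, TSS at 0-based 31999 (last transcribed base)
  minus <- prom[S4Vectors::mcols(prom)$gene_id == "gMinus"]
  expect_equal(GenomicRanges::start(minus), 31900L)  # [31899, 33999) 0-based
  expect_equal(GenomicRanges::end(minus), 33999L)
})

test_that("spec'd promoter boundary examples hold through annotate_sites", {
  # gene with TSS exactly at 10000 on +: midpoints 8000 and 10099 inside,
  # 7999 and 10100 outside
  idx <- build_feature_index(toy_model())
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(8000L, 10099L, 7999L, 10100L),
                          end = c(8001L, 10100L, 8000L, 10101L))
  ann <- annotate_sites(sites, idx)
  expect_equal(as.character(ann$category[1:2]), c("promoter", "promoter"))
  expect_false(ann$category[3] == "promoter")
  expect_false(ann$category[4] == "promoter")
})

test_that("single-exon transcripts produce no intron intervals", {
  m <- methylegacy:::new_gene_model(tibble::tibble(
    gene_id = "g1", transcript_id = "t1", chrom = "chr1", strand = "+",
    start = 1000L, end = 1500L,
    exon_starts = list(1000L), exon_ends = list(1500L),
    utr5_starts = list(integer(0)), utr5_ends = list(integer(0)),
    utr3_starts = list(integer(0)), utr3_ends = list(integer(0))
  ))
  idx <- build_feature_index(m)
  expect_equal(length(idx$categories$intron), 0L)
})

test_that("category precedence equals brute-force overlap evaluation", {
  model <- random_gene_model(n_genes = 25, chrom_length = 6e5, seed = 33)
  idx <- build_feature_index(model)
  withr::local_seed(34)
  sites <- tibble::tibble(chrom = "chr1",
                          start = sample.int(6e5, 1000) - 1L)
  sites$end <- sites$start + 1L
  ann <- annotate_sites(sites, idx)

  # oracle: evaluate every category by direct interval containment of the
  # midpoint and apply the precedence order
  cat_tables <- lapply(idx$categories, function(gr) {
    tibble::tibble(s = GenomicRanges::start(gr) - 1L,
                   e = GenomicRanges::end(gr))
  })
  precedence <- names(idx$categories)
  oracle <- vapply(seq_len(nrow(sites)), function(i) {
    mid <- (sites$start[i] + sites$end[i]) %/% 2
    for (cat in precedence) {
      tb <- cat_tables[[cat]]
      if (any(tb$s <= mid & mid < tb$e)) return(cat)
    }
    "intergenic"
  }, character(1))
  expect_equal(as.character(ann$category), oracle)
})

test_that("annotation is invariant to transcript input order", {
  model <- random_gene_model(n_genes = 15, chrom_length = 4e5, seed = 51)
  shuffled <- model[rev(seq_len(nrow(model))), ]
  class(shuffled) <- class(model)
  withr::local_seed(52)
  sites <- tibble::tibble(chrom = "chr1", start = sample.int(4e5, 300) - 1L)
  sites$end <- sites$start + 1L
  a <- annotate_sites(sites, build_feature_index(model))
  b <- annotate_sites(sites, build_feature_index(shuffled))
  expect_equal(as.character(a$category), as.character(b$category))
  expect_equal(a$gene_id, b$gene_id)
})

test_that("tiles are annotated by their midpoint base", {
  # exon [10000,10400) then intron; tile [10300,10400+] straddles the boundary
  idx <- build_feature_index(toy_model())
  tile <- tibble::tibble(chrom = "chr1", start = 10350L, end = 10450L)
  ann <- annotate_sites(tile, idx)      # midpoint 10400 = first intron base
  expect_equal(as.character(ann$category), "intron")
  tile2 <- tibble::tibble(chrom = "chr1", start = 10250L, end = 10350L)
  ann2 <- annotate_sites(tile2, idx)    # midpoint 10300 inside the exon
  expect_equal(as.character(ann2$category), "exon")
})

test_that("far sites are intergenic with the nearest gene attached and excluded", {
  idx <- build_feature_index(toy_model())
  site <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20001L)
  ann <- annotate_sites(site, idx)
  expect_equal(as.character(ann$category), "intergenic")
  expect_equal(ann$gene_id, "gPlus")   # TSS 10000 is closer than 31999
  expect_true(ann$gene_excluded)
  # signed TSS distance in transcript orientation
  expect_equal(ann$distance_to_tss, 20000L - 10000L)
})

test_that("unknown chromosomes warn once and fall back to intergenic", {
  idx <- build_feature_index(toy_model())
  site <- tibble::tibble(chrom = "chrUn", start = 5L, end = 6L)
  expect_warning(ann <- annotate_sites(site, idx), "chrUn")
  expect_equal(as.character(ann$category), "intergenic")
  expect_true(is.na(ann$gene_id))
})

test_that("category fractions tally by hand and sum to one", {
  idx <- build_feature_index(toy_model())
  ann <- annotate_sites(
    tibble::tibble(chrom = "chr1",
                   start = c(10500L, 10600L, 10700L, 10800L),
                   end = c(10501L, 10601L, 10701L, 10801L)),
    idx
  )
  dist <- category_distribution(ann)
  expect_equal(dist$fraction[dist$category == "intron"], 1)
  expect_equal(sum(dist$fraction), 1, tolerance = 1e-9)

  # ten sites with hand-known categories, split by direction
  ann10 <- annotate_sites(
    tibble::tibble(chrom = "chr1",
                   start = c(9000L, 9100L, 10200L, 10500L, 20000L,
                             31000L, 31600L, 31950L, 30050L, 11900L),
                   end = c(9001L, 9101L, 10201L, 10501L, 20001L,
                           31001L, 31601L, 31951L, 30051L, 11901L)),
    idx
  )
  ann10$direction <- factor(rep(c("hyper", "hypo"), 5),
                            levels = c("hyper", "hypo", "ns"))
  d <- category_distribution(ann10)
  hyper_intron <- d$n[d$direction == "hyper" & d$category == "intron"]
  expect_equal(hyper_intron, sum(ann10$category[c(1, 3, 5, 7, 9)] == "intron"))
  sums <- tapply(d$fraction, d$direction, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(category_distribution(ann10[0, ]), "empty")
})

test_that("GTF gene models parse and skip exonless transcripts with a warning", {
  gtf <- c(
    'chr1\ttest\texon\t1001\t1400\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\texon\t2001\t2400\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\tCDS\t1101\t2300\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\tCDS\t5001\t5200\t.\t-\t.\tgene_id "gB"; transcript_id "tB";'
  )
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  expect_warning(model <- read_gene_model(f), "zero exons")
  expect_equal(nrow(model), 1L)
  expect_equal(model$start, 1000L)       # 0-based
  expect_equal(model$end, 2400L)
  expect_equal(model$tss, 1000L)
  expect_equal(model$exon_starts[[1]], c(1000L, 2000L))
  expect_equal(model$utr5_starts[[1]], 1000L)   # exon bp before CDS at 1100
  expect_equal(model$utr5_ends[[1]], 1100L)
  expect_equal(model$utr3_starts[[1]], 2300L)
  expect_equal(model$utr3_ends[[1]], 2400L)
})

test_that("BED12 gene models parse blocks into exons and thick into CDS", {
  bed <- "chr1\t1000\t2400\ttxX\t0\t-\t1100\t2300\t0\t2\t400,400\t0,1000"
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed, f)
  model <- read_gene_model(f)
  expect_equal(model$strand, "-")
  expect_equal(model$tss, 2399L)
  expect_equal(model$exon_starts[[1]], c(1000L, 2000L))
  expect_equal(model$exon_ends[[1]], c(1400L, 2400L))
  # on the minus strand the 5' UTR is the high-coordinate side
  expect_equal(model$utr5_starts[[1]], 2300L)
  expect_equal(model$utr3_ends[[1]], 1100L)
})
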