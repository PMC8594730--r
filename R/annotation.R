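#' Build the genomic feature index for annotation
#'
#' Derives the six genic feature classes from a gene model, with the study's
#' redefined promoter window: a strand-aware interval from `promoter_up` bp
#' upstream to `promoter_down` bp downstream of the TSS (default -2 kb to
#' +100 bp). The TTS window is symmetric `tts_window` bp around the
#' transcription termination site. Exons are the transcript's exon intervals;
#' introns the gaps between them; UTRs come from the model. Overlaps between
#' classes are resolved at annotation time by the fixed precedence
#' promoter > TTS > 5'UTR > 3'UTR > exon > intron.
#'
#' @param model A `gene_model` tibble (see [read_gene_model()],
#'   [random_gene_model()]).
#' @param promoter_up,promoter_down Promoter extent upstream / downstream of
#'   the TSS, in bp.
#' @param tts_window Half-width of the TTS window in bp.
#' @return A `feature_index`: a list of per-category
#'   [GenomicRanges::GRanges-class] objects (with `gene_id` metadata) plus
#'   the TSS table used for nearest-gene assignment.
#' @export
build_feature_index <- function(model, promoter_up = 2000,
                                promoter_down = 100, tts_window = 100) {
  stopifnot(inherits(model, "gene_model"))
  plus <- model$strand == "+"
  # 0-based half-open windows; spec'd promoter: + strand [tss-up, tss+down),
  # - strand [tss-down, tss+up)
  prom_s <- ifelse(plus, model$tss - promoter_up, model$tss - promoter_down)
  prom_e <- ifelse(plus, model$tss + promoter_down, model$tss + promoter_up)
  tts_s <- model$tts - tts_window
  tts_e <- model$tts + tts_window

  gr0 <- function(chrom, s, e, gene) {
    keep <- e > s
    GenomicRanges::GRanges(
      chrom[keep],
      IRanges::IRanges(pmax(s[keep], 0) + 1L, e[keep]),
      gene_id = gene[keep]
    )
  }
  exon_tbl <- tidyr::unnest(
    dplyr::select(model, "gene_id", "chrom",
                  s = "exon_starts", e = "exon_ends"),
    c("s", "e")
  )
  intron_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(model)), function(i) {
    es <- sort(model$exon_starts[[i]]); ee <- sort(model$exon_ends[[i]])
    if (length(es) < 2) return(NULL)
    tibble::tibble(gene_id = model$gene_id[i], chrom = model$chrom[i],
                   s = ee[-length(ee)], e = es[-1])
  }))
  utr_tbl <- function(which) {
    tidyr::unnest(
      dplyr::select(model, "gene_id", "chrom",
                    s = paste0(which, "_starts"), e = paste0(which, "_ends")),
      c("s", "e")
    )
  }
  u5 <- utr_tbl("utr5"); u3 <- utr_tbl("utr3")
  structure(list(
    categories = list(
      promoter = gr0(model$chrom, prom_s, prom_e, model$gene_id),
      TTS = gr0(model$chrom, tts_s, tts_e, model$gene_id),
      utr5 = gr0(u5$chrom, u5$s, u5$e, u5$gene_id),
      utr3 = gr0(u3$chrom, u3$s, u3$e, u3$gene_id),
      exon = gr0(exon_tbl$chrom, exon_tbl$s, exon_tbl$e, exon_tbl$gene_id),
      intron = if (nrow(intron_tbl)) {
        gr0(intron_tbl$chrom, intron_tbl$s, intron_tbl$e, intron_tbl$gene_id)
      } else GenomicRanges::GRanges()
    ),
    tss = tibble::tibble(gene_id = model$gene_id, chrom = model$chrom,
                         strand = model$strand, tss = model$tss)
  ), class = "feature_index")
}

#' Annotate sites or tiles with a genomic category and nearest gene
#'
#' Each record is annotated by its midpoint base: the first category in the
#' precedence order promoter > TTS > 5'UTR > 3'UTR > exon > intron whose
#' intervals contain the midpoint wins (ties within a category go to the
#' gene with the nearest TSS); a midpoint overlapping nothing is
#' `intergenic` and gets the nearest gene by TSS distance. `distance_to_tss`
#' is signed in transcript orientation (positive downstream of the TSS).
#' Genes attached to intergenic records are flagged `gene_excluded = TRUE`
#' and should be dropped from downstream gene sets.
#'
#' @param sites Tibble with `chrom, start, end` (other columns pass through).
#' @param index A [build_feature_index()] result.
#' @return `sites` with `category` (factor over the 7 classes), `gene_id`,
#'   `distance_to_tss` and `gene_excluded` columns added.
#' @export
annotate_sites <- function(sites, index) {
  stopifnot(inherits(index, "feature_index"))
  n <- nrow(sites)
  mid <- (sites$start + sites$end) %/% 2L            # 0-based midpoint base
  cats <- c(names(index$categories), "intergenic")
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)

  known_chroms <- unique(index$tss$chrom)
  off_model <- !sites$chrom %in% known_chroms
  for (ch in unique(sites$chrom[off_model])) {
    warnf("chromosome %s absent from the gene model; sites set intergenic", ch)
  }

  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  tss_by_gene <- stats::setNames(index$tss$tss, index$tss$gene_id)
  for (cat in names(index$categories)) {
    open <- is.na(category)
    if (!any(open)) break
    gr <- index$categories[[cat]]
    if (length(gr) == 0) next
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q[open], gr))
    if (length(hits) == 0) next
    qh <- which(open)[S4Vectors::queryHits(hits)]
    genes <- S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)]
    d <- abs(mid[qh] - tss_by_gene[genes])
    best <- tapply(seq_along(qh), qh, function(ii) ii[which.min(d[ii])])
    pick <- unlist(best)
    category[qh[pick]] <- cat
    gene_id[qh[pick]] <- genes[pick]
  }

  open <- is.na(category)
  if (any(open)) {
    category[open] <- "intergenic"
    for (i in which(open)) {
      same <- index$tss$chrom == sites$chrom[i]
      if (!any(same)) next
      j <- which(same)[which.min(abs(mid[i] - index$tss$tss[same]))]
      gene_id[i] <- index$tss$gene_id[j]
    }
  }

  tss <- tss_by_gene[gene_id]
  strand_of <- stats::setNames(index$tss$strand, index$tss$gene_id)[gene_id]
  dist <- ifelse(strand_of == "+", mid - tss, tss - mid)
  out <- sites
  out$category <- factor(category, levels = cats)
  out$gene_id <- gene_id
  out$distance_to_tss <- as.integer(dist)
  out$gene_excluded <- out$category == "intergenic"
  out
}

#' Genomic category distribution of annotated DMS
#'
#' Fraction of sites in each of the 7 categories, reported separately for
#' hyper- and hypo-methylated sets when a `direction` column is present
#' (`ns` records are dropped).
#'
#' @param annotated Output of [annotate_sites()].
#' @return Tibble with `direction` (if available), `category`, `n`,
#'   `fraction`; fractions sum to 1 within each direction.
#' @export
category_distribution <- function(annotated) {
  if (nrow(annotated) == 0) stopf("category_distribution: empty input")
  if ("direction" %in% names(annotated)) {
    x <- dplyr::filter(annotated, .data$direction != "ns")
    x$direction <- droplevels(factor(x$direction))
    out <- dplyr::count(x, .data$direction, .data$category,
                        .drop = FALSE, name = "n")
    out <- dplyr::mutate(dplyr::group_by(out, .data$direction),
                         fraction = .data$n / sum(.data$n))
    dplyr::ungroup(out)
  } else {
    out <- dplyr::count(annotated, .data$category, .drop = FALSE, name = "n")
    dplyr::mutate(out, fraction = .data$n / sum(.data$n))
  }
}
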