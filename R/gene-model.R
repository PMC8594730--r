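# Gene models are held as a transcript-level tibble with 0-based half-open
# coordinates: gene_id, transcript_id, chrom, strand, start, end plus
# list-columns exon_starts/exon_ends and (possibly empty) utr5_* / utr3_*
# interval lists. TSS is the strand-aware first transcribed base, TTS the
# last.

new_gene_model <- function(tbl) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends", "utr5_starts", "utr5_ends",
            "utr3_starts", "utr3_ends")
  stopifnot(all(need %in% names(tbl)))
  n_ex <- lengths(tbl$exon_starts)
  if (any(n_ex == 0)) {
    warnf("dropping %d transcript(s) with zero exons", sum(n_ex == 0))
    tbl <- tbl[n_ex > 0, ]
  }
  tbl <- dplyr::mutate(tbl,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tts = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
  )
  structure(tibble::as_tibble(tbl), class = c("gene_model", class(tbl)))
}

#' Read a gene model from GTF/GFF3 or BED12
#'
#' GTF/GFF3 files are parsed with `rtracklayer`; exons are grouped per
#' transcript and 5'/3' UTRs derived from the CDS span (non-coding
#' transcripts get empty UTRs). BED12 files use the block structure as exons
#' and the thick region as CDS. Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path File path; format inferred from the extension (`.gtf`, `.gff`,
#'   `.gff3`, `.bed`) unless given.
#' @param format `"auto"`, `"gtf"`, `"gff3"` or `"bed12"`.
#' @return A `gene_model` tibble (one row per transcript).
#' @export
read_gene_model <- function(path, format = c("auto", "gtf", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed12", stopf("cannot infer gene model format from '%s'", ext))
  }
  if (format == "bed12") return(read_gene_model_bed12(path))
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  tx_id <- as.character(md$transcript_id %||% md$Parent)
  gene_id <- as.character(md$gene_id %||% md$gene %||% tx_id)
  keep <- md$type %in% c("exon", "CDS")
  df <- tibble::tibble(
    type = as.character(md$type[keep]),
    transcript_id = tx_id[keep],
    gene_id = gene_id[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,   # to 0-based
    end = GenomicRanges::end(gr)[keep]
  )
  build_model_from_parts(df)
}

read_gene_model_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  thick <- S4Vectors::mcols(gr)$thick
  rows <- lapply(seq_along(gr), function(i) {
    tx_start <- GenomicRanges::start(gr)[i] - 1L
    bl <- blocks[[i]]
    ex_s <- tx_start + IRanges::start(bl) - 1L
    ex_e <- tx_start + IRanges::end(bl)
    cds_s <- IRanges::start(thick)[i] - 1L
    cds_e <- IRanges::end(thick)[i]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    name <- S4Vectors::mcols(gr)$name[i] %||% paste0("tx", i)
    utr <- split_utrs(ex_s, ex_e, cds_s, cds_e, strand)
    tibble::tibble(
      gene_id = name, transcript_id = name,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = strand, start = tx_start,
      end = GenomicRanges::end(gr)[i],
      exon_starts = list(ex_s), exon_ends = list(ex_e),
      utr5_starts = list(utr$u5s), utr5_ends = list(utr$u5e),
      utr3_starts = list(utr$u3s), utr3_ends = list(utr$u3e)
    )
  })
  new_gene_model(dplyr::bind_rows(rows))
}

build_model_from_parts <- function(df) {
  rows <- lapply(split(df, df$transcript_id), function(tx) {
    ex <- tx[tx$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) == 0) {
      warnf("transcript %s has zero exons; skipped", tx$transcript_id[1])
      return(NULL)
    }
    cds <- tx[tx$type == "CDS", ]
    strand <- ex$strand[1]
    cds_s <- if (nrow(cds)) min(cds$start) else NA_integer_
    cds_e <- if (nrow(cds)) max(cds$end) else NA_integer_
    utr <- split_utrs(ex$start, ex$end, cds_s, cds_e, strand)
    tibble::tibble(
      gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
      chrom = ex$chrom[1], strand = strand,
      start = min(ex$start), end = max(ex$end),
      exon_starts = list(ex$start), exon_ends = list(ex$end),
      utr5_starts = list(utr$u5s), utr5_ends = list(utr$u5e),
      utr3_starts = list(utr$u3s), utr3_ends = list(utr$u3e)
    )
  })
  new_gene_model(dplyr::bind_rows(rows))
}

# exonic sequence outside the CDS span, split into the 5' and 3' sides in
# transcript orientation; all coordinates 0-based half-open
split_utrs <- function(ex_s, ex_e, cds_s, cds_e, strand) {
  none <- list(u5s = integer(0), u5e = integer(0),
               u3s = integer(0), u3e = integer(0))
  if (is.na(cds_s) || cds_e <= cds_s) return(none)
  up_s <- ex_s; up_e <- pmin(ex_e, cds_s)          # exon bp left of the CDS
  keep_up <- up_e > up_s
  dn_s <- pmax(ex_s, cds_e); dn_e <- ex_e          # exon bp right of the CDS
  keep_dn <- dn_e > dn_s
  left <- list(s = up_s[keep_up], e = up_e[keep_up])
  right <- list(s = dn_s[keep_dn], e = dn_e[keep_dn])
  if (strand == "+") {
    list(u5s = left$s, u5e = left$e, u3s = right$s, u3e = right$e)
  } else {
    list(u5s = right$s, u5e = right$e, u3s = left$s, u3e = left$e)
  }
}

#' Generate a random toy gene model
#'
#' Places `n_genes` multi-exon transcripts (random strand, 1–5 exons, a CDS
#' spanning the interior exon sequence) non-overlappingly along one
#' chromosome. Used to exercise annotation logic against brute-force oracles
#' and to give simulated DMS a gene context; it does not emulate real gene
#' architecture.
#'
#' @param n_genes Number of transcripts.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param seed Integer seed.
#' @return A `gene_model` tibble.
#' @export
random_gene_model <- function(n_genes = 20, chrom = "chr1",
                              chrom_length = 1e6, seed = 1) {
  withr::with_seed(seed, {
    slot <- floor(chrom_length / n_genes)
    rows <- lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(1:5, 1)
      ex_len <- sample(100:300, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(200:1000, n_ex - 1, replace = TRUE) else integer(0)
      g_start <- (i - 1) * slot + sample(2500:4000, 1)
      ex_s <- g_start + cumsum(c(0, ex_len[-n_ex] + gaps))
      ex_e <- ex_s + ex_len
      strand <- sample(c("+", "-"), 1)
      tx_len <- sum(ex_len)
      # CDS covers the middle ~60% of the exonic sequence when long enough
      cds <- if (tx_len >= 150) {
        trim <- floor(tx_len * 0.2)
        genomic_from_tx(ex_s, ex_e, trim, tx_len - trim)
      } else c(NA_integer_, NA_integer_)
      utr <- split_utrs(ex_s, ex_e, cds[1], cds[2], strand)
      tibble::tibble(
        gene_id = sprintf("gene%03d", i), transcript_id = sprintf("tx%03d", i),
        chrom = chrom, strand = strand, start = min(ex_s), end = max(ex_e),
        exon_starts = list(ex_s), exon_ends = list(ex_e),
        utr5_starts = list(utr$u5s), utr5_ends = list(utr$u5e),
        utr3_starts = list(utr$u3s), utr3_ends = list(utr$u3e)
      )
    })
    new_gene_model(dplyr::bind_rows(rows))
  })
}

# genomic span corresponding to transcript-coordinate interval [a, b)
# (orientation-agnostic: measured along the + strand exon chain)
genomic_from_tx <- function(ex_s, ex_e, a, b) {
  lens <- ex_e - ex_s
  offs <- cumsum(c(0, lens[-length(lens)]))
  pos_of <- function(t) {
    i <- max(which(offs <= t))
    ex_s[i] + (t - offs[i])
  }
  c(pos_of(a), pos_of(b - 1) + 1L)
}
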