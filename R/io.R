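#' Read a per-CpG methylation count file
#'
#' Parses one sample's cytosine report into a tibble of per-site methylated /
#' unmethylated read counts. Two dialects are supported:
#'
#' * `"bismark_cov"`: tab-separated `chrom, start, end, percent_methylation,
#'   count_methylated, count_unmethylated` with 1-based `start == end` per
#'   CpG and no header (the bismark coverage format).
#' * `"methylkit_text"`: tab-separated with header
#'   `chrBase chr base strand coverage freqC freqT` (methylKit's raw text
#'   format); strand `F`/`R` is mapped to `+`/`-`.
#'
#' Counts are the primary data: the percent-methylation column is recomputed
#' from the counts and only validated against the file (a mismatch beyond 0.1
#' raises a warning). Coordinates are converted to the package-internal
#' 0-based half-open convention (`end = start + 1` per CpG).
#'
#' @param path Path to the count file.
#' @param dialect `"bismark_cov"` (default) or `"methylkit_text"`.
#' @param sample_id Optional sample id attached as a column; defaults to the
#'   file name without extension.
#' @return A tibble with columns `sample_id, chrom, start, end, strand,
#'   methylated, unmethylated, coverage`, sorted by `(chrom, start)`.
#' @export
read_count_file <- function(path, dialect = c("bismark_cov", "methylkit_text"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("count file not found: %s", path)
  sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))

  if (dialect == "bismark_cov") {
    raw <- suppressWarnings(readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "pct", "methylated", "unmethylated"),
      col_types = "ciidii", progress = FALSE
    ))
    check_parse_problems(raw, path)
    if (nrow(raw) == 0) return(empty_counts(sample_id))
    tbl <- tibble::tibble(
      sample_id = sample_id,
      chrom = raw$chrom,
      start = to_zero_based(raw$start),
      end = raw$end,           # 1-based inclusive end == 0-based half-open end
      strand = "unknown",
      methylated = raw$methylated,
      unmethylated = raw$unmethylated
    )
    validate_percent_column(raw$pct, tbl$methylated, tbl$unmethylated, path)
  } else {
    raw <- suppressWarnings(readr::read_tsv(path, col_types = "ccicidd",
                                            progress = FALSE))
    check_parse_problems(raw, path)
    need <- c("chr", "base", "strand", "coverage", "freqC")
    if (!all(need %in% names(raw))) {
      stopf("%s: missing methylKit columns: %s", path,
            paste(setdiff(need, names(raw)), collapse = ", "))
    }
    if (nrow(raw) == 0) return(empty_counts(sample_id))
    meth <- as.integer(round(raw$coverage * raw$freqC / 100))
    tbl <- tibble::tibble(
      sample_id = sample_id,
      chrom = raw$chr,
      start = to_zero_based(raw$base),
      end = raw$base,
      strand = dplyr::case_match(raw$strand, "F" ~ "+", "R" ~ "-",
                                 "+" ~ "+", "-" ~ "-", .default = "unknown"),
      methylated = meth,
      unmethylated = raw$coverage - meth
    )
  }

  if (any(tbl$methylated < 0 | tbl$unmethylated < 0)) {
    stopf("%s: negative counts", path)
  }
  tbl$coverage <- tbl$methylated + tbl$unmethylated
  dplyr::arrange(tbl, .data$chrom, .data$start)
}

check_parse_problems <- function(raw, path) {
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stopf("%s: malformed line %d (%s)", path, probs$row[1], probs$expected[1])
  }
}

validate_percent_column <- function(pct, m, u, path) {
  cov <- m + u
  ok <- cov == 0 | abs(pct - 100 * m / pmax(cov, 1)) <= 0.1
  if (!all(ok)) {
    warnf("%s: %d rows where the percent column disagrees with the counts by > 0.1; counts are used",
          path, sum(!ok))
  }
  invisible(NULL)
}

empty_counts <- function(sample_id = character()) {
  tibble::tibble(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), methylated = integer(),
    unmethylated = integer(), coverage = integer()
  )
}

#' Write a per-CpG count file in bismark coverage format
#'
#' Inverse of [read_count_file()] for the `bismark_cov` dialect; internal
#' 0-based half-open coordinates are converted back to 1-based inclusive.
#'
#' @param counts Count tibble for a single sample (as from
#'   [read_count_file()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_file <- function(counts, path) {
  stopifnot(length(unique(counts$sample_id)) <= 1)
  cov <- counts$methylated + counts$unmethylated
  out <- tibble::tibble(
    chrom = counts$chrom,
    start = to_one_based(counts$start),
    end = counts$end,
    pct = ifelse(cov > 0, 100 * counts$methylated / cov, 0),
    methylated = counts$methylated,
    unmethylated = counts$unmethylated
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet assigns each sperm sample to a generation and an exposure
#' group. Expected CSV columns: `sample_id, generation, group` and optionally
#' `file_path`. The default study design has 6 exposed and 6 control animals
#' in each of F1, F2 and F3; unbalanced designs are accepted with a warning
#' (the permutation engine requires at least 2 samples per cell).
#'
#' @param path CSV file path.
#' @param generations Allowed generation labels.
#' @param groups Allowed group labels.
#' @return A validated tibble with columns `sample_id, generation, group`
#'   (factors with the given levels) and `file_path` (possibly `NA`).
#' @export
read_sample_sheet <- function(path, generations = c("F1", "F2", "F3"),
                              groups = c("control", "exposed")) {
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_sample_sheet(sheet, generations, groups)
}

#' Validate an in-memory sample sheet
#'
#' @param sheet A data frame with `sample_id`, `generation`, `group`.
#' @inheritParams read_sample_sheet
#' @return The validated sheet as a tibble.
#' @export
validate_sample_sheet <- function(sheet, generations = c("F1", "F2", "F3"),
                                  groups = c("control", "exposed")) {
  need <- c("sample_id", "generation", "group")
  if (!all(need %in% names(sheet))) {
    stopf("sample sheet missing columns: %s",
          paste(setdiff(need, names(sheet)), collapse = ", "))
  }
  sheet <- tibble::as_tibble(sheet)
  if (anyDuplicated(sheet$sample_id)) {
    stopf("duplicated sample_id: %s",
          paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                collapse = ", "))
  }
  bad_gen <- setdiff(unique(sheet$generation), generations)
  if (length(bad_gen)) stopf("unknown generation token: %s",
                             paste(bad_gen, collapse = ", "))
  bad_grp <- setdiff(unique(sheet$group), groups)
  if (length(bad_grp)) stopf("unknown group token: %s",
                             paste(bad_grp, collapse = ", "))
  cells <- dplyr::count(sheet, .data$generation, .data$group)
  full <- tidyr::expand_grid(generation = generations, group = groups)
  missing <- dplyr::anti_join(full, cells, by = c("generation", "group"))
  if (nrow(missing) > 0) {
    stopf("empty design cell: %s",
          paste(missing$generation, missing$group, collapse = "; "))
  }
  if (length(unique(cells$n)) > 1) {
    warnf("unbalanced design: cell sizes %s",
          paste(sprintf("%s/%s=%d", cells$generation, cells$group, cells$n),
                collapse = ", "))
  }
  if (!"file_path" %in% names(sheet)) sheet$file_path <- NA_character_
  sheet$generation <- factor(sheet$generation, levels = generations)
  sheet$group <- factor(sheet$group, levels = groups)
  sheet
}

#' Read all count files listed in a sample sheet
#'
#' @param sheet Sample sheet tibble with a `file_path` column.
#' @param dialect Count-file dialect, see [read_count_file()].
#' @param base_dir Directory that relative `file_path` entries are resolved
#'   against.
#' @return One long count tibble covering all samples.
#' @export
read_counts_for_sheet <- function(sheet, dialect = "bismark_cov",
                                  base_dir = ".") {
  stopifnot(all(!is.na(sheet$file_path)))
  purrr::map2_dfr(sheet$file_path, sheet$sample_id, function(fp, sid) {
    if (!file.exists(fp)) fp <- file.path(base_dir, fp)
    read_count_file(fp, dialect = dialect, sample_id = sid)
  })
}

#' Write called DMS to a BED file
#'
#' Emits one BED6 line per differentially methylated site/tile: 0-based
#' half-open coordinates, `name` = direction, `score` =
#' `min(1000, round(-100 * log10(q)))`, strand `.`. Records with
#' `direction == "ns"` are dropped.
#'
#' @param dms DMS tibble with `chrom, start, end, q_value, direction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dms_bed <- function(dms, path) {
  dms <- dplyr::filter(dms, .data$direction != "ns")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track name=dms description=\"differentially methylated sites\"", con)
  if (nrow(dms) > 0) {
    score <- pmin(1000, round(-100 * log10(pmax(dms$q_value, 1e-10))))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                     dms$chrom, dms$start, dms$end,
                     as.character(dms$direction), as.integer(score))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a DMS BED file written by [write_dms_bed()]
#'
#' @param path BED file path.
#' @return Tibble with `chrom, start, end, direction, score`.
#' @export
read_dms_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          score = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = purrr::map_chr(parts, 1),
    start = as.integer(purrr::map_chr(parts, 2)),
    end = as.integer(purrr::map_chr(parts, 3)),
    direction = purrr::map_chr(parts, 4),
    score = as.integer(purrr::map_chr(parts, 5))
  )
}
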