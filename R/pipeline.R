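#' Assemble a pipeline configuration
#'
#' One object drives the full analysis: simulate (or read) counts, filter and
#' tile, test each generation, call DMS, annotate, intersect across
#' generations and run the permutation test. A single global seed derives the
#' per-stage seeds (`stage_seed = (global * 101 + stage_index) mod 2^31 - 1`)
#' so individual stages can be re-run reproducibly.
#'
#' @param out_dir Output directory for stage files.
#' @param sim A [sim_config()] to simulate input data, or `NULL` to read
#'   counts from `sheet_path`.
#' @param sheet_path,dialect Sample sheet CSV (with `file_path` column) and
#'   count-file dialect, used when `sim` is `NULL`.
#' @param filter A [filter_config()].
#' @param preset A [stringency_preset()].
#' @param plan A [permutation_plan()], or `NULL` to skip the permutation
#'   stage.
#' @param gene_model_path Optional gene model (GTF/GFF3/BED12) for the
#'   annotation stage.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            sheet_path = NULL,
                            dialect = "bismark_cov",
                            filter = filter_config(),
                            preset = stringency_preset("COV10_Met20"),
                            plan = permutation_plan(n_permutations = 199),
                            gene_model_path = NULL,
                            seed = 1L) {
  if (is.null(sim) && is.null(sheet_path)) {
    stopf("pipeline_config: provide either `sim` or `sheet_path`")
  }
  if (!is.null(sheet_path) && !file.exists(sheet_path)) {
    stopf("sample sheet not found: %s", sheet_path)
  }
  if (!is.null(gene_model_path) && !file.exists(gene_model_path)) {
    stopf("gene model not found: %s", gene_model_path)
  }
  structure(list(out_dir = out_dir, sim = sim, sheet_path = sheet_path,
                 dialect = dialect, filter = filter, preset = preset,
                 plan = plan, gene_model_path = gene_model_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(global, k) {
  as.integer((as.numeric(global) * 101 + k) %% (2^31 - 1))
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]. Recognised top-level keys:
#' `out_dir`, `seed`, `sheet_path`, `dialect`, `gene_model_path`, and the
#' nested blocks `sim` (fields of [sim_config()]), `filter` (fields of
#' [filter_config()]), `preset` (name or fields of [stringency_preset()])
#' and `plan` (fields of [permutation_plan()]; `plan: null` skips the
#' permutation stage). Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  args <- list(
    out_dir = resolve(y$out_dir %||% stopf("config needs out_dir")),
    sheet_path = resolve(y$sheet_path),
    dialect = y$dialect %||% "bismark_cov",
    gene_model_path = resolve(y$gene_model_path),
    seed = y$seed %||% 1L
  )
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$preset)) {
    args$preset <- if (is.character(y$preset)) stringency_preset(y$preset)
                   else do.call(stringency_preset, y$preset)
  }
  if ("plan" %in% names(y)) {
    # args["plan"] <- list(NULL) stores an explicit NULL (skip the stage)
    # where args$plan <- NULL would delete the element
    args["plan"] <- if (is.null(y$plan)) list(NULL)
                    else list(do.call(permutation_plan, y$plan))
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> preprocess -> diffmeth -> annotate -> inherit ->
#' permtest, writing every stage output under `out_dir` (per-generation
#' statistics TSV, DMS BED, conserved-site TSVs, Venn counts and permutation
#' JSON) plus `summary.json` and a `manifest.json` with file hashes. Re-runs
#' with the same configuration and seed are byte-identical. A stage failure
#' halts the run with the failing stage named; earlier outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  truth <- NULL
  input <- run_stage("input", {
    if (!is.null(config$sim)) {
      sc <- config$sim
      sc$seed <- stage_seed(config$seed, 1)
      sim <- simulate_dataset(sc)
      truth <- sim$truth
      readr::write_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"),
                       progress = FALSE)
      list(counts = sim$counts, sheet = sim$sheet, truth = sim$truth)
    } else {
      sheet <- read_sample_sheet(config$sheet_path)
      list(counts = read_counts_for_sheet(sheet, config$dialect,
                                          dirname(config$sheet_path)),
           sheet = sheet, truth = NULL)
    }
  })

  gens <- levels(input$sheet$generation)
  filtered <- run_stage("preprocess", filter_coverage(input$counts, config$filter))
  readr::write_tsv(coverage_filter_report(filtered),
                   file.path(config$out_dir, "filter_report.tsv"),
                   progress = FALSE)

  dms_by_gen <- list()
  for (g in gens) {
    run_stage(paste0("diffmeth_", g), {
      ids <- input$sheet$sample_id[input$sheet$generation == g]
      gc <- dplyr::filter(filtered, .data$sample_id %in% ids)
      tiles <- tile_counts(unite_samples(gc, config$filter), config$filter)
      stats <- diff_methylation(tiles, input$sheet)
      called <- call_dms(stats, config$preset)
      readr::write_tsv(called, file.path(config$out_dir,
                                         sprintf("dms_%s.tsv", g)),
                       progress = FALSE)
      write_dms_bed(called, file.path(config$out_dir,
                                      sprintf("dms_%s.bed", g)))
      dms_by_gen[[g]] <- called
    })
  }

  ann_summary <- NULL
  if (!is.null(config$gene_model_path)) {
    run_stage("annotate", {
      index <- build_feature_index(read_gene_model(config$gene_model_path))
      for (g in gens) {
        ann <- annotate_sites(dms_by_gen[[g]], index)
        readr::write_tsv(ann, file.path(config$out_dir,
                                        sprintf("annotated_%s.tsv", g)),
                         progress = FALSE)
        dms_by_gen[[g]] <- ann
      }
      sig <- dplyr::bind_rows(dms_by_gen, .id = "generation")
      sig <- dplyr::filter(sig, .data$direction != "ns")
      ann_summary <- if (nrow(sig)) category_distribution(sig) else NULL
    })
  }

  inherit <- run_stage("inherit", {
    chains <- if (!is.null(config$plan)) config$plan$statistic_chains
              else list(gens[1:2], gens)
    res <- list()
    for (chain in chains) {
      for (dirn in c("hyper", "hypo")) {
        cs <- conserved_sites(dms_by_gen, chain, dirn)
        nm <- paste0(paste(chain, collapse = "."), "|", dirn)
        res[[nm]] <- attr(cs, "count")
        readr::write_tsv(cs, file.path(config$out_dir,
          sprintf("conserved_%s_%s.tsv", paste(chain, collapse = "-"), dirn)),
          progress = FALSE)
      }
    }
    vc <- venn_counts(dms_by_gen, gens)
    jsonlite::write_json(vc, file.path(config$out_dir, "venn_counts.json"),
                         dataframe = "rows")
    res
  })

  perm <- NULL
  if (!is.null(config$plan)) {
    perm <- run_stage("permtest", {
      plan <- config$plan
      plan$seed <- stage_seed(config$seed, 2)
      pt <- run_permutation_test(input$counts, input$sheet, config$filter,
                                 config$preset, plan)
      readr::write_tsv(tibble::as_tibble(pt$null_counts),
                       file.path(config$out_dir, "null_counts.tsv"),
                       progress = FALSE)
      pt
    })
  }

  summary <- list(
    generations = gens,
    n_samples = nrow(input$sheet),
    dms_counts = lapply(dms_by_gen, function(d) {
      as.list(table(d$direction)[c("hyper", "hypo")])
    }),
    conserved = inherit,
    permutation = if (!is.null(perm)) {
      list(p_values = as.list(perm$p_value),
           n_permutations = perm$n_permutations,
           convergence = convergence(perm)$status)
    } else NULL,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest <- list(files = as.list(tools::md5sum(files)), seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage files of a [run_pipeline()] output directory and returns
#' (and prints) the per-generation DMS counts, the genomic category table if
#' annotation ran, the conserved counts, and the permutation p-values
#' (marked `"not computed"` when that stage was skipped). Missing stages are
#' listed.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return A list of summary tables, invisibly.
#' @export
report_run <- function(run_dir) {
  summary_path <- file.path(run_dir, "summary.json")
  if (!file.exists(summary_path)) stopf("incomplete run: missing summary.json")
  s <- jsonlite::read_json(summary_path)
  dms <- purrr::imap_dfr(s$dms_counts, function(x, g) {
    tibble::tibble(generation = g, hyper = x$hyper %||% 0L,
                   hypo = x$hypo %||% 0L)
  })
  conserved <- tibble::tibble(statistic = names(s$conserved),
                              conserved = unlist(s$conserved))
  perm <- if (length(s$permutation$p_values)) {
    tibble::tibble(statistic = names(s$permutation$p_values),
                   p_value = unlist(s$permutation$p_values),
                   convergence = s$permutation$convergence)
  } else "not computed"
  cat("DMS counts per generation:\n"); print(dms)
  cat("\nConserved DMS:\n"); print(conserved)
  cat("\nPermutation test:\n"); print(perm)
  missing <- setdiff(sprintf("dms_%s.tsv", unlist(s$generations)),
                     list.files(run_dir))
  if (length(missing)) cat("\nMissing stage files:",
                           paste(missing, collapse = ", "), "\n")
  invisible(list(dms = dms, conserved = conserved, permutation = perm))
}
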