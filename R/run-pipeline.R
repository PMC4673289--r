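#' Pipeline runners behind the command-line interface
#'
#' Each runner takes a flat configuration list (paths + thresholds,
#' all thresholds defaulting to the published design/screening values)
#' and writes its report files into `config$out_dir`. The thin
#' `sirnakit.R` script under `inst/scripts/` dispatches the `design`,
#' `scan`, `analyze` and `simulate` subcommands onto these functions.
#'
#' @param config named list. Common fields: `out_dir` (created if
#'   missing). `run_design`: `fasta`, `annotation`, `target_gene`,
#'   `top_k` (5), `run_threshold` (12), `gene_limit` (2).
#'   `run_scan`: `guide`, `fasta`, `annotation`, `run_threshold`,
#'   `gene_limit`, `exclude_gene`. `run_analyze`: `ct`, `viability`,
#'   `kd_min` (60), `kd_gap_min` (50), `viability_threshold` (0.80).
#'   `run_simulate`: `seed`, `n_transcripts`, `length_nt`, `n_pairs`,
#'   `guide`.
#' @return The report object, invisibly; files are written as a side
#'   effect.
#' @name runners
NULL

cfg <- function(config, key, default = NULL) {
  v <- config[[key]]
  if (is.null(v)) default else v
}

ensure_out <- function(config) {
  out <- cfg(config, "out_dir", ".")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' @rdname runners
#' @export
run_design <- function(config) {
  out <- ensure_out(config)
  tx <- load_transcriptome(config$fasta, config$annotation)
  report <- design_sirnas(tx, config$target_gene,
                          top_k = cfg(config, "top_k", 5L),
                          run_threshold = cfg(config, "run_threshold", 12L),
                          gene_limit = cfg(config, "gene_limit", 2L))
  message(sprintf("design: %d candidate(s) reported for %s",
                  nrow(report), config$target_gene))
  write_tsv(report, file.path(out, "design_report.tsv"))
  invisible(report)
}

#' @rdname runners
#' @export
run_scan <- function(config) {
  out <- ensure_out(config)
  tx <- load_transcriptome(config$fasta, config$annotation)
  g <- guide_strand(config$guide)
  res <- if (is_concrete(g)) {
    scan_guide(g, tx,
               run_threshold = cfg(config, "run_threshold", 12L),
               gene_limit = cfg(config, "gene_limit", 2L),
               exclude_gene = cfg(config, "exclude_gene"))
  } else {
    scan_pool(expand_pool(g), tx,
              run_threshold = cfg(config, "run_threshold", 12L),
              gene_limit = cfg(config, "gene_limit", 2L),
              exclude_gene = cfg(config, "exclude_gene"))
  }
  write_tsv(res$hits, file.path(out, "run_hits.tsv"))
  jsonlite::write_json(
    list(guide = unclass(res$guide$core),
         offtarget_genes = res$offtarget_genes,
         scf_count = res$scf_count,
         scf_fraction = res$scf_fraction,
         passes_gene_filter = res$passes_gene_filter,
         run_threshold = res$run_threshold,
         gene_limit = res$gene_limit),
    file.path(out, "scan_result.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' @rdname runners
#' @export
run_analyze <- function(config) {
  out <- ensure_out(config)
  ct <- utils::read.delim(config$ct)
  via <- utils::read.delim(config$viability)
  res <- analyze_screen(
    ct, via,
    kd_min = cfg(config, "kd_min", 60),
    kd_gap_min = cfg(config, "kd_gap_min", 50),
    viability_threshold = cfg(config, "viability_threshold", 0.80))
  write_tsv(res$records, file.path(out, "classification_report.tsv"))
  jsonlite::write_json(as.list(res$summary),
                       file.path(out, "classification_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("analyze: %s",
                  paste(names(res$summary), res$summary, sep = "=",
                        collapse = ", ")))
  invisible(res)
}

#' @rdname runners
#' @export
run_simulate <- function(config) {
  out <- ensure_out(config)
  seed <- as.integer(cfg(config, "seed", 1L))
  guide <- guide_strand(cfg(config, "guide", "ACCGUAUGAAGUACUUGGC"))
  fix <- gen_transcriptome(
    guide,
    n_transcripts = cfg(config, "n_transcripts", 5L),
    length_nt = cfg(config, "length_nt", 300L),
    plants = cfg(config, "plants", list()),
    seed = seed)
  write_transcriptome(fix$tx, file.path(out, "transcriptome.fasta"),
                      file.path(out, "annotation.tsv"))
  write_tsv(fix$manifest, file.path(out, "manifest.tsv"))
  assays <- gen_assay_tables(
    default_screen_plan(cfg(config, "n_pairs", 7L)), seed = seed)
  write_tsv(assays$ct, file.path(out, "ct_table.tsv"))
  write_tsv(assays$viability, file.path(out, "viability_table.tsv"))
  jsonlite::write_json(list(seed = seed,
                            guide = unclass(guide$core),
                            plants = nrow(fix$manifest),
                            n_pairs = nrow(assays$truth)),
                       file.path(out, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(transcriptome = fix, assays = assays))
}
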