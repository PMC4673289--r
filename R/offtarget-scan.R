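#' Longest complementary run between a guide and a transcript
#'
#' Finds the longest contiguous stretch of the transcript that is
#' Watson-Crick complementary, in antiparallel orientation, to a
#' contiguous stretch of the 19-nt guide core. Equivalent to the
#' longest common substring between the transcript and the guide's
#' reverse complement. G:U wobble pairs do not count; the dTdT
#' overhang is never scanned.
#'
#' @param guide concrete [guide_strand()] (no N; scan pool members
#'   individually for degenerate guides).
#' @param transcript_seq transcript sequence (string or [nuc_seq()],
#'   RNA; T is converted).
#' @return list with `run_length` (0 when no base pairs at all) and
#'   `positions`, the 1-based transcript start positions of every
#'   maximal-length run.
#' @export
longest_complementary_run <- function(guide, transcript_seq) {
  guide <- as_guide(guide)
  if (!is_concrete(guide))
    stop("guide must be concrete (no N); expand the pool first")
  tseq <- toupper(chartr("T", "U", as.character(transcript_seq)))
  tch <- strsplit(tseq, "")[[1L]]
  rc <- strsplit(unclass(reverse_complement(guide$core)), "")[[1L]]
  n <- length(tch)
  # run-length DP over the transcript, one vector pass per guide base
  prev <- integer(n)
  best <- 0L
  ends <- integer(0)
  for (j in seq_along(rc)) {
    hit <- tch == rc[j]
    cur <- integer(n)
    if (any(hit)) cur[hit] <- c(0L, prev)[which(hit)] + 1L
    mx <- if (any(hit)) max(cur) else 0L
    if (mx > best) {
      best <- mx
      ends <- which(cur == mx)
    } else if (mx == best && best > 0L) {
      ends <- union(ends, which(cur == mx))
    }
    prev <- cur
  }
  list(run_length = best,
       positions = if (best > 0L) sort(ends) - best + 1L else integer(0))
}

#' Scan a guide against a transcriptome for off-target liability
#'
#' Two liabilities are measured. (1) Complementary-run gene count: a
#' gene is an off-target liability when any of its transcripts carries
#' a complementary run strictly longer than `run_threshold` nt; the
#' guide passes the design filter when the number of such genes
#' (deduplicated by gene id, intended target included unless
#' `exclude_gene` is given) is strictly below `gene_limit`.
#' (2) Seed-complement frequency (SCF): the number of UTR-annotated
#' transcripts whose 3'UTR contains at least one exact occurrence of
#' the reverse complement of the guide seed (positions 2-8); multiple
#' occurrences in one UTR count once.
#'
#' @param guide concrete [guide_strand()].
#' @param tx a [transcriptome()].
#' @param run_threshold runs must exceed this length (nt) to count;
#'   default 12, i.e. runs of 13+ count.
#' @param gene_limit exclusive upper bound on liable genes; default 2,
#'   i.e. at most 1 gene (the intended target) may carry a run.
#' @param exclude_gene optional gene id (the intended target) left out
#'   of the gene count.
#' @return A `scan_result`: list with `guide`, `hits` (data.frame
#'   transcript_id/gene_id/run_length/transcript_position, one row per
#'   transcript with run_length >= 1), `offtarget_genes`, `scf_count`,
#'   `scf_fraction`, `passes_gene_filter`, `run_threshold`,
#'   `gene_limit`.
#' @export
scan_guide <- function(guide, tx, run_threshold = 12L, gene_limit = 2L,
                       exclude_gene = NULL) {
  guide <- as_guide(guide)
  if (!inherits(tx, "transcriptome")) stop("tx must be a transcriptome")
  if (length(tx) == 0L) stop("cannot scan an empty transcriptome")
  ann <- tx$annotation
  runs <- lapply(names(tx$sequences), function(id)
    longest_complementary_run(guide, tx$sequences[[id]]))
  run_len <- vapply(runs, `[[`, integer(1), "run_length")
  run_pos <- vapply(runs, function(r)
    if (r$run_length > 0L) r$positions[1L] else NA_integer_, integer(1))
  hits <- data.frame(transcript_id = ann$transcript_id,
                     gene_id = ann$gene_id,
                     run_length = run_len,
                     transcript_position = run_pos)[run_len >= 1L, ]
  rownames(hits) <- NULL

  liable <- unique(ann$gene_id[run_len > run_threshold])
  counted <- setdiff(liable, exclude_gene)

  seed_rc <- unclass(reverse_complement(seed_region(guide)))
  # degenerate seeds (sN templates) are scanned per pool member; an N
  # in the seed complement never matches a concrete transcript base
  has_utr <- !is.na(ann$utr3_start)
  scf_hit <- vapply(which(has_utr), function(i) {
    utr <- substr(tx$sequences[[i]], ann$utr3_start[i], ann$utr3_end[i])
    !grepl("N", seed_rc, fixed = TRUE) &&
      grepl(seed_rc, utr, fixed = TRUE)
  }, logical(1))
  scf_count <- sum(scf_hit)

  structure(list(guide = guide,
                 hits = hits,
                 offtarget_genes = sort(counted),
                 scf_count = scf_count,
                 scf_fraction = if (sum(has_utr)) scf_count / sum(has_utr)
                                else NA_real_,
                 passes_gene_filter = length(counted) < gene_limit,
                 run_threshold = as.integer(run_threshold),
                 gene_limit = as.integer(gene_limit)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(paste0("<scan_result: %d liable gene(s) (run > %d nt), ",
                     "SCF %d (%.3f), %s gene filter (< %d)>\n"),
              length(x$offtarget_genes), x$run_threshold, x$scf_count,
              x$scf_fraction, if (x$passes_gene_filter) "passes" else "fails",
              x$gene_limit))
  invisible(x)
}

#' Scan a degenerate pool against a transcriptome
#'
#' Conservative aggregation of per-member scans: liable genes are the
#' union over members, SCF is the maximum over members, and the gene
#' filter is evaluated on the union.
#'
#' @inheritParams scan_guide
#' @param pool a `degenerate_pool` from [expand_pool()].
#' @return A `scan_result` for the pool; `hits` rows carry the maximal
#'   run per transcript over members.
#' @export
scan_pool <- function(pool, tx, run_threshold = 12L, gene_limit = 2L,
                      exclude_gene = NULL) {
  if (!inherits(pool, "degenerate_pool") || length(pool$members) == 0L)
    stop("pool must be a non-empty degenerate_pool")
  scans <- lapply(pool$members, scan_guide, tx = tx,
                  run_threshold = run_threshold, gene_limit = gene_limit,
                  exclude_gene = exclude_gene)
  genes <- sort(unique(unlist(lapply(scans, `[[`, "offtarget_genes"))))
  scf_count <- max(vapply(scans, `[[`, integer(1), "scf_count"))
  n_utr <- sum(!is.na(tx$annotation$utr3_start))
  hits <- do.call(rbind, lapply(scans, `[[`, "hits"))
  if (nrow(hits)) {
    hits <- hits[order(hits$transcript_id, -hits$run_length), ]
    hits <- hits[!duplicated(hits$transcript_id), ]
    rownames(hits) <- NULL
  }
  structure(list(guide = pool$template,
                 hits = hits,
                 offtarget_genes = genes,
                 scf_count = scf_count,
                 scf_fraction = if (n_utr) scf_count / n_utr else NA_real_,
                 passes_gene_filter = length(genes) < gene_limit,
                 run_threshold = as.integer(run_threshold),
                 gene_limit = as.integer(gene_limit)),
            class = "scan_result")
}
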