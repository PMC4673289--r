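#' Enumerate Match candidates on a target transcript
#'
#' One candidate per 19-nt window of the transcript, excluding any
#' window that overlaps the annotated 3'UTR by even one base (the
#' 3'UTR is avoided as a target region). The guide is the reverse
#' complement of the window, in the RNA alphabet.
#'
#' @param tx a [transcriptome()].
#' @param transcript_id transcript to enumerate on.
#' @return data.frame with columns `transcript_id`, `gene_id`,
#'   `site_start`, `site_end` (1-based closed target coordinates) and
#'   `match` (guide core sequence). Zero rows (with a warning) when
#'   the transcript is shorter than 19 nt.
#' @export
enumerate_candidates <- function(tx, transcript_id) {
  r <- tx_record(tx, transcript_id)
  len <- nchar(r$sequence)
  empty <- data.frame(transcript_id = character(), gene_id = character(),
                      site_start = integer(), site_end = integer(),
                      match = character())
  if (len < 19L) {
    warning(sprintf("transcript %s is shorter than 19 nt", transcript_id))
    return(empty)
  }
  starts <- seq_len(len - 18L)
  if (!is.na(r$utr3_start)) {
    # keep windows with zero overlap: [s, s+18] disjoint from UTR
    keep <- (starts + 18L) < r$utr3_start | starts > r$utr3_end
    starts <- starts[keep]
  }
  if (length(starts) == 0L) return(empty)
  guides <- vapply(starts, function(s) {
    site <- nuc_seq(substr(r$sequence, s, s + 18L), "RNA")
    unclass(reverse_complement(site))
  }, character(1))
  data.frame(transcript_id = transcript_id, gene_id = r$gene_id,
             site_start = starts, site_end = starts + 18L,
             match = guides)
}

mismatch_candidates <- function(match) {
  ch <- guide_chars(match)
  bases <- c("A", "C", "G", "U")
  out <- list()
  for (pos in 9:11) {
    for (b in setdiff(bases, ch[pos])) {
      cc <- ch
      cc[pos] <- b
      out[[length(out) + 1L]] <-
        list(guide = guide_strand(paste(cc, collapse = "")),
             position = pos, base = b)
    }
  }
  out
}

#' Construct the Mismatch negative control for a Match guide
#'
#' Replaces exactly one nucleotide at guide position 9, 10 or 11 - the
#' central region whose substitution abolishes on-target cleavage - so
#' the control retains the Match guide's off-target signature while
#' losing its on-target effect. Among the 9 possible substitutions
#' (3 positions x 3 alternative bases) the one introducing the least
#' new off-target liability is chosen: fewest genes with qualifying
#' complementary runs, then lowest SCF, ties broken by lower position
#' then base order A < C < G < U.
#'
#' @param match concrete [guide_strand()].
#' @param tx [transcriptome()] scanned to score candidate
#'   substitutions, or `NULL` when no off-target context is available
#'   (all candidates then score equally and the tie-break picks
#'   position 9, base A when position 9 is not already A).
#' @param run_threshold,gene_limit,exclude_gene passed to
#'   [scan_guide()].
#' @param pin_position,pin_base optionally force the substitution
#'   (used to reproduce published designs).
#' @return list with `guide` (the Mismatch [guide_strand()]),
#'   `position` and `base`.
#' @export
make_mismatch <- function(match, tx = NULL, run_threshold = 12L,
                          gene_limit = 2L, exclude_gene = NULL,
                          pin_position = NULL, pin_base = NULL) {
  match <- as_guide(match)
  if (!is_concrete(match)) stop("Match guide must be concrete (no N)")
  cands <- mismatch_candidates(match)
  if (!is.null(pin_position))
    cands <- Filter(function(c) c$position == pin_position, cands)
  if (!is.null(pin_base))
    cands <- Filter(function(c) c$base == pin_base, cands)
  if (length(cands) == 0L)
    stop("pinned position/base does not yield a substitution")
  has_ctx <- !is.null(tx) && inherits(tx, "transcriptome") && length(tx) > 0L
  scores <- vapply(cands, function(c) {
    if (!has_ctx) return(c(0, 0))
    sc <- scan_guide(c$guide, tx, run_threshold = run_threshold,
                     gene_limit = gene_limit, exclude_gene = exclude_gene)
    c(length(sc$offtarget_genes), sc$scf_count)
  }, numeric(2))
  pos <- vapply(cands, `[[`, integer(1), "position")
  base_rank <- match(vapply(cands, `[[`, character(1), "base"),
                     c("A", "C", "G", "U"))
  best <- order(scores[1L, ], scores[2L, ], pos, base_rank)[1L]
  cands[[best]][c("guide", "position", "base")]
}

#' Degenerate guide variants: sN and dN
#'
#' `make_sN` substitutes the degenerate base N (an even mixture of the
#' four nucleotides) at guide position 2; `make_dN` at positions 2 and
#' 18. Expanding the variant ([expand_pool()]) yields a pool of 4 (sN)
#' or 16 (dN) concrete guides that dilutes seed-driven off-target
#' effects across pool members while each member retains the on-target
#' match outside the substituted positions.
#'
#' @param match concrete [guide_strand()].
#' @return A [guide_strand()] with N at the degenerate position(s).
#' @export
make_sN <- function(match) {
  match <- as_guide(match)
  if (!is_concrete(match)) stop("Match guide must be concrete (no N)")
  ch <- guide_chars(match)
  ch[2L] <- "N"
  guide_strand(paste(ch, collapse = ""))
}

#' @rdname make_sN
#' @export
make_dN <- function(match) {
  match <- as_guide(match)
  if (!is_concrete(match)) stop("Match guide must be concrete (no N)")
  ch <- guide_chars(match)
  ch[c(2L, 18L)] <- "N"
  guide_strand(paste(ch, collapse = ""))
}

#' Passenger strand of a guide
#'
#' Reverse complement of the 19-nt guide core with its own dTdT
#' overhang; duplex asymmetry optimization is out of scope.
#'
#' @param guide a [guide_strand()] (concrete).
#' @return A [guide_strand()] for the passenger strand.
#' @export
passenger_strand <- function(guide) {
  guide <- as_guide(guide)
  guide_strand(reverse_complement(guide$core))
}

#' Design siRNAs for a target gene
#'
#' Full design pipeline: enumerate non-3'UTR 19-nt windows on every
#' transcript of the target gene, scan each Match candidate against
#' the transcriptome (complementary-run gene count with the target
#' gene excluded, plus SCF), rank by (passes gene filter, ascending
#' SCF, ascending liable-gene count, position), and construct the
#' Mismatch, sN and dN variants for the top `top_k` candidates.
#'
#' @param tx a [transcriptome()].
#' @param target_gene gene id present in the annotation.
#' @param top_k number of designs to return (default 5).
#' @param run_threshold,gene_limit passed to [scan_guide()].
#' @return data.frame with columns `target_gene`, `transcript_id`,
#'   `site_start`, `site_end`, `match`, `mismatch`,
#'   `mismatch_position`, `sN`, `dN`, `offtarget_gene_count`, `scf`,
#'   `scf_fraction`, `passes_gene_filter`.
#' @export
design_sirnas <- function(tx, target_gene, top_k = 5L,
                          run_threshold = 12L, gene_limit = 2L) {
  if (!target_gene %in% tx$annotation$gene_id)
    stop(sprintf("unknown target gene '%s'; available: %s", target_gene,
                 paste(sort(unique(tx$annotation$gene_id)), collapse = ", ")))
  tids <- tx$annotation$transcript_id[tx$annotation$gene_id == target_gene]
  cands <- do.call(rbind, lapply(tids, function(id)
    suppressWarnings(enumerate_candidates(tx, id))))
  empty <- data.frame(target_gene = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      match = character(), mismatch = character(),
                      mismatch_position = integer(), sN = character(),
                      dN = character(), offtarget_gene_count = integer(),
                      scf = integer(), scf_fraction = numeric(),
                      passes_gene_filter = logical())
  if (is.null(cands) || nrow(cands) == 0L || top_k == 0L) return(empty)
  scans <- lapply(cands$match, function(m)
    scan_guide(guide_strand(m), tx, run_threshold = run_threshold,
               gene_limit = gene_limit, exclude_gene = target_gene))
  cands$offtarget_gene_count <-
    vapply(scans, function(s) length(s$offtarget_genes), integer(1))
  cands$scf <- vapply(scans, `[[`, integer(1), "scf_count")
  cands$scf_fraction <- vapply(scans, `[[`, numeric(1), "scf_fraction")
  cands$passes_gene_filter <- vapply(scans, `[[`, logical(1),
                                     "passes_gene_filter")
  ord <- order(!cands$passes_gene_filter, cands$scf,
               cands$offtarget_gene_count, cands$site_start)
  cands <- cands[ord, ][seq_len(min(top_k, nrow(cands))), ]
  rownames(cands) <- NULL

  mm <- lapply(cands$match, function(m)
    make_mismatch(guide_strand(m), tx, run_threshold = run_threshold,
                  gene_limit = gene_limit, exclude_gene = target_gene))
  cands$mismatch <- vapply(mm, function(x) unclass(x$guide$core), character(1))
  cands$mismatch_position <- vapply(mm, `[[`, integer(1), "position")
  cands$sN <- vapply(cands$match, function(m)
    unclass(make_sN(guide_strand(m))$core), character(1))
  cands$dN <- vapply(cands$match, function(m)
    unclass(make_dN(guide_strand(m))$core), character(1))
  cands$target_gene <- target_gene
  cands[, names(empty)]
}
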