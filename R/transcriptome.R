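#' Construct a transcriptome from sequences and annotation
#'
#' @param sequences named character vector (or `Biostrings` XStringSet)
#'   of mRNA sequences, names = transcript ids. DNA input (containing T)
#'   is converted to the RNA alphabet.
#' @param annotation data.frame with columns `transcript_id`, `gene_id`,
#'   `utr3_start`, `utr3_end`. UTR coordinates are 1-based closed
#'   transcript coordinates; `NA` in both means no 3'UTR annotation.
#' @return A `transcriptome` object: list with `sequences` (named
#'   character, RNA) and `annotation` (data.frame).
#' @export
transcriptome <- function(sequences, annotation) {
  if (inherits(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) == 0L) stop("transcriptome must be non-empty")
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("sequences must be named by transcript_id")
  sequences <- toupper(chartr("T", "U", sequences))
  need <- c("transcript_id", "gene_id", "utr3_start", "utr3_end")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  annotation <- as.data.frame(annotation)[, need]
  annotation$transcript_id <- as.character(annotation$transcript_id)
  annotation$gene_id <- as.character(annotation$gene_id)
  annotation$utr3_start <- as.integer(annotation$utr3_start)
  annotation$utr3_end <- as.integer(annotation$utr3_end)

  if (anyDuplicated(annotation$transcript_id)) {
    dup <- annotation$transcript_id[duplicated(annotation$transcript_id)]
    stop("duplicate transcript_id in annotation: ", dup[1L])
  }
  if (!setequal(names(sequences), annotation$transcript_id)) {
    off <- c(setdiff(names(sequences), annotation$transcript_id),
             setdiff(annotation$transcript_id, names(sequences)))
    stop("FASTA/annotation id mismatch for: ", paste(off, collapse = ", "))
  }
  annotation <- annotation[match(names(sequences), annotation$transcript_id), ]
  rownames(annotation) <- NULL

  len <- nchar(sequences)
  for (i in seq_len(nrow(annotation))) {
    s <- annotation$utr3_start[i]; e <- annotation$utr3_end[i]
    if (is.na(s) != is.na(e))
      stop("half-specified 3'UTR interval for ", annotation$transcript_id[i])
    if (!is.na(s) && (s < 1L || e < s || e > len[i]))
      stop(sprintf("malformed 3'UTR interval [%d,%d] for %s (length %d)",
                   s, e, annotation$transcript_id[i], len[i]))
  }
  bad <- grepl("[^ACGUN]", sequences)
  if (any(bad))
    stop("illegal residues in transcript ", names(sequences)[bad][1L])
  structure(list(sequences = sequences, annotation = annotation),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome: %d transcripts, %d genes, %d with 3'UTR>\n",
              length(x$sequences), length(unique(x$annotation$gene_id)),
              sum(!is.na(x$annotation$utr3_start))))
  invisible(x)
}

#' @export
length.transcriptome <- function(x) length(x$sequences)

tx_record <- function(tx, transcript_id) {
  i <- match(transcript_id, tx$annotation$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  list(transcript_id = transcript_id,
       gene_id = tx$annotation$gene_id[i],
       sequence = tx$sequences[[transcript_id]],
       utr3_start = tx$annotation$utr3_start[i],
       utr3_end = tx$annotation$utr3_end[i])
}

#' Load a transcriptome from FASTA + TSV annotation
#'
#' The annotation TSV has a header row with columns `transcript_id`,
#' `gene_id`, `utr3_start`, `utr3_end`; empty UTR fields mean no 3'UTR
#' annotation. Coordinates are 1-based closed, on the transcript.
#' FASTA sequences in the DNA alphabet are stored as RNA.
#'
#' @param fasta_path FASTA of transcript sequences (ids must match the
#'   annotation).
#' @param annotation_path TSV as above.
#' @return A [transcriptome()].
#' @export
load_transcriptome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           colClasses = c("character", "character",
                                          "integer", "integer"),
                           comment.char = "#")
  transcriptome(seqs, ann)
}

#' Write a transcriptome to FASTA + TSV annotation
#'
#' Inverse of [load_transcriptome()]; round-trips sequences and UTR
#' intervals exactly.
#'
#' @param tx a [transcriptome()].
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, `tx`.
#' @export
write_transcriptome <- function(tx, fasta_path, annotation_path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(tx$sequences),
                              fasta_path)
  utils::write.table(tx$annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(tx)
}

#' 3'UTR subsequence of a transcript
#'
#' @param tx a [transcriptome()].
#' @param transcript_id transcript to extract from.
#' @return RNA [nuc_seq()] of the annotated 3'UTR, or `NULL` when the
#'   transcript carries no UTR annotation.
#' @export
utr3_sequence <- function(tx, transcript_id) {
  r <- tx_record(tx, transcript_id)
  if (is.na(r$utr3_start)) return(NULL)
  nuc_seq(substr(r$sequence, r$utr3_start, r$utr3_end), "RNA")
}

#' Derive a 3'UTR annotation table from GFF3
#'
#' Maps `three_prime_UTR` features with genome coordinates equal to
#' transcript coordinates (i.e. a transcript-space GFF3) onto the
#' annotation columns used by [load_transcriptome()]. Multiple UTR
#' features per transcript are merged to their spanning interval.
#' Requires the rtracklayer package.
#'
#' @param gff3_path path to a GFF3 file whose seqnames are transcript
#'   ids and whose `three_prime_UTR` features carry a `gene_id`
#'   attribute.
#' @return data.frame with columns `transcript_id`, `gene_id`,
#'   `utr3_start`, `utr3_end`.
#' @export
utr3_from_gff3 <- function(gff3_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("utr3_from_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(gff3_path)
  gr <- gr[gr$type == "three_prime_UTR"]
  if (length(gr) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      utr3_start = integer(), utr3_end = integer()))
  d <- data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
                  gene_id = as.character(gr$gene_id),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr))
  out <- do.call(rbind, lapply(split(d, d$transcript_id), function(g) {
    data.frame(transcript_id = g$transcript_id[1L],
               gene_id = g$gene_id[1L],
               utr3_start = min(g$start), utr3_end = max(g$end))
  }))
  rownames(out) <- NULL
  out
}
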