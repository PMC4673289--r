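# Independent oracles and small generators used across the suite.
# Deliberately naive implementations, kept separate from the package's
# algorithms so they can serve as cross-checks.

# reverse complement by explicit character mapping (RNA)
oracle_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# longest common substring by substring enumeration + fixed grepl
oracle_lcs <- function(a, b) {
  for (L in seq(min(nchar(a), nchar(b)), 1L)) {
    starts <- 1:(nchar(b) - L + 1L)
    subs <- unique(substring(b, starts, starts + L - 1L))
    if (any(vapply(subs, grepl, logical(1), x = a, fixed = TRUE)))
      return(L)
  }
  0L
}

# longest complementary run oracle: LCS of transcript vs rc(guide core)
oracle_run <- function(guide_core, transcript) {
  oracle_lcs(transcript, oracle_revcomp(guide_core))
}

# brute-force count of 19-nt windows with zero 3'UTR overlap
oracle_window_count <- function(len, utr_start = NA, utr_end = NA) {
  if (len < 19L) return(0L)
  n <- 0L
  for (s in 1:(len - 18L)) {
    e <- s + 18L
    overlap <- !is.na(utr_start) && s <= utr_end && e >= utr_start
    if (!overlap) n <- n + 1L
  }
  n
}

# naive SCF: count UTR-annotated transcripts containing the 7-mer
oracle_scf <- function(seed7_rc, tx) {
  ann <- tx$annotation
  n <- 0L
  for (i in seq_len(nrow(ann))) {
    if (is.na(ann$utr3_start[i])) next
    utr <- substr(tx$sequences[[i]], ann$utr3_start[i], ann$utr3_end[i])
    if (grepl(seed7_rc, utr, fixed = TRUE)) n <- n + 1L
  }
  n
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_guide <- function() guide_strand(random_rna(19L))

# Table 1 worked sequences (19-nt guide cores, dTdT overhang implicit)
T1_MATCH_0N    <- "ACCGUAUGAAGUACUUGGC"
T1_MISMATCH_0N <- "ACCGUAUGAAAUACUUGGC"
T1_MATCH_SN    <- "ANCGUAUGAAGUACUUGGC"
T1_MATCH_DN    <- "ANCGUAUGAAGUACUUGNC"
T1_MISMATCH_SN <- "ANCGUAUGAAAUACUUGGC"
T1_MISMATCH_DN <- "ANCGUAUGAAAUACUUGNC"
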