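tx_single <- function(seq, utr3_start = NA, utr3_end = NA,
                      gene_id = "G1", transcript_id = "TX1") {
  transcriptome(stats::setNames(seq, transcript_id),
                data.frame(transcript_id = transcript_id, gene_id = gene_id,
                           utr3_start = utr3_start, utr3_end = utr3_end))
}

test_that("candidate enumeration avoids the 3'UTR entirely", {
  withr::with_seed(21, {
    s100 <- random_rna(100)
    tx <- tx_single(s100, 81, 100)
    cand <- enumerate_candidates(tx, "TX1")
    expect_equal(nrow(cand), 62L)  # windows 1..62 end at <= 80
    expect_equal(cand$site_start, 1:62)
    expect_equal(max(cand$site_end), 80L)

    # guide is the reverse complement of its window
    i <- 17
    site <- substr(s100, cand$site_start[i], cand$site_end[i])
    expect_identical(cand$match[i], oracle_revcomp(site))

    # UTR covering everything leaves no candidate
    expect_equal(nrow(enumerate_candidates(tx_single(s100, 1, 100), "TX1")),
                 0L)
    # no UTR annotation: every window
    expect_equal(nrow(enumerate_candidates(tx_single(s100), "TX1")),
                 100L - 18L)
    # shorter than a guide
    expect_warning(
      out <- enumerate_candidates(tx_single(random_rna(10)), "TX1"),
      "shorter")
    expect_equal(nrow(out), 0L)

    # brute-force window/interval intersection on random cases
    for (k in 1:20) {
      len <- sample(19:120, 1)
      us <- sample(c(NA, sample(len, 1)), 1)
      ue <- if (is.na(us)) NA else us + sample.int(len - us + 1L, 1L) - 1L
      txr <- tx_single(random_rna(len), us, ue)
      expect_equal(nrow(enumerate_candidates(txr, "TX1")),
                   oracle_window_count(len, us, ue))
    }
  })
})

test_that("Mismatch construction substitutes one base at positions 9-11", {
  g <- guide_strand(T1_MATCH_0N)
  # pinning reproduces the published worked design (G->A at 11)
  mm <- make_mismatch(g, pin_position = 11, pin_base = "A")
  expect_identical(unclass(mm$guide$core)[1], T1_MISMATCH_0N)
  expect_equal(mm$position, 11L)

  # postcondition holds for random guides with no off-target context
  withr::with_seed(31, {
    for (i in 1:25) {
      gr <- random_guide()
      m <- make_mismatch(gr)
      d <- diff_positions(gr, m$guide)
      expect_length(d, 1L)
      expect_true(d >= 9L && d <= 11L)
      expect_equal(d, m$position)
    }
  })

  # tie-break on no off-target signal: position 9, first base in
  # A<C<G<U order that differs from the current residue
  m9 <- make_mismatch(g)                # position 9 of the core is A
  expect_equal(m9$position, 9L)
  expect_equal(m9$base, "C")
  g2 <- guide_strand("ACCGUAUGGAGUACUUGGC")  # position 9 is G
  m9b <- make_mismatch(g2)
  expect_equal(m9b$position, 9L)
  expect_equal(m9b$base, "A")

  expect_error(make_mismatch(guide_strand(T1_MATCH_SN)), "concrete")
})

test_that("Mismatch selection avoids substitutions creating off-targets", {
  g <- guide_strand(T1_MATCH_0N)
  # decoy fully complementary to the position-9 C variant: choosing
  # that substitution would create a 19-nt run in a non-target gene
  bad <- make_mismatch(g, pin_position = 9, pin_base = "C")$guide
  decoy <- oracle_revcomp(unclass(bad$core)[1])
  tx <- withr::with_seed(61, transcriptome(
    c(TX1 = paste0(random_rna(40), decoy, random_rna(40))),
    data.frame(transcript_id = "TX1", gene_id = "GDECOY",
               utr3_start = NA, utr3_end = NA)))
  chosen <- make_mismatch(g, tx)
  expect_false(identical(unclass(chosen$guide$core)[1],
                         unclass(bad$core)[1]))
  expect_equal(length(scan_guide(chosen$guide, tx)$offtarget_genes), 0L)
  expect_equal(length(scan_guide(bad, tx)$offtarget_genes), 1L)
})

test_that("sN and dN variants place N at positions 2 and 2+18", {
  g <- guide_strand(T1_MATCH_0N)
  expect_identical(unclass(make_sN(g)$core)[1], T1_MATCH_SN)
  expect_identical(unclass(make_dN(g)$core)[1], T1_MATCH_DN)
  # applying the same rules to the Mismatch guide gives the paired
  # degenerate negative controls
  mm <- guide_strand(T1_MISMATCH_0N)
  expect_identical(unclass(make_sN(mm)$core)[1], T1_MISMATCH_SN)
  expect_identical(unclass(make_dN(mm)$core)[1], T1_MISMATCH_DN)
  # the Match guide is one concretization of its dN pool
  members <- vapply(expand_pool(make_dN(g))$members,
                    function(m) unclass(m$core)[1], character(1))
  expect_true(T1_MATCH_0N %in% members)
  # positions outside the degenerate ones are untouched
  withr::with_seed(41, {
    for (i in 1:15) {
      gr <- random_guide()
      expect_equal(diff_positions(gr, make_sN(gr)), 2L)
      expect_equal(diff_positions(gr, make_dN(gr)), c(2L, 18L))
    }
  })
})

test_that("passenger strand is the reverse complement of the guide core", {
  g <- guide_strand(T1_MATCH_0N)
  p <- passenger_strand(g)
  expect_identical(unclass(p$core)[1], oracle_revcomp(T1_MATCH_0N))
  expect_equal(p$overhang, "dTdT")
})

test_that("design_sirnas emits designs satisfying every invariant", {
  withr::with_seed(51, {
    fix <- gen_transcriptome(guide_strand(T1_MATCH_0N), n_transcripts = 3,
                             length_nt = 150, utr3_frac = 0.2, seed = 99)
    designs <- design_sirnas(fix$tx, "G1", top_k = 8)
    expect_gt(nrow(designs), 0L)
    for (i in seq_len(nrow(designs))) {
      m <- guide_strand(designs$match[i])
      site <- substr(fix$tx$sequences[["TX1"]], designs$site_start[i],
                     designs$site_end[i])
      expect_identical(unclass(m$core)[1], oracle_revcomp(site))
      d <- diff_positions(m, guide_strand(designs$mismatch[i]))
      expect_equal(d, designs$mismatch_position[i])
      expect_true(d >= 9 && d <= 11)
      expect_equal(diff_positions(m, guide_strand(designs$sN[i])), 2L)
      expect_equal(diff_positions(m, guide_strand(designs$dN[i])),
                   c(2L, 18L))
      # designed sites never overlap the 3'UTR
      expect_lt(designs$site_end[i],
                fix$tx$annotation$utr3_start[1])
    }
    expect_error(design_sirnas(fix$tx, "NOPE"), "unknown target gene.*G1")
    expect_equal(nrow(design_sirnas(fix$tx, "G1", top_k = 0)), 0L)
  })
})
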