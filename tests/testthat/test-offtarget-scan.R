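decoy_tx <- function(seqs, genes = paste0("G", seq_along(seqs)),
                     utr3_start = NA, utr3_end = NA) {
  n <- length(seqs)
  transcriptome(stats::setNames(seqs, paste0("TX", seq_len(n))),
                data.frame(transcript_id = paste0("TX", seq_len(n)),
                           gene_id = genes,
                           utr3_start = rep_len(utr3_start, n),
                           utr3_end = rep_len(utr3_end, n)))
}

test_that("longest complementary run agrees with the substring oracle", {
  withr::with_seed(71, {
    g <- random_guide()
    target <- paste0(random_rna(30), oracle_revcomp(unclass(g$core)[1]),
                     random_rna(30))
    expect_equal(longest_complementary_run(g, target)$run_length, 19L)
    expect_equal(longest_complementary_run(g, target)$positions, 31L)

    # no complementary base at all: poly-A transcript vs U-free guide
    gc_guide <- guide_strand(paste(rep(c("G", "C"), 10)[1:19],
                                   collapse = ""))
    expect_equal(
      longest_complementary_run(gc_guide,
                                paste(rep("A", 50), collapse = ""))$run_length,
      0L)

    # random pairs against the brute-force oracle
    for (i in 1:200) {
      gr <- random_guide()
      t <- random_rna(sample(19:120, 1))
      got <- longest_complementary_run(gr, t)
      expect_equal(got$run_length,
                   oracle_run(unclass(gr$core)[1], t))
      if (got$run_length > 0) {
        # every reported position really carries a maximal run
        rc <- oracle_revcomp(unclass(gr$core)[1])
        for (p in got$positions) {
          frag <- substr(t, p, p + got$run_length - 1L)
          expect_true(grepl(frag, rc, fixed = TRUE))
        }
      }
    }
  })
  expect_error(longest_complementary_run(guide_strand(T1_MATCH_SN), "ACGU"),
               "concrete")
})

test_that("planted runs are located exactly where the manifest says", {
  g <- guide_strand(T1_MATCH_0N)
  fix <- gen_transcriptome(g, n_transcripts = 3, length_nt = 200,
                           plants = list(list(kind = "complementary_run",
                                              transcript = 2, length = 13,
                                              guide_start = 4)),
                           seed = 8)
  r <- longest_complementary_run(g, fix$tx$sequences[["TX2"]])
  expect_equal(r$run_length, 13L)
  expect_equal(r$positions, fix$manifest$position[1])
})

test_that("gene filter: runs must exceed 12 nt and genes stay below 2", {
  g <- guide_strand(T1_MATCH_0N)
  plant <- function(lens, seed = 13) {
    gen_transcriptome(g, n_transcripts = length(lens) + 1, length_nt = 250,
                      plants = lapply(seq_along(lens), function(i)
                        list(kind = "complementary_run", transcript = i,
                             length = lens[i])),
                      seed = seed)$tx
  }
  # a 12-nt complement is NOT more than 12 consecutive basepairs
  s12 <- scan_guide(g, plant(12))
  expect_equal(length(s12$offtarget_genes), 0L)
  expect_true(s12$passes_gene_filter)
  # 13 nt is
  s13 <- scan_guide(g, plant(13))
  expect_equal(length(s13$offtarget_genes), 1L)
  expect_true(s13$passes_gene_filter)   # 1 < 2
  # two liable genes fail the "less than 2 genes" rule
  s2 <- scan_guide(g, plant(c(13, 14)))
  expect_equal(length(s2$offtarget_genes), 2L)
  expect_false(s2$passes_gene_filter)
  # excluding the intended target counts only unintended genes
  sx <- scan_guide(g, plant(c(13, 14)), exclude_gene = "G1")
  expect_equal(length(sx$offtarget_genes), 1L)
  expect_true(sx$passes_gene_filter)

  # gene-level deduplication: two transcripts of one gene, one liability
  two_iso <- transcriptome(
    stats::setNames(
      rep(paste0(strrep("A", 50),
                 oracle_revcomp(substr(T1_MATCH_0N, 3, 17)),
                 strrep("A", 50)), 2),
      c("TXa", "TXb")),
    data.frame(transcript_id = c("TXa", "TXb"), gene_id = "GX",
               utr3_start = NA, utr3_end = NA))
  expect_equal(scan_guide(g, two_iso)$offtarget_genes, "GX")

  # monotonicity: raising the run threshold never adds genes
  tx3 <- plant(c(13, 14, 15))
  sizes <- vapply(10:16, function(th)
    length(scan_guide(g, tx3, run_threshold = th)$offtarget_genes),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("SCF counts UTR-annotated transcripts bearing the seed complement",
{
  g <- guide_strand(T1_MATCH_0N)
  fix <- gen_transcriptome(
    g, n_transcripts = 6, length_nt = 300, utr3_frac = 0.3,
    plants = list(list(kind = "seed_match", transcript = 2),
                  list(kind = "seed_match", transcript = 5)),
    seed = 17)
  s <- scan_guide(g, fix$tx)
  seed_rc <- oracle_revcomp(substr(T1_MATCH_0N, 2, 8))
  expect_equal(s$scf_count, oracle_scf(seed_rc, fix$tx))
  expect_gte(s$scf_count, 2L)
  expect_equal(s$scf_fraction, s$scf_count / 6)
  expect_true(s$scf_fraction >= 0 && s$scf_fraction <= 1)

  # random fixtures: SCF equals the naive oracle
  withr::with_seed(77, {
    for (i in 1:10) {
      gr <- random_guide()
      txr <- decoy_tx(replicate(4, random_rna(120)),
                      utr3_start = 61, utr3_end = 120)
      expect_equal(scan_guide(gr, txr)$scf_count,
                   oracle_scf(oracle_revcomp(
                     substr(unclass(gr$core)[1], 2, 8)), txr))
    }
  })
})

test_that("pool scans aggregate conservatively over members", {
  g <- guide_strand(T1_MATCH_0N)
  fix <- gen_transcriptome(g, n_transcripts = 3, length_nt = 200,
                           utr3_frac = 0.2,
                           plants = list(list(kind = "complementary_run",
                                              transcript = 1, length = 13)),
                           seed = 23)
  # pool of one behaves exactly like a plain scan
  p1 <- structure(list(template = g, members = list(g)),
                  class = "degenerate_pool")
  s1 <- scan_guide(g, fix$tx)
  sp <- scan_pool(p1, fix$tx)
  expect_equal(sp$offtarget_genes, s1$offtarget_genes)
  expect_equal(sp$scf_count, s1$scf_count)
  expect_equal(sp$passes_gene_filter, s1$passes_gene_filter)

  # a decoy complementary to one specific dN-pool member is caught
  dn <- make_dN(g)
  pool <- expand_pool(dn)
  member <- pool$members[[7]]
  decoy <- oracle_revcomp(unclass(member$core)[1])
  tx2 <- withr::with_seed(29, decoy_tx(
    c(paste0(random_rna(30), decoy, random_rna(30)), random_rna(80)),
    genes = c("GHIT", "GBG")))
  sd <- scan_pool(pool, tx2)
  expect_true("GHIT" %in% sd$offtarget_genes)

  # SCF of the pool dominates every member's SCF
  scf_members <- vapply(pool$members, function(m)
    scan_guide(m, fix$tx)$scf_count, integer(1))
  sp2 <- scan_pool(pool, fix$tx)
  expect_equal(sp2$scf_count, max(scf_members))
  expect_true(all(sp2$scf_count >= scf_members))
})
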