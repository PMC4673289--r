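#' Generate a synthetic transcriptome with planted off-target structure
#'
#' Builds a seeded random transcriptome (uniform base composition
#' unless `gc` is given) and plants features relative to a fixed guide
#' strand, returning the ground truth alongside. Two feature kinds are
#' supported:
#' \describe{
#'   \item{`complementary_run`}{an exact `length`-nt antiparallel
#'     complement of a contiguous stretch of the guide core, written
#'     over the transcript at `position` (length-preserving). The
#'     flanking base on each side is set to a non-extending base so
#'     the planted run length is exact.}
#'   \item{`seed_match`}{one exact occurrence of the reverse
#'     complement of the guide seed (positions 2-8) written inside the
#'     transcript's 3'UTR.}
#' }
#'
#' @param guide the reference [guide_strand()] the plants are defined
#'   against (concrete).
#' @param n_transcripts number of transcripts (one gene each:
#'   `G1..Gn` / `TX1..TXn`).
#' @param length_nt transcript length(s), recycled.
#' @param utr3_frac fraction of each transcript annotated as 3'UTR
#'   (suffix); 0 = no UTR annotation.
#' @param plants list of plant descriptions: each a list with `kind`
#'   (`"complementary_run"` or `"seed_match"`), `transcript` (index),
#'   and for runs `length` plus optional `position` and `guide_start`
#'   (1-based start of the complemented stretch on the guide); for
#'   seed matches an optional `position` within the UTR.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param gc optional GC fraction for the random background.
#' @return list with `tx` (a [transcriptome()]) and `manifest`
#'   (data.frame of every planted feature with its coordinates).
#' @export
gen_transcriptome <- function(guide, n_transcripts = 5L, length_nt = 300L,
                              utr3_frac = 0.2, plants = list(),
                              seed = 1L, gc = NULL) {
  guide <- as_guide(guide)
  if (!is_concrete(guide)) stop("reference guide must be concrete")
  lens <- as.integer(rep_len(length_nt, n_transcripts))
  bases <- c("A", "C", "G", "U")
  prob <- if (is.null(gc)) rep(0.25, 4L)
          else c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rc_full <- strsplit(unclass(reverse_complement(guide$core)), "")[[1L]]
  seed_rc <- strsplit(unclass(reverse_complement(seed_region(guide))),
                      "")[[1L]]

  withr::with_seed(seed, {
    seqs <- lapply(lens, function(n) sample(bases, n, replace = TRUE,
                                            prob = prob))
    utr_start <- rep(NA_integer_, n_transcripts)
    utr_end <- rep(NA_integer_, n_transcripts)
    if (utr3_frac > 0) {
      utr_len <- pmax(1L, as.integer(floor(utr3_frac * lens)))
      utr_start <- lens - utr_len + 1L
      utr_end <- lens
    }

    manifest <- list()
    for (p in plants) {
      i <- p$transcript
      if (is.null(i) || i < 1L || i > n_transcripts)
        stop("plant references transcript outside the fixture")
      if (p$kind == "complementary_run") {
        L <- as.integer(p$length)
        if (L > 19L) stop("cannot plant a run longer than the 19-nt guide")
        if (L > lens[i]) stop("planted run longer than transcript")
        gs <- p$guide_start %||% (((19L - L) %/% 2L) + 1L)
        if (gs < 1L || gs + L - 1L > 19L)
          stop("guide_start places the run outside the guide")
        # guide positions [gs, gs+L-1] pair with rc positions
        # [20-(gs+L-1), 20-gs]
        a <- 20L - (gs + L - 1L)
        frag <- rc_full[a:(a + L - 1L)]
        pos <- p$position %||% sample.int(lens[i] - L + 1L, 1L)
        if (pos < 1L || pos + L - 1L > lens[i])
          stop("planted run does not fit the transcript")
        seqs[[i]][pos:(pos + L - 1L)] <- frag
        # break the flanks so the run is exactly L
        if (pos > 1L && a > 1L)
          seqs[[i]][pos - 1L] <- sample(setdiff(bases, rc_full[a - 1L]), 1L)
        if (pos + L <= lens[i] && a + L <= 19L)
          seqs[[i]][pos + L] <- sample(setdiff(bases, rc_full[a + L]), 1L)
        manifest[[length(manifest) + 1L]] <-
          data.frame(kind = "complementary_run",
                     transcript_id = paste0("TX", i),
                     gene_id = paste0("G", i),
                     position = pos, length = L, guide_start = gs)
      } else if (p$kind == "seed_match") {
        if (is.na(utr_start[i]))
          stop("seed_match plant needs a UTR-annotated transcript")
        lo <- utr_start[i]; hi <- utr_end[i] - 7L + 1L
        if (hi < lo) stop("3'UTR too short for a seed match")
        pos <- p$position %||% (lo + sample.int(hi - lo + 1L, 1L) - 1L)
        if (pos < lo || pos > hi)
          stop("seed_match position falls outside the 3'UTR")
        seqs[[i]][pos:(pos + 6L)] <- seed_rc
        manifest[[length(manifest) + 1L]] <-
          data.frame(kind = "seed_match",
                     transcript_id = paste0("TX", i),
                     gene_id = paste0("G", i),
                     position = pos, length = 7L, guide_start = NA_integer_)
      } else stop("unknown plant kind: ", p$kind)
    }

    sequences <- stats::setNames(
      vapply(seqs, paste, character(1), collapse = ""),
      paste0("TX", seq_len(n_transcripts)))
    ann <- data.frame(transcript_id = paste0("TX", seq_len(n_transcripts)),
                      gene_id = paste0("G", seq_len(n_transcripts)),
                      utr3_start = utr_start, utr3_end = utr_end)
    list(tx = transcriptome(sequences, ann),
         manifest = if (length(manifest)) do.call(rbind, manifest)
                    else data.frame(kind = character(),
                                    transcript_id = character(),
                                    gene_id = character(),
                                    position = integer(), length = integer(),
                                    guide_start = integer()))
  })
}

#' Default 7-pair screen plan
#'
#' Emulates the structure of a small Match/Mismatch essentiality
#' screen: 7 gene pairs, one planted essential pattern (Match
#' viability 0.75 vs ~1.0 Mismatch), one planted off-target pattern
#' (both arms' viability 0.75, the Mismatch arm betraying the
#' unintended targets) and five null pairs (~1.0 both arms). All
#' pairs carry a strong planted on-target knockdown (85% Match vs 5%
#' Mismatch) so every pair passes the knockdown screen; effect sizes
#' sit at least ~4 standard errors from every decision threshold under
#' the default noise model (see the methods vignette).
#'
#' @param n_pairs number of pairs (>= 2), default 7.
#' @return data.frame with columns `gene_id`, `pattern`, `kd_match`,
#'   `kd_mismatch`, `viability_match`, `viability_mismatch`,
#'   `expected_call`.
#' @export
default_screen_plan <- function(n_pairs = 7L) {
  if (n_pairs < 2L) stop("need at least 2 pairs for both planted patterns")
  pattern <- c("essential", "off_target", rep("null", n_pairs - 2L))
  data.frame(
    gene_id = paste0("G", seq_len(n_pairs)),
    pattern = pattern,
    kd_match = 85,
    kd_mismatch = 5,
    viability_match = c(0.75, 0.75, rep(0.98, n_pairs - 2L)),
    viability_mismatch = c(1.00, 0.75, rep(1.00, n_pairs - 2L)),
    expected_call = c("essential", "off_target_confounded",
                      rep("non_essential", n_pairs - 2L)))
}

#' Generate synthetic Ct and viability tables with planted effects
#'
#' Ct values are drawn as a per-gene baseline (reference gene at a
#' fixed baseline) shifted by the planted knockdown on the log2 scale,
#' plus Gaussian replicate noise; viability ratios are the planted
#' values plus Gaussian noise, truncated at 0. Sample naming follows
#' the convention of [analyze_screen()] (`<gene>_match`,
#' `<gene>_mismatch`, blank control `0C`).
#'
#' @param plan a screen plan as from [default_screen_plan()].
#' @param seed integer seed.
#' @param n_replicates qPCR/viability replicates per condition.
#' @param ct_noise_sd replicate noise on Ct values (cycles).
#' @param viability_noise_sd noise on viability ratios.
#' @param reference_gene,control_sample naming, as in
#'   [analyze_screen()].
#' @param ref_ct,target_ct baseline Ct of the reference gene and of
#'   each target in the blank control (cycles).
#' @return list with `ct` (long-format Ct table), `viability`
#'   (gene/arm/replicate/viability) and `truth` (the plan).
#' @export
gen_assay_tables <- function(plan = default_screen_plan(), seed = 1L,
                             n_replicates = 3L, ct_noise_sd = 0.1,
                             viability_noise_sd = 0.02,
                             reference_gene = "GAPDH",
                             control_sample = "0C",
                             ref_ct = 20, target_ct = 24) {
  withr::with_seed(seed, {
    samples <- c(control_sample,
                 paste0(rep(plan$gene_id, each = 2L), "_",
                        c("match", "mismatch")))
    ct <- list()
    emit <- function(sample, gene, mean_ct) {
      data.frame(sample_id = sample, gene_id = gene,
                 replicate = seq_len(n_replicates),
                 ct = mean_ct + stats::rnorm(n_replicates, 0, ct_noise_sd))
    }
    for (s in samples) ct[[length(ct) + 1L]] <- emit(s, reference_gene, ref_ct)
    for (i in seq_len(nrow(plan))) {
      g <- plan$gene_id[i]
      ct[[length(ct) + 1L]] <- emit(control_sample, g, target_ct)
      for (arm in c("match", "mismatch")) {
        kd <- if (arm == "match") plan$kd_match[i] else plan$kd_mismatch[i]
        fc <- 1 - kd / 100
        if (fc <= 0) stop("planted knockdown must be < 100%")
        ct[[length(ct) + 1L]] <-
          emit(paste0(g, "_", arm), g, target_ct - log2(fc))
      }
    }
    via <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
      do.call(rbind, lapply(c("match", "mismatch"), function(arm) {
        v <- if (arm == "match") plan$viability_match[i]
             else plan$viability_mismatch[i]
        data.frame(gene_id = plan$gene_id[i], arm = arm,
                   replicate = seq_len(n_replicates),
                   viability = pmax(0, v + stats::rnorm(n_replicates, 0,
                                                        viability_noise_sd)))
      }))
    }))
    list(ct = do.call(rbind, ct), viability = via, truth = plan)
  })
}
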