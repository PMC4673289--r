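#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (sample, gene); dCt is the
#' target Ct minus the reference-gene Ct within each sample; ddCt is
#' the sample dCt minus the blank-control dCt; fold change is
#' `2^-ddCt`, the expression of the target relative to the blank
#' control (1.0 = unchanged).
#'
#' @param ct_table long-format data.frame with columns `sample_id`,
#'   `gene_id`, `replicate`, `ct` (cycles, > 0).
#' @param target_gene gene quantified.
#' @param reference_gene endogenous control; default `"GAPDH"`.
#' @param control_sample blank-control sample id; default `"0C"`.
#' @return data.frame with columns `sample_id`, `gene_id`, `ddct`,
#'   `fold_change`, one row per non-control sample carrying the target.
#' @export
ddct_fold_change <- function(ct_table, target_gene,
                             reference_gene = "GAPDH",
                             control_sample = "0C") {
  need <- c("sample_id", "gene_id", "replicate", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("ct_table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("Ct values must be finite and positive")
  mean_ct <- stats::aggregate(ct ~ sample_id + gene_id, ct_table, mean)
  get_ct <- function(sample, gene) {
    v <- mean_ct$ct[mean_ct$sample_id == sample & mean_ct$gene_id == gene]
    if (length(v) != 1L)
      stop(sprintf("missing Ct for gene '%s' in sample '%s'", gene, sample))
    v
  }
  dct0 <- get_ct(control_sample, target_gene) -
    get_ct(control_sample, reference_gene)
  samples <- setdiff(unique(mean_ct$sample_id[mean_ct$gene_id == target_gene]),
                     control_sample)
  ddct <- vapply(samples, function(s)
    (get_ct(s, target_gene) - get_ct(s, reference_gene)) - dct0, numeric(1))
  data.frame(sample_id = samples, gene_id = target_gene,
             ddct = unname(ddct), fold_change = 2^-unname(ddct))
}

#' Knockdown efficiency from fold change
#'
#' `100 * (1 - fold change)` in percent, clipped below at 0 so that
#' fold changes above 1 (apparent up-regulation) report 0% knockdown.
#'
#' @param fold_change relative expression vs the blank control.
#' @return Knockdown efficiency in percent, in `[0, 100)`.
#' @export
knockdown_efficiency <- function(fold_change) {
  if (any(fold_change <= 0)) stop("fold change must be positive")
  pmax(0, 100 * (1 - fold_change))
}

#' Screen a Match/Mismatch siRNA pair
#'
#' A pair is usable for essentiality calling when (i) the Match
#' knockdown efficiency strictly exceeds `kd_min` percent relative to
#' the blank control, and (ii) the Match knockdown exceeds the
#' Mismatch knockdown by at least `kd_gap_min` percentage points, so
#' the Mismatch is a genuine negative control on-target.
#'
#' @param kd_match,kd_mismatch knockdown efficiencies in percent.
#' @param kd_min criterion (i) threshold, percent (default 60,
#'   exclusive).
#' @param kd_gap_min criterion (ii) threshold, percentage points
#'   (default 50, inclusive).
#' @return Logical: does the pair pass both criteria? Vectorized.
#' @export
screen_pair <- function(kd_match, kd_mismatch, kd_min = 60, kd_gap_min = 50) {
  kd_match > kd_min & (kd_match - kd_mismatch) >= kd_gap_min
}

#' Classify a screened pair by its viability outcome
#'
#' Pairs failing the knockdown screen are `invalid_pair`. For passing
#' pairs: if the Mismatch control itself depresses viability below the
#' threshold, the phenotype is attributed to unintended targets
#' (`off_target_confounded`); otherwise a Match viability below the
#' threshold calls the gene `essential`; otherwise `non_essential`.
#'
#' @param screen_pass logical from [screen_pair()].
#' @param viability_match,viability_mismatch cell-viability ratios to
#'   the blank control (dimensionless, ~1 = no effect).
#' @param viability_threshold default 0.80; viability strictly below
#'   it counts as a drop.
#' @return Character vector over `{essential, off_target_confounded,
#'   non_essential, invalid_pair}`. Vectorized.
#' @export
classify_pair <- function(screen_pass, viability_match, viability_mismatch,
                          viability_threshold = 0.80) {
  if (any(viability_match < 0) || any(viability_mismatch < 0))
    stop("viability ratios must be >= 0")
  ifelse(!screen_pass, "invalid_pair",
    ifelse(viability_mismatch < viability_threshold, "off_target_confounded",
      ifelse(viability_match < viability_threshold, "essential",
             "non_essential")))
}

#' Differential-expression filter
#'
#' Keeps records changed more than `fc_min`-fold in either direction
#' (i.e. `max(fc, 1/fc) > fc_min`) with `p < p_max`. Optionally
#' applies Benjamini-Hochberg correction to the p-values before
#' thresholding (off by default; the raw-p rule is the screening
#' default).
#'
#' @param table data.frame with columns `gene_id`, `fold_change`
#'   (> 0) and `p_value`.
#' @param fc_min fold-change threshold (exclusive), default 1.5.
#' @param p_max p-value threshold (exclusive), default 0.01.
#' @param adjust apply BH correction before thresholding.
#' @return The surviving rows of `table`.
#' @export
de_filter <- function(table, fc_min = 1.5, p_max = 0.01, adjust = FALSE) {
  if (any(table$fold_change <= 0)) stop("fold changes must be positive")
  if (any(table$p_value < 0 | table$p_value > 1))
    stop("p-values must lie in [0, 1]")
  p <- if (adjust) stats::p.adjust(table$p_value, method = "BH")
       else table$p_value
  keep <- pmax(table$fold_change, 1 / table$fold_change) > fc_min &
    p < p_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select qPCR validation candidates by expression level
#'
#' Keeps genes whose FPKM strictly exceeds `fpkm_min` in every sample
#' (reliably quantifiable by qPCR), ordered by gene id; optionally
#' draws a seeded random subsample of size `k`.
#'
#' @param table data.frame with a `gene_id` column and one or more
#'   `fpkm_*` columns (one per sample).
#' @param fpkm_min per-sample threshold (exclusive), default 20.
#' @param k optional subsample size.
#' @param seed seed for the subsample draw (required with `k`).
#' @return The surviving (possibly subsampled) rows.
#' @export
validation_candidates <- function(table, fpkm_min = 20, k = NULL,
                                  seed = NULL) {
  fpkm_cols <- grep("^fpkm", names(table), value = TRUE)
  if (length(fpkm_cols) == 0L) stop("no fpkm_* columns in table")
  fpkm <- as.matrix(table[, fpkm_cols, drop = FALSE])
  if (any(fpkm < 0)) stop("FPKM values must be >= 0")
  keep <- apply(fpkm > fpkm_min, 1L, all)
  out <- table[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  if (!is.null(k) && nrow(out) > k) {
    if (is.null(seed)) stop("subsampling requires a seed")
    idx <- withr::with_seed(seed, sample.int(nrow(out), k))
    out <- out[sort(idx), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Analyze a Match/Mismatch knockdown-viability screen
#'
#' End-to-end pair analysis: per-gene fold changes from the Ct table
#' by [ddct_fold_change()] (samples named `<gene>_match` and
#' `<gene>_mismatch`, blank control `0C`), knockdown efficiencies,
#' pair screening and essentiality classification against the paired
#' viability table.
#'
#' @param ct_table long-format Ct table (see [ddct_fold_change()]).
#' @param viability_table data.frame with columns `gene_id`, `arm`
#'   (`"match"`/`"mismatch"`) and `viability`.
#' @param reference_gene,control_sample passed to [ddct_fold_change()].
#' @param kd_min,kd_gap_min passed to [screen_pair()].
#' @param viability_threshold passed to [classify_pair()].
#' @return list with `records` (per-gene data.frame: `gene_id`,
#'   `kd_match`, `kd_mismatch`, `viability_match`,
#'   `viability_mismatch`, `screen_pass`, `call`) and `summary`
#'   (named counts per call category).
#' @export
analyze_screen <- function(ct_table, viability_table,
                           reference_gene = "GAPDH", control_sample = "0C",
                           kd_min = 60, kd_gap_min = 50,
                           viability_threshold = 0.80) {
  genes <- sort(unique(viability_table$gene_id))
  cats <- c("essential", "off_target_confounded", "non_essential",
            "invalid_pair")
  if (length(genes) == 0L) {
    return(list(records = data.frame(gene_id = character(),
                                     kd_match = numeric(),
                                     kd_mismatch = numeric(),
                                     viability_match = numeric(),
                                     viability_mismatch = numeric(),
                                     screen_pass = logical(),
                                     call = character()),
                summary = stats::setNames(integer(length(cats)), cats)))
  }
  get_via <- function(g, arm) {
    v <- viability_table$viability[viability_table$gene_id == g &
                                     viability_table$arm == arm]
    if (length(v) == 0L)
      stop(sprintf("missing viability for gene '%s' arm '%s'", g, arm))
    mean(v)
  }
  rec <- do.call(rbind, lapply(genes, function(g) {
    fc <- ddct_fold_change(ct_table, g, reference_gene = reference_gene,
                           control_sample = control_sample)
    get_fc <- function(arm) {
      v <- fc$fold_change[fc$sample_id == paste0(g, "_", arm)]
      if (length(v) != 1L)
        stop(sprintf("missing Ct sample '%s_%s'", g, arm))
      v
    }
    data.frame(gene_id = g,
               kd_match = knockdown_efficiency(get_fc("match")),
               kd_mismatch = knockdown_efficiency(get_fc("mismatch")),
               viability_match = get_via(g, "match"),
               viability_mismatch = get_via(g, "mismatch"))
  }))
  rec$screen_pass <- screen_pair(rec$kd_match, rec$kd_mismatch,
                                 kd_min = kd_min, kd_gap_min = kd_gap_min)
  rec$call <- classify_pair(rec$screen_pass, rec$viability_match,
                            rec$viability_mismatch,
                            viability_threshold = viability_threshold)
  counts <- stats::setNames(vapply(cats, function(cc) sum(rec$call == cc),
                                   integer(1)), cats)
  list(records = rec, summary = counts)
}
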