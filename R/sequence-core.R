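#' Nucleic-acid sequence
#'
#' Lightweight validated container for a single RNA or DNA sequence.
#' `N` (any base) is legal in both alphabets; `U` is RNA-only and `T`
#' DNA-only. Lowercase input is upper-cased.
#'
#' @param x single character string of residues.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return A `nuc_seq` object: the residue string with an `alphabet`
#'   attribute.
#' @examples
#' nuc_seq("AUGC", "RNA")
#' nuc_seq("ATGC", "DNA")
#' @export
nuc_seq <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  x <- toupper(x)
  if (nchar(x) == 0L) stop("sequence must be non-empty")
  legal <- if (alphabet == "RNA") "ACGUN" else "ACGTN"
  bad <- setdiff(strsplit(x, "")[[1L]], strsplit(legal, "")[[1L]])
  if (length(bad))
    stop(sprintf("illegal %s residue(s): %s", alphabet,
                 paste(unique(bad), collapse = ", ")))
  structure(x, alphabet = alphabet, class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq %s, %d nt> %s\n", attr(x, "alphabet"), nchar(x),
              unclass(x)))
  invisible(x)
}

seq_alphabet <- function(s) attr(s, "alphabet") %||% "RNA"

`%||%` <- function(a, b) if (is.null(a)) b else a

as_nuc_seq <- function(x, alphabet = "RNA") {
  if (inherits(x, "nuc_seq")) x else nuc_seq(x, alphabet)
}

#' Convert a sequence between RNA and DNA alphabets
#'
#' T<->U transliteration; all other residues (including N) unchanged.
#'
#' @param s a [nuc_seq()].
#' @param to `"RNA"` or `"DNA"`.
#' @return A `nuc_seq` in the requested alphabet, same length.
#' @export
convert_alphabet <- function(s, to = c("RNA", "DNA")) {
  to <- match.arg(to)
  s <- as_nuc_seq(s, "RNA")
  out <- if (to == "RNA") chartr("T", "U", unclass(s))
         else chartr("U", "T", unclass(s))
  nuc_seq(out, to)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed. `N` maps to `N`; the alphabet of
#' the input is preserved, so the complement of `U` is `A` and the
#' complement of `A` is `U` (RNA) or `T` (DNA).
#'
#' @param s a [nuc_seq()] or plain string (assumed RNA).
#' @return A `nuc_seq` of the same length and alphabet.
#' @examples
#' reverse_complement(nuc_seq("AUGC")) # "GCAU"
#' @export
reverse_complement <- function(s) {
  s <- as_nuc_seq(s)
  alpha <- seq_alphabet(s)
  comp <- if (alpha == "RNA") chartr("ACGUN", "UGCAN", unclass(s))
          else chartr("ACGTN", "TGCAN", unclass(s))
  rev_ <- paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
  nuc_seq(rev_, alpha)
}

#' siRNA guide strand
#'
#' A 19-nt RNA guide core (5'->3', 1-based positions) with the
#' conventional dTdT DNA overhang. The overhang is carried for display
#' and synthesis output only: it takes no part in position arithmetic,
#' seed extraction or complementarity scans. The core may contain `N`
#' at degenerate positions (see [expand_pool()]).
#'
#' @param core 19-residue RNA sequence (string or [nuc_seq()]).
#' @return A `guide_strand` object with elements `core` (nuc_seq) and
#'   `overhang` (`"dTdT"`).
#' @examples
#' guide_strand("ACCGUAUGAAGUACUUGGC")
#' @export
guide_strand <- function(core) {
  core <- as_nuc_seq(core, "RNA")
  if (nchar(core) != 19L)
    stop(sprintf("guide core must be exactly 19 nt, got %d", nchar(core)))
  structure(list(core = core, overhang = "dTdT"), class = "guide_strand")
}

#' @export
print.guide_strand <- function(x, ...) {
  cat(sprintf("<guide_strand 5'-%s%s-3'>\n", unclass(x$core), x$overhang))
  invisible(x)
}

as_guide <- function(g) {
  if (inherits(g, "guide_strand")) g else guide_strand(g)
}

guide_chars <- function(g) strsplit(unclass(as_guide(g)$core), "")[[1L]]

is_concrete <- function(g) !any(guide_chars(g) == "N")

#' Seed region of a guide strand
#'
#' The 7-mer at guide positions 2-8 (1-based from the 5' end of the
#' core), the region whose complementarity to transcript 3'UTRs drives
#' miRNA-like off-target repression.
#'
#' @param g a [guide_strand()].
#' @return A length-7 RNA [nuc_seq()].
#' @examples
#' seed_region(guide_strand("ACCGUAUGAAGUACUUGGC")) # "CCGUAUG"
#' @export
seed_region <- function(g) {
  g <- as_guide(g)
  nuc_seq(substr(unclass(g$core), 2L, 8L), "RNA")
}

#' Expand a degenerate guide into its concrete pool
#'
#' Every `N` in the core stands for an even mixture of the four bases;
#' the pool enumerates all concretizations. Order is deterministic:
#' bases in order A < C < G < U at each N position, with the leftmost
#' N position varying slowest, so member indices are stable across runs.
#'
#' @param g a [guide_strand()], 0-19 N positions.
#' @return A `degenerate_pool`: list with `template` and `members`
#'   (list of concrete `guide_strand`s, length `4^#N`).
#' @examples
#' length(expand_pool(guide_strand("ANCGUAUGAAGUACUUGNC"))$members) # 16
#' @export
expand_pool <- function(g) {
  g <- as_guide(g)
  ch <- guide_chars(g)
  npos <- which(ch == "N")
  bases <- c("A", "C", "G", "U")
  if (length(npos) == 0L) {
    members <- list(g)
  } else {
    # expand.grid varies the first column fastest; feed positions in
    # reverse so the leftmost N is the slowest-varying digit
    grid <- do.call(expand.grid,
                    c(rep(list(bases), length(npos)),
                      list(stringsAsFactors = FALSE)))
    grid <- grid[, rev(seq_along(npos)), drop = FALSE]
    members <- lapply(seq_len(nrow(grid)), function(i) {
      cc <- ch
      cc[npos] <- unlist(grid[i, ])
      guide_strand(paste(cc, collapse = ""))
    })
  }
  structure(list(template = g, members = members), class = "degenerate_pool")
}

#' @export
print.degenerate_pool <- function(x, ...) {
  cat(sprintf("<degenerate_pool of %d from template %s>\n",
              length(x$members), unclass(x$template$core)))
  invisible(x)
}

#' Positions at which two guides differ
#'
#' 1-based core positions whose residues differ. `N` counts as
#' differing from any concrete base (and from `N` it does not differ).
#'
#' @param a,b [guide_strand()]s of equal core length.
#' @return Sorted integer vector of differing positions.
#' @examples
#' diff_positions(guide_strand("ACCGUAUGAAGUACUUGGC"),
#'                guide_strand("ACCGUAUGAAAUACUUGGC")) # 11
#' @export
diff_positions <- function(a, b) {
  ca <- guide_chars(a); cb <- guide_chars(b)
  if (length(ca) != length(cb)) stop("guides differ in length")
  diff <- ca != cb | (ca == "N" & cb != "N") | (cb == "N" & ca != "N")
  which(diff)
}
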