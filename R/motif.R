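# In-silico restriction-site counting. The classifier uses the CfoI
# recognition motif GCGC, which occurs twice in the ITS1-ITS2 region of
# S. pectinata but only once in S. vaginata — a classical corroborating
# character for separating the two species.

count_motif_one <- function(s, motif, mode) {
  s <- degap(toupper(s))
  if (mode == "strict") {
    pat <- paste0("(?=", motif, ")")
  } else {
    # compatible mode: a residue matches a motif base when its IUPAC set
    # contains that base (e.g. S = G/C matches both G and C)
    classes <- vapply(seq_chars(motif), function(b) {
      mb <- IUPAC_MASK[[b]]
      hits <- IUPAC_LETTERS[bitwAnd(IUPAC_MASK[IUPAC_LETTERS], mb) == mb]
      paste0("[", paste(hits, collapse = ""), "]")
    }, character(1))
    pat <- paste0("(?=", paste(classes, collapse = ""), ")")
  }
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Count motif occurrences in sequences
#'
#' Occurrences are counted on the ungapped sequence; overlapping matches are
#' counted (so `GCGCGC` contains `GCGC` twice). `strict` mode counts exact
#' character matches only; `compatible` mode also counts positions whose
#' IUPAC ambiguity set contains the motif base, i.e. sites that *may* be
#' present given the ambiguity calls. Strict counts are always less than or
#' equal to compatible counts.
#'
#' @param seqs a data frame with `id` and `seq` columns, or a character
#'   vector of sequences.
#' @param motif unambiguous A/C/G/T motif, e.g. `"GCGC"` (CfoI).
#' @param mode `"strict"` (default) or `"compatible"`.
#' @return A tibble with `id` and `count` (for a bare character vector,
#'   an integer vector).
#' @export
count_motif <- function(seqs, motif = "GCGC", mode = c("strict", "compatible")) {
  mode <- match.arg(mode)
  motif <- toupper(motif)
  stopifnot(nzchar(motif), all(seq_chars(motif) %in% c("A", "C", "G", "T")))
  if (is.character(seqs)) {
    return(vapply(seqs, count_motif_one, integer(1), motif = motif,
                  mode = mode, USE.NAMES = FALSE))
  }
  tibble::tibble(
    id = seqs$id,
    count = vapply(seqs$seq, count_motif_one, integer(1), motif = motif,
                   mode = mode, USE.NAMES = FALSE)
  )
}
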