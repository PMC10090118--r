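# IUPAC nucleotide alphabet machinery shared across the package.
# Bases are encoded as 4-bit masks (A=1, C=2, G=4, T=8); an ambiguity code is
# the bitwise OR of its base set and the gap character maps to 0.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  `-` = 0L
)

IUPAC_LETTERS <- setdiff(names(IUPAC_MASK), "-")

# inverse lookup: mask value (0..15) -> IUPAC letter
MASK_CHAR <- character(16L)
MASK_CHAR[IUPAC_MASK + 1L] <- names(IUPAC_MASK)

#' Split a sequence string into single characters
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Encode a (possibly gapped) sequence string as integer bit masks
#' @noRd
encode_seq <- function(x) {
  m <- unname(IUPAC_MASK[seq_chars(x)])
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("illegal character '", seq_chars(x)[bad], "' at position ", bad,
         call. = FALSE)
  }
  m
}

#' Decode integer bit masks back to a sequence string
#' @noRd
decode_seq <- function(m) paste(MASK_CHAR[m + 1L], collapse = "")

#' Position-wise IUPAC union of two equal-length sequences
#'
#' Combines two haplotypes the way a Sanger consensus of a heterozygote
#' (or an interspecific hybrid) reads: positions where the inputs agree are
#' unchanged, positions where they differ become the ambiguity code covering
#' both base sets.
#'
#' @param a,b equal-length ungapped sequence strings.
#' @return A sequence string of the same length.
#' @examples
#' iupac_union("ACGT", "ACTT")  # "ACKT"
#' @export
iupac_union <- function(a, b) {
  ma <- encode_seq(a)
  mb <- encode_seq(b)
  stopifnot(length(ma) == length(mb))
  decode_seq(bitwOr(ma, mb))
}

#' Do two IUPAC codes share at least one base?
#' @noRd
iupac_intersects <- function(a, b) {
  bitwAnd(unname(IUPAC_MASK[a]), unname(IUPAC_MASK[b])) > 0L
}

is_unambiguous_base <- function(chars) chars %in% c("A", "C", "G", "T")

#' Validate residues against the IUPAC nucleotide alphabet
#'
#' @param x character vector of sequence strings (one per record).
#' @param allow_gap allow the alignment gap character `-`.
#' @return `x`, uppercased, invisibly validated; `.` gap dialect is
#'   normalized to `-` with a warning when gaps are allowed.
#' @noRd
validate_residues <- function(x, allow_gap = FALSE, ids = NULL) {
  x <- toupper(x)
  if (allow_gap && any(grepl(".", x, fixed = TRUE))) {
    warning("'.' gap characters normalized to '-'", call. = FALSE)
    x <- gsub(".", "-", x, fixed = TRUE)
  }
  allowed <- if (allow_gap) names(IUPAC_MASK) else IUPAC_LETTERS
  for (i in seq_along(x)) {
    if (!nzchar(x[i])) {
      stop("empty sequence", if (!is.null(ids)) paste0(" for record '", ids[i], "'"),
           call. = FALSE)
    }
    ch <- seq_chars(x[i])
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
           if (!is.null(ids)) paste0(" in record '", ids[i], "'"),
           call. = FALSE)
    }
  }
  x
}
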