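# Multiple sequence alignment: pairwise global alignment with affine gaps
# (Gotoh), progressive profile-profile merging along a UPGMA guide tree built
# from k-mer distances, and coordinate mapping between ungapped (residue) and
# alignment (column) frames.
#
# An alignment is an ordinary sequence tibble (id, note, seq) whose `seq`
# strings are gapped and share one length; columns are addressed 1-based.

#' Alignment scoring scheme
#'
#' Parameters of the affine-gap global aligner. A gap run of length k costs
#' `|gap_open| + (k - 1) * |gap_extend|`. With `ambiguity_match = TRUE` two
#' residues score as a match whenever their IUPAC base sets intersect
#' (so K vs G is a match); otherwise only identical characters match.
#'
#' Defaults (+2/-1, open -5, extend -1) are chosen so that short indels of
#' the sizes seen in the Stuckenia ITS1-ITS2 locus (1 and 9 nt) align as
#' single contiguous gap blocks.
#'
#' @param match,mismatch,gap_open,gap_extend signed scores;
#'   `gap_open <= gap_extend <= 0 < match` and `match > mismatch` required.
#' @param ambiguity_match logical IUPAC-intersection match policy.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -5,
                           gap_extend = -1, ambiguity_match = TRUE) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0,
            match > mismatch, match > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, ambiguity_match = ambiguity_match),
            class = "scoring_scheme")
}

# 16 x 16 symbol score matrix over bitmask codes 0..15 (0 = gap, scores 0)
symbol_score_matrix <- function(scheme) {
  codes <- 0:15
  inter <- outer(codes, codes, bitwAnd) > 0L
  K <- matrix(scheme$mismatch, 16L, 16L)
  if (scheme$ambiguity_match) {
    K[inter] <- scheme$match
  } else {
    diag(K) <- scheme$match
  }
  K[1L, ] <- 0
  K[, 1L] <- 0
  K
}

# profile = integer code matrix (rows = sequences, cols = alignment columns)
profile_counts <- function(prof) {
  L <- ncol(prof)
  C <- matrix(0, nrow = 16L, ncol = L)
  tab <- prof + 1L  # codes 0..15 -> rows 1..16
  for (j in seq_len(L)) C[, j] <- tabulate(tab[, j], nbins = 16L)
  C
}

# merge two profiles along a Gotoh path; returns merged code matrix
merge_profiles <- function(pa, pb, scheme) {
  K <- symbol_score_matrix(scheme)
  S <- crossprod(profile_counts(pa), K %*% profile_counts(pb)) /
    (nrow(pa) * nrow(pb))
  res <- gotoh_align(S, scheme$gap_open, scheme$gap_extend)
  path <- res$path
  n <- length(path)
  out <- matrix(0L, nrow = nrow(pa) + nrow(pb), ncol = n)
  ia <- cumsum(path != 2L)  # A column consumed at this alignment column
  ib <- cumsum(path != 1L)
  out[seq_len(nrow(pa)), path != 2L] <- pa[, ia[path != 2L], drop = FALSE]
  out[nrow(pa) + seq_len(nrow(pb)), path != 1L] <- pb[, ib[path != 1L], drop = FALSE]
  attr(out, "score") <- res$score
  out
}

#' Pairwise global alignment of two sequences
#'
#' Needleman–Wunsch with affine gap penalties (Gotoh) and a fixed traceback
#' tie-break (diagonal over up over left) so results are deterministic.
#' Terminal gaps are penalized like internal ones.
#'
#' @param seqs a 2-row sequence data frame (columns `id`, `seq`).
#' @param scheme a [scoring_scheme()].
#' @return A 2-row alignment tibble (`id`, `seq`) with the optimal `score`
#'   attached as attribute `"score"` (see [alignment_score()]).
#' @export
align_pairwise <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(is.data.frame(seqs), nrow(seqs) == 2L)
  seqs$seq <- validate_residues(seqs$seq, ids = seqs$id)
  pa <- matrix(encode_seq(seqs$seq[1]), nrow = 1L)
  pb <- matrix(encode_seq(seqs$seq[2]), nrow = 1L)
  merged <- merge_profiles(pa, pb, scheme)
  out <- tibble::tibble(
    id = seqs$id,
    seq = apply(merged, 1L, decode_seq)
  )
  attr(out, "score") <- attr(merged, "score")
  out
}

#' Optimal score of a pairwise alignment
#' @param aln result of [align_pairwise()].
#' @return numeric scalar.
#' @export
alignment_score <- function(aln) attr(aln, "score")

# shared-k-mer distance between two ungapped sequences
kmer_distance <- function(a, b, k = 4L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  ka <- km(a); kb <- km(b)
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from shared-k-mer distances and merges
#' single-sequence profiles pairwise in guide-tree order, each merge being a
#' global affine-gap profile alignment. Sequences are canonically ordered by
#' id before clustering, so the result is invariant under permutation of the
#' input rows (up to row order, which follows the input).
#'
#' @param seqs sequence data frame (`id`, `seq`), at least 2 rows,
#'   unique ids.
#' @param scheme a [scoring_scheme()].
#' @param k k-mer size for the guide-tree distance.
#' @return An alignment tibble (`id`, `seq`) in input row order; the guide
#'   tree is attached as attribute `"guide_tree"` (an ape `phylo`).
#' @export
align_progressive <- function(seqs, scheme = scoring_scheme(), k = 4L) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 2L)
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids", call. = FALSE)
  seqs$seq <- validate_residues(seqs$seq, ids = seqs$id)
  ord <- order(seqs$id)
  s <- seqs[ord, , drop = FALSE]
  n <- nrow(s)

  D <- matrix(0, n, n, dimnames = list(s$id, s$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- kmer_distance(s$seq[i], s$seq[j], k = k)
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  profiles <- lapply(s$seq, function(x) matrix(encode_seq(x), nrow = 1L))
  members <- lapply(seq_len(n), identity)
  merged <- vector("list", nrow(hc$merge))
  mem_merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(v) {
      if (v < 0) list(prof = profiles[[-v]], mem = members[[-v]])
      else list(prof = merged[[v]], mem = mem_merged[[v]])
    }
    a <- pick(hc$merge[m, 1]); b <- pick(hc$merge[m, 2])
    merged[[m]] <- merge_profiles(a$prof, b$prof, scheme)
    mem_merged[[m]] <- c(a$mem, b$mem)
  }
  final <- merged[[nrow(hc$merge)]]
  mem <- mem_merged[[nrow(hc$merge)]]

  gapped <- apply(final, 1L, decode_seq)
  ids_sorted <- s$id[mem]
  out <- tibble::tibble(id = ids_sorted, seq = gapped)
  out <- out[match(seqs$id, out$id), , drop = FALSE]
  out <- check_alignment(out)
  attr(out, "guide_tree") <- ape::as.phylo(hc)
  out
}

#' Validate an alignment tibble
#'
#' Checks equal gapped lengths, the IUPAC+gap alphabet, unique ids and the
#' absence of all-gap columns.
#'
#' @param aln data frame with columns `id`, `seq` (gapped).
#' @return the validated tibble.
#' @export
check_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "seq") %in% names(aln)))
  if (anyDuplicated(aln$id)) stop("duplicate alignment ids", call. = FALSE)
  aln$seq <- validate_residues(aln$seq, allow_gap = TRUE, ids = aln$id)
  if (length(unique(nchar(aln$seq))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(aln$seq, encode_seq))
  if (any(colSums(mat > 0L) == 0L)) {
    stop("alignment contains an all-gap column", call. = FALSE)
  }
  tibble::as_tibble(aln)
}

#' Number of columns of an alignment
#' @param aln alignment tibble.
#' @return integer column count.
#' @export
alignment_length <- function(aln) nchar(aln$seq[1])

aln_row <- function(aln, id) {
  i <- match(id, aln$id)
  if (is.na(i)) stop("id '", id, "' not found in alignment", call. = FALSE)
  aln$seq[i]
}

#' Map an ungapped residue index to its alignment column
#'
#' For row `id`, residue `index` (1-based position in the degapped sequence)
#' is mapped to its 1-based alignment column. The mapping is a bijection
#' between the row's residues and its non-gap columns; [unmap_position()] is
#' the inverse.
#'
#' @param aln alignment tibble.
#' @param id row id.
#' @param index 1-based ungapped residue position(s).
#' @return integer alignment column(s).
#' @export
map_position <- function(aln, id, index) {
  ch <- seq_chars(aln_row(aln, id))
  cols <- which(ch != "-")
  if (any(index < 1L | index > length(cols))) {
    stop("residue index out of range for row '", id, "'", call. = FALSE)
  }
  cols[index]
}

#' Map an alignment column back to the ungapped residue index
#'
#' Inverse of [map_position()]; the addressed column must not be a gap in
#' the row.
#'
#' @inheritParams map_position
#' @param column 1-based alignment column(s).
#' @return integer ungapped residue position(s).
#' @export
unmap_position <- function(aln, id, column) {
  ch <- seq_chars(aln_row(aln, id))
  if (any(column < 1L | column > length(ch))) {
    stop("column out of range", call. = FALSE)
  }
  if (any(ch[column] == "-")) {
    stop("column is a gap in row '", id, "'", call. = FALSE)
  }
  cumsum(ch != "-")[column]
}

#' Remove gaps from sequences
#' @param x character vector of (possibly gapped) sequences.
#' @return character vector without `-`.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
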