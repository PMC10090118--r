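# Pairwise distance matrices on alignments.
#
# Both estimators treat IUPAC ambiguity codes as missing data, because in
# Sanger consensus sequences of hybrids the ambiguity codes are additivity
# artifacts that would otherwise inflate distances. Under the default
# pairwise-deletion policy a column is dropped only for the pairs in which
# either row carries a gap or an ambiguity; complete deletion drops such
# columns for everybody.

# integer code matrix (rows = sequences) from an alignment tibble
aln_code_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$seq, encode_seq))
  rownames(m) <- aln$id
  m
}

new_dist_matrix <- function(values, labels, method, flagged = NULL) {
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("stk_dist", "matrix"), method = method,
            flagged = flagged)
}

# pairwise counts shared by both estimators; X_b are one-hot base indicators
pair_counts <- function(codes, deletion) {
  V <- (codes == 1L) | (codes == 2L) | (codes == 4L) | (codes == 8L)
  storage.mode(V) <- "numeric"
  if (deletion == "complete") {
    keep <- colSums(V) == nrow(V)
    codes <- codes[, keep, drop = FALSE]
    V <- V[, keep, drop = FALSE]
  }
  X <- lapply(c(A = 1L, C = 2L, G = 4L, T = 8L), function(b) {
    M <- codes == b
    storage.mode(M) <- "numeric"
    M
  })
  comp <- tcrossprod(V)                     # comparable columns per pair
  match_ <- Reduce(`+`, lapply(X, tcrossprod))
  list(V = V, X = X, comp = comp, match = match_)
}

check_comparable <- function(comp, labels) {
  bad <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("no comparable columns for pair ", labels[bad[1, 1]], " / ",
         labels[bad[1, 2]], call. = FALSE)
  }
}

#' Uncorrected p-distance matrix
#'
#' Entry (i, j) is the proportion of mismatching residues among the columns
#' comparable for that pair (both rows an unambiguous base). Character
#' differences among A/C/G/T only are counted; gaps and ambiguity codes are
#' excluded per the deletion policy.
#'
#' @param aln alignment tibble (`id`, `seq`), at least 2 rows.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric `stk_dist` matrix with zero diagonal; values in
#'   \[0, 1\]. Use [generics::tidy()] for the long-tibble form.
#' @export
p_distances <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- check_alignment(aln)
  stopifnot(nrow(aln) >= 2L)
  pc <- pair_counts(aln_code_matrix(aln), deletion)
  check_comparable(pc$comp, aln$id)
  d <- (pc$comp - pc$match) / pc$comp
  diag(d) <- 0
  new_dist_matrix(d, aln$id, paste0("p-distance (", deletion, " deletion)"))
}

#' Tamura–Nei (TN93) distance matrix
#'
#' The 1993 Tamura–Nei correction, allowing unequal base frequencies and
#' distinct purine/pyrimidine transition rates. Base frequencies are
#' estimated empirically from the compared columns of each pair. Pairs whose
#' correction logarithm has a non-positive argument (saturation) are set to
#' `NaN` and listed in attribute `"flagged"` with code `"saturation"`.
#'
#' @inheritParams p_distances
#' @return A symmetric `stk_dist` matrix with zero diagonal.
#' @export
tn93_distances <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- check_alignment(aln)
  stopifnot(nrow(aln) >= 2L)
  pc <- pair_counts(aln_code_matrix(aln), deletion)
  check_comparable(pc$comp, aln$id)
  n <- nrow(pc$comp)
  X <- pc$X
  V <- pc$V
  # per-pair transition/transversion proportions
  P1 <- (tcrossprod(X$A, X$G) + tcrossprod(X$G, X$A)) / pc$comp  # A<->G
  P2 <- (tcrossprod(X$C, X$T) + tcrossprod(X$T, X$C)) / pc$comp  # C<->T
  Q <- (pc$comp - pc$match) / pc$comp - P1 - P2                  # transversions
  # per-pair empirical base frequencies over the compared columns
  freq <- lapply(X, function(Xb) {
    cnt <- tcrossprod(Xb, V)
    (cnt + t(cnt)) / (2 * pc$comp)
  })
  gA <- freq$A; gC <- freq$C; gG <- freq$G; gT <- freq$T
  gR <- gA + gG
  gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  term <- function(k, w) {
    # negative log arguments are handled below as explicit saturation flags
    out <- suppressWarnings(-k * log(w))
    out[k == 0] <- 0  # absent base class contributes nothing
    out
  }
  d <- term(k1, w1) + term(k2, w2) + term(k3, w3)
  sat <- (w1 <= 0 & k1 > 0) | (w2 <= 0 & k2 > 0) | (w3 <= 0 & k3 > 0)
  d[sat] <- NaN
  diag(d) <- 0
  flagged <- NULL
  bad <- which(sat & upper.tri(sat), arr.ind = TRUE)
  if (nrow(bad)) {
    flagged <- tibble::tibble(item1 = aln$id[bad[, 1]],
                              item2 = aln$id[bad[, 2]],
                              code = "saturation")
    warning(nrow(bad), " pair(s) flagged as saturated (TN93 undefined)",
            call. = FALSE)
  }
  new_dist_matrix(d, aln$id, paste0("TN93 (", deletion, " deletion)"),
                  flagged = flagged)
}

#' @export
print.stk_dist <- function(x, ...) {
  cat("<distance matrix: ", attr(x, "method"), ", ",
      nrow(x), " sequences>\n", sep = "")
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Write a distance matrix as labelled CSV
#'
#' Full square matrix (lower triangle mirrored), label column first.
#'
#' @param d an `stk_dist` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(d, path) {
  df <- tibble::as_tibble(formatC(unclass(d), format = "g", digits = 10))
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(d)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into a long tibble
#'
#' @param x an `stk_dist` matrix.
#' @param ... unused.
#' @return tibble with `item1`, `item2`, `distance`, one row per unordered
#'   pair (upper triangle).
#' @export
tidy.stk_dist <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(x)[idx[, 1]],
                 item2 = colnames(x)[idx[, 2]],
                 distance = x[idx])
}
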