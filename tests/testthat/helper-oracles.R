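# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

seq_tbl <- function(...) {
  s <- c(...)
  tibble::tibble(id = names(s), seq = unname(s))
}

# Independent brute-force optimal global alignment score: plain memoized
# recursion over (prefix of a, prefix of b, previous move), written without
# any code shared with the package's DP. Gap run of length k costs
# open + (k - 1) * extend.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

bf_align_score <- function(a, b, match = 2, mismatch = -1, open = -5,
                           extend = -1, ambiguity_match = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  subst <- function(x, y) {
    hit <- if (ambiguity_match) {
      length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0
    } else x == y
    if (hit) match else mismatch
  }
  memo <- new.env(hash = TRUE)
  # state: "M" (last was aligned pair or start), "X" (gap in b), "Y" (gap in a)
  f <- function(i, j, state) {
    if (i == 0 && j == 0) return(if (state == "M") 0 else -Inf)  # start state
    k <- paste(i, j, state)
    if (!is.null(memo[[k]])) return(memo[[k]])
    best <- -Inf
    if (i > 0 && j > 0 && state == "M") {
      best <- max(best,
                  f(i - 1, j - 1, "M") + subst(av[i], bv[j]),
                  f(i - 1, j - 1, "X") + subst(av[i], bv[j]),
                  f(i - 1, j - 1, "Y") + subst(av[i], bv[j]))
    }
    if (i > 0 && state == "X") {
      best <- max(best,
                  f(i - 1, j, "M") + open,
                  f(i - 1, j, "X") + extend,
                  f(i - 1, j, "Y") + open)
    }
    if (j > 0 && state == "Y") {
      best <- max(best,
                  f(i, j - 1, "M") + open,
                  f(i, j - 1, "X") + open,
                  f(i, j - 1, "Y") + extend)
    }
    memo[[k]] <- best
    best
  }
  max(f(length(av), length(bv), "M"),
      f(length(av), length(bv), "X"),
      f(length(av), length(bv), "Y"))
}

# support value attached to the split separating `tips` from the rest, or NA
split_support <- function(tree, tips) {
  for (side in list(tips, setdiff(tree$tip.label, tips))) {
    node <- ape::getMRCA(tree, side)
    if (is.null(node)) next
    desc <- ape::extract.clade(tree, node)$tip.label
    if (setequal(desc, side)) {
      lab <- tree$node.label[node - ape::Ntip(tree)]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

# tiny simulated study used by several tests
small_composition <- function(hybrids = 1L) {
  tibble::tibble(
    true_taxon = c(rep(c("vaginata", "pectinata_A", "pectinata_B",
                         "macrocarpa", "chakassiensis"), each = 2L),
                   rep("hybrid", hybrids)),
    morphology_label = "unknown"
  )
}
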