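aln2 <- function(a, b) tibble::tibble(id = c("a", "b"), seq = c(a, b))

as_dnabin <- function(aln) {
  ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$seq), "")))
}

test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(p_distances(aln2("ACGT", "ACGT"))["a", "b"], 0)
  expect_equal(p_distances(aln2("ACGT", "ACGA"))["a", "b"], 0.25)
  # gap and ambiguity columns excluded under pairwise deletion
  expect_equal(p_distances(aln2("AC-T", "ACGT"))["a", "b"], 0)
  expect_equal(p_distances(aln2("ACKT", "ACGT"))["a", "b"], 0)
  expect_error(p_distances(aln2("NNNN", "ACGT")), "no comparable.*a / b")
})

test_that("deletion policies agree with the ape oracle", {
  withr::local_seed(21)
  for (k in 1:10) {
    a <- rand_dna(120)
    v <- strsplit(a, "")[[1]]
    pos <- sample(120, 12)  # ~10% divergence, well below saturation
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    b <- paste(v, collapse = "")
    al <- aln2(a, b)
    expect_equal(p_distances(al)["a", "b"],
                 as.numeric(ape::dist.dna(as_dnabin(al), model = "raw",
                                          pairwise.deletion = TRUE)))
    expect_equal(tn93_distances(al)["a", "b"],
                 as.numeric(ape::dist.dna(as_dnabin(al), model = "TN93")),
                 tolerance = 1e-10)
  }
  # complete deletion drops a column with a gap anywhere for every pair
  al3 <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c("ACGT", "ACGA", "AC-A"))
  expect_equal(p_distances(al3, deletion = "complete")["a", "b"], 1 / 3)
})

test_that("TN93 reduces to Kimura 2-parameter under symmetric frequencies", {
  # equal base frequencies and equal A<->G / C<->T transition proportions by
  # construction: every change is mirrored so per-pair frequencies stay 1/4
  const <- paste0(strrep("A", 9), strrep("C", 9), strrep("G", 10),
                  strrep("T", 10))
  a <- paste0(const, "AG", "CT", "AC")
  b <- paste0(const, "GA", "TC", "CA")
  L <- nchar(a)  # pooled base counts are 22/22/22/22: frequencies all 1/4
  P <- 4 / L  # total transitions
  Q <- 2 / L  # transversions
  k2p <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  expect_equal(tn93_distances(aln2(a, b))["a", "b"], k2p, tolerance = 1e-12)
})

test_that("TN93 approaches the p-distance for small divergence", {
  withr::local_seed(5)
  base <- rand_dna(600)
  ch <- strsplit(base, "")[[1]]
  pos <- sample(600, 4)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  al <- aln2(base, paste(ch, collapse = ""))
  d_p <- p_distances(al)["a", "b"]
  d_tn <- tn93_distances(al)["a", "b"]
  expect_gte(d_tn, d_p)              # the correction never shrinks a distance
  expect_equal(d_tn, d_p, tolerance = 0.05)  # first-order agreement
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  panel <- build_haplotype_panel(seed = 2)
  aln <- panel$alignment
  for (d in list(p_distances(aln), tn93_distances(aln))) {
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_equal(unname(diag(d)), rep(0, nrow(d)))
    expect_true(all(d >= 0))
  }
  expect_true(all(p_distances(aln) <= 1))
  expect_true(all(tn93_distances(aln) >= p_distances(aln) - 1e-12))
})

test_that("saturated pairs are flagged, not silently dropped", {
  # extreme divergence drives the transversion log argument non-positive
  a <- strrep("A", 40)
  b <- strrep("C", 40)
  expect_warning(d <- tn93_distances(aln2(a, b)), "saturated")
  expect_true(is.nan(d["a", "b"]))
  fl <- attr(d, "flagged")
  expect_equal(fl$code, "saturation")
  expect_setequal(c(fl$item1, fl$item2), c("a", "b"))
})

test_that("distance CSV export mirrors the lower triangle and tidies", {
  panel <- build_haplotype_panel(seed = 2)
  d <- p_distances(panel$alignment)
  f <- withr::local_tempfile(fileext = ".csv")
  write_distances(d, f)
  back <- readr::read_csv(f, col_types = readr::cols(), progress = FALSE)
  expect_equal(back$id, rownames(d))
  expect_equal(as.numeric(back$pectinata_A[back$id == "vaginata"]),
               d["vaginata", "pectinata_A"], tolerance = 1e-9)
  long <- generics::tidy(d)
  expect_equal(nrow(long), choose(nrow(d), 2))
})
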