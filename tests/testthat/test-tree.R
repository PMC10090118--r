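test_that("three taxa solve the closed-form three-point equations", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  co <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(co, d, tolerance = 1e-9)
})

test_that("an additive four-taxon matrix is recovered exactly", {
  # path-length matrix of ((A:1,B:2):1,(C:3,D:1))
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- nj_tree(d)
  co <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(co, d, tolerance = 1e-9)
})

test_that("NJ recovers random additive trees up to 8 leaves", {
  withr::local_seed(17)
  for (k in 1:12) {
    n <- sample(4:8, 1)
    true <- ape::unroot(ape::rtree(n, br = function(x) stats::runif(x, 0.05, 1)))
    d <- ape::cophenetic.phylo(true)
    tr <- nj_tree(d)
    co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(co, d, tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), true), 0)
    # independent cross-check against ape's NJ topology
    expect_equal(phangorn::RF.dist(ape::unroot(ape::nj(d)), ape::unroot(tr)), 0)
  }
})

test_that("branch lengths are never negative and input must be a metric", {
  # near-zero internal structure with noise tends to produce negative NJ
  # branches; the clamp moves the deficit to the sister branch
  withr::local_seed(23)
  for (k in 1:10) {
    n <- 6
    d <- matrix(stats::runif(n * n, 0.4, 0.6), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(bad), "3")
  d2 <- matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d2), "symmetric")
})

test_that("bootstrap separates two haplotype clusters with high support", {
  withr::local_seed(31)
  base <- rand_dna(300)
  ch <- strsplit(base, "")[[1]]
  pos <- sample(300, 20)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  other <- paste(ch, collapse = "")
  jitter1 <- function(s, i) {
    v <- strsplit(s, "")[[1]]
    v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  aln <- tibble::tibble(
    id = c(paste0("x", 1:5), paste0("y", 1:5)),
    seq = c(base, jitter1(base, 40), jitter1(base, 80), jitter1(base, 120),
            jitter1(base, 160),
            other, jitter1(other, 45), jitter1(other, 85), jitter1(other, 125),
            jitter1(other, 165))
  )
  tr <- bootstrap_support(aln, replicates = 100, seed = 99)
  sup <- split_support(tr, paste0("x", 1:5))
  expect_gte(sup, 95)

  # identical seed, identical supports; permuted rows, identical supports
  tr2 <- bootstrap_support(aln, replicates = 100, seed = 99)
  expect_identical(tr$node.label, tr2$node.label)
  perm <- aln[sample(nrow(aln)), ]
  tr3 <- bootstrap_support(perm, replicates = 100, seed = 99)
  expect_equal(split_support(tr3, paste0("x", 1:5)), sup)
})

test_that("identical sequences give a star-like tree with no supported splits", {
  aln <- tibble::tibble(id = paste0("s", 1:4), seq = rep(rand_dna(60), 4))
  tr <- bootstrap_support(aln, replicates = 20, seed = 1)
  expect_true(all(tr$edge.length < 1e-9))
  nwk <- to_newick(tr, support_min = 50)
  expect_false(grepl("\\)[0-9]", nwk))
})

test_that("the Newick display rule hides support at or below the threshold", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr$node.label <- c("", "49", "97")
  nwk <- to_newick(tr, support_min = 50)
  expect_false(grepl("49", nwk))
  expect_true(grepl("97", nwk))
  # write -> parse -> write is idempotent on topology, lengths and labels
  back <- ape::read.tree(text = nwk)
  expect_equal(to_newick(back, support_min = 0), nwk)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f, support_min = 50)
  expect_equal(readLines(f), nwk)
})
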