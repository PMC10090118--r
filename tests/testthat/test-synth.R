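test_that("panel generation is deterministic and invariant-clean", {
  p1 <- build_haplotype_panel(seed = 5)
  p2 <- build_haplotype_panel(seed = 5)
  expect_identical(p1$seqs, p2$seqs)
  expect_identical(p1$alignment, p2$alignment)
  expect_identical(p1$key$rules, p2$key$rules)
  expect_length(validate_panel(p1), 0L)

  p3 <- build_haplotype_panel(seed = 6)
  expect_false(identical(p1$seqs$seq, p3$seqs$seq))
  expect_error(build_haplotype_panel(seed = 1, length = 500), "600")
})

test_that("panel invariants hold across seeds and re-measurement", {
  for (seed in c(11, 12, 13)) {
    p <- build_haplotype_panel(seed = seed)
    expect_length(validate_panel(p), 0L)
    gc <- count_motif(p$seqs, "GCGC", mode = "strict")
    expect_equal(gc$count[gc$id == "vaginata"], 1L)
    expect_true(all(gc$count[gc$id != "vaginata"] == 2L))
    # the alignment equals base length + the 11 insertion columns
    expect_equal(alignment_length(p$alignment), p$base_length + 11L)
    # degapping recovers the ungapped haplotypes
    expect_equal(degap(p$alignment$seq[match(p$seqs$id, p$alignment$id)]),
                 p$seqs$seq)
  }
})

test_that("noiseless samples equal their haplotype; hybrids are IUPAC unions", {
  p <- build_haplotype_panel(seed = 7)
  s <- simulate_samples(p, composition = small_composition(), noise_rate = 0,
                        n_polymorphic = 0L, seed = 3)
  expect_equal(nrow(s), 11L)
  hap <- stats::setNames(p$seqs$seq, p$seqs$taxon)
  pure <- s[s$true_taxon != "hybrid(S. pectinata type B x S. macrocarpa)", ]
  expect_equal(pure$seq, unname(hap[pure$true_taxon]))

  hyb <- s$seq[s$true_taxon == "hybrid(S. pectinata type B x S. macrocarpa)"]
  expect_equal(hyb, iupac_union(hap[["S. pectinata type B"]],
                                hap[["S. macrocarpa"]]))
  amb <- ambiguity_profile(hyb)
  expect_equal(amb$n_ambiguous, 2L)  # exactly the diagnostic dinucleotide
})

test_that("noise respects the protected diagnostic and motif positions", {
  p <- build_haplotype_panel(seed = 8)
  s <- simulate_samples(p, composition = small_composition(2L),
                        noise_rate = 0.05, n_polymorphic = 2L,
                        ambiguity_extra_rate = 0.02, seed = 4)
  expect_true(any(s$n_noise > 0))
  aln <- align_progressive(
    dplyr::bind_rows(p$seqs[, c("id", "seq")],
                     dplyr::transmute(s, id = sample_id, seq = seq)))
  calls <- classify_samples(aln, p$key, samples = s$sample_id)
  cmp <- dplyr::left_join(calls, s, by = "sample_id")
  expect_equal(cmp$call, cmp$true_taxon)
})

test_that("identical seeds give byte-identical simulated samples", {
  p <- build_haplotype_panel(seed = 2)
  s1 <- simulate_samples(p, noise_rate = 0.01, n_polymorphic = 1L, seed = 9)
  s2 <- simulate_samples(p, noise_rate = 0.01, n_polymorphic = 1L, seed = 9)
  expect_identical(s1, s2)
})

test_that("fixtures round-trip through the package readers", {
  p <- build_haplotype_panel(seed = 10)
  s <- simulate_samples(p, composition = small_composition(), seed = 5)
  dir <- withr::local_tempdir()
  write_fixture(p, s, dir)
  expect_setequal(list.files(dir),
                  c("samples.fasta", "panel.fasta", "metadata.tsv",
                    "truth.tsv", "key.txt"))
  back <- read_fasta(file.path(dir, "samples.fasta"))
  expect_equal(back$seq, s$seq)
  panel_back <- read_fasta(file.path(dir, "panel.fasta"))
  expect_equal(panel_back$seq, p$seqs$seq)
  key_back <- read_key(file.path(dir, "key.txt"))
  expect_equal(key_back$rules$anchor, p$key$rules$anchor)
  # key anchors resolve uniquely on the re-loaded panel
  aln <- align_progressive(panel_back)
  expect_equal(nrow(locate_rules(aln, key_back)), nrow(p$key$rules))
  # a panel-only fixture is allowed
  dir2 <- withr::local_tempdir()
  write_fixture(p, s[0, ], dir2)
  expect_false(file.exists(file.path(dir2, "samples.fasta")))
  expect_true(file.exists(file.path(dir2, "panel.fasta")))
})

test_that("the default composition mirrors the published study design", {
  comp <- default_composition()
  expect_equal(nrow(comp), 28L)
  expect_equal(sum(comp$morphology_label == "S. pectinata"), 7L)
  expect_equal(sum(comp$morphology_label == "S. vaginata"), 7L)
  expect_equal(sum(comp$morphology_label == "S. macrocarpa"), 9L)
  expect_equal(sum(comp$morphology_label == "S. chakassiensis"), 5L)
  expect_equal(sum(comp$true_taxon == "hybrid"), 3L)
})
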