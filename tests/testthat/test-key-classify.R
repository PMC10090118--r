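# classification scenarios are built by appending crafted rows to the
# construction-true panel alignment, so every diagnostic column is known
panel <- build_haplotype_panel(seed = 3)
loc <- locate_rules(panel$alignment, panel$key)
with_sample <- function(gapped_seq, id = "q") {
  dplyr::bind_rows(panel$alignment, tibble::tibble(id = id, seq = gapped_seq))
}
row_of <- function(taxon) panel$alignment$seq[panel$alignment$id == taxon]
set_cols <- function(s, cols, chars) {
  v <- strsplit(s, "")[[1]]
  v[cols] <- chars
  paste(v, collapse = "")
}
di_cols <- loc$column[loc$role == "dinucleotide"]
sg_col <- loc$column[loc$role == "subgroup"]

test_that("the key file round-trips through its text serialization", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_key(panel$key, f)
  back <- read_key(f)
  expect_equal(back$reference, panel$key$reference)
  expect_equal(back$motif_expected, panel$key$motif_expected)
  expect_equal(back$rules$anchor, panel$key$rules$anchor)
  expect_equal(back$rules$states, panel$key$rules$states)
  expect_error(read_key(file.path(tempdir(), "none.txt")), "not found")
})

test_that("rules anchor uniquely and in the reference frame only", {
  expect_equal(nrow(loc), nrow(panel$key$rules))
  # nominal metadata positions are retained but anchoring is contextual
  expect_equal(loc$column[loc$name == "pos103"],
               loc$column[loc$name == "pos102"] + 1L)
  # the anchored column is where the reference's own residue sits
  ref <- panel$alignment$seq[panel$alignment$id == "pectinata_B"]
  expect_equal(unname(substr(ref, sg_col, sg_col)), "T")
  # a corrupted anchor fails loudly
  bad <- panel$key
  bad$rules$anchor[1] <- strrep("A", 10)
  expect_error(locate_rules(panel$alignment, bad), "anchor.*(not found|occurs)")
})

test_that("each pure haplotype is called as its generating taxon", {
  for (tx in c("vaginata", "pectinata_A", "pectinata_B", "macrocarpa",
               "chakassiensis")) {
    aln <- with_sample(row_of(tx))
    call <- classify_samples(aln, panel$key, samples = "q")
    expect_equal(call$call, unname(stuckenia:::TAXON_NAMES[[tx]]), info = tx)
    expect_equal(length(call$conflicts[[1]]), 0L, info = tx)
    expect_gt(nrow(call$evidence[[1]]), 0L)
  }
  # vaginata's evidence includes the single strict GCGC site
  call <- classify_samples(with_sample(row_of("vaginata")), panel$key,
                           samples = "q")
  expect_equal(call$motif_count, 1L)
})

test_that("IUPAC additivity at both dinucleotide positions calls a hybrid", {
  hyb <- iupac_union(row_of("pectinata_B"), row_of("macrocarpa"))
  call <- classify_samples(with_sample(hyb), panel$key, samples = "q")
  expect_equal(call$call, "hybrid(S. pectinata type B x S. macrocarpa)")
  obs <- call$evidence[[1]]
  expect_equal(obs$observed[obs$rule == "pos102"], "K")  # G + T
  expect_equal(obs$observed[obs$rule == "pos103"], "M")  # C + A
})

test_that("additivity at only one position is unresolved with a flag", {
  hyb <- iupac_union(row_of("pectinata_B"), row_of("macrocarpa"))
  half <- set_cols(hyb, di_cols[2], "C")  # back to the pure type-B state
  call <- classify_samples(with_sample(half), panel$key, samples = "q")
  expect_equal(call$call, "unresolved")
  expect_match(call$conflicts[[1]], "partial hybrid", all = FALSE)
})

test_that("the subgroup position separates type B from S. chakassiensis", {
  chakified <- set_cols(row_of("pectinata_B"), sg_col, "C")
  call <- classify_samples(with_sample(chakified), panel$key, samples = "q")
  expect_equal(call$call, "S. chakassiensis")
  backcross <- set_cols(row_of("chakassiensis"), sg_col, "T")
  call2 <- classify_samples(with_sample(backcross), panel$key, samples = "q")
  expect_equal(call2$call, "S. pectinata type B")
})

test_that("gaps at non-diagnostic positions never block a call", {
  # a type-A haplotype with a private deletion away from every diagnostic
  # site and motif must still be identified as type A
  protected <- c(loc$residue_index, panel$diagnostics$motifs[1] + 0:3,
                 panel$diagnostics$motifs[2] + 0:3)
  free <- setdiff(seq(30, panel$base_length - 30),
                  unlist(lapply(protected, function(p) (p - 12):(p + 12))))
  cols <- map_position(panel$alignment, "pectinata_A", free[1] + 0:1)
  gapped <- set_cols(row_of("pectinata_A"), cols, c("-", "-"))
  call <- classify_samples(with_sample(gapped), panel$key, samples = "q")
  expect_equal(call$call, "S. pectinata type A")
})

test_that("a motif-count disagreement is recorded, never dropped", {
  # destroy one GCGC site of a type-B sample at a non-diagnostic position
  m1 <- panel$diagnostics$motifs[1]
  col <- map_position(panel$alignment, "pectinata_B", m1 + 2L)
  broken <- set_cols(row_of("pectinata_B"), col, "A")
  call <- classify_samples(with_sample(broken), panel$key, samples = "q")
  expect_equal(call$call, "S. pectinata type B")
  expect_match(call$conflicts[[1]], "GCGC count 1", all = FALSE)
})

test_that("group partitioning follows the group definitions", {
  aln <- dplyr::bind_rows(
    panel$alignment,
    tibble::tibble(id = "hyb", seq = iupac_union(row_of("pectinata_B"),
                                                 row_of("macrocarpa")))
  )
  calls <- classify_samples(aln, panel$key, samples = setdiff(aln$id, "none"))
  groups <- partition_groups(calls)
  expect_equal(groups$group[groups$sample_id == "vaginata"], "I")
  expect_equal(groups$group[groups$sample_id == "pectinata_A"], "II")
  expect_setequal(groups$sample_id[groups$group == "III-I"],
                  c("pectinata_B", "macrocarpa", "hyb"))
  expect_equal(groups$group[groups$sample_id == "chakassiensis"], "III-II")

  none <- tibble::tibble(sample_id = c("u1", "u2"),
                         call = c("unresolved", "unresolved"))
  g2 <- partition_groups(none)
  expect_true(all(is.na(g2$group)))
})

test_that("ambiguity profiling finds positions and flags polymorphism", {
  prof <- ambiguity_profile(c("ACGT", "ACKT"))
  expect_equal(prof$ambiguity_fraction, c(0, 0.25))
  expect_equal(prof$positions[[2]], 3L)
  expect_false(prof$polymorphic[1])
  expect_true(prof$polymorphic[2])

  p <- build_haplotype_panel(seed = 9)
  s <- simulate_samples(p, composition = small_composition(),
                        n_polymorphic = 1L, ambiguity_extra_rate = 0.01,
                        seed = 12)
  prof2 <- ambiguity_profile(tibble::tibble(id = s$sample_id, seq = s$seq))
  expect_setequal(prof2$id[prof2$polymorphic],
                  s$sample_id[s$polymorphic_truth])
})

test_that("discordance honours synonymy, types and hybrid parentage", {
  calls <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    call = c("S. pectinata type B", "S. pectinata type B",
             "hybrid(S. pectinata type B x S. macrocarpa)",
             "hybrid(S. pectinata type B x S. macrocarpa)",
             "S. chakassiensis", "unresolved")
  )
  meta <- tibble::tibble(
    sample_id = paste0("s", c(1:6, 9)),
    morphology_label = c("S. vaginata", "Potamogeton pectinatus",
                         "S. macrocarpa", "S. vaginata",
                         "P. chakassiensis", "S. pectinata", "S. pectinata")
  )
  rep <- discordance_report(calls, meta)
  expect_equal(rep$concordant,
               c(FALSE, TRUE, TRUE, FALSE, TRUE, NA))
  expect_equal(attr(rep, "orphans"), "s9")
})
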