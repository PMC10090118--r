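# Seeded synthetic-haplotype generator.
#
# Builds a five-haplotype ITS1-ITS2-like panel that embodies, by
# construction, the known difference structure of the locus:
#   * S. vaginata vs either S. pectinata type: 3 indels (1, 1 and 9 nt,
#     realised as insertions in vaginata) and 16 one-nucleotide plus 2
#     two-nucleotide substitution runs, all at columns where types A and B
#     agree;
#   * S. pectinata type A vs type B: 5 one-nucleotide plus 1 two-nucleotide
#     substitution runs, no indels;
#   * S. macrocarpa = type B with a two-nucleotide state change at the
#     diagnostic dinucleotide (the "positions 102-103" analogue, GC -> TA);
#   * S. chakassiensis = type B with one T -> C change at the subgroup
#     position (the "position 524" analogue);
#   * two strict CfoI (GCGC) sites in every pectinata-clade haplotype, one
#     in vaginata (one vaginata substitution is constrained to hit the
#     third base of the second site).
# Every panel is re-verified against these invariants after construction
# and placement is retried (deterministically per seed) on failure.

BASES <- c("A", "C", "G", "T")

rand_other_base <- function(b) sample(setdiff(BASES, b), 1L)

# base-coordinate -> own-coordinate shift for a haplotype with insertions
shift_coord <- function(p, junctions, lengths) {
  p + sum(lengths[junctions < p])
}

place_intervals <- function(L, widths, occ, buffer = 2L, lo = 16L, hi = L - 15L,
                            max_tries = 2000L) {
  starts <- integer(length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample(lo:(hi - w + 1L), 1L)
      span <- max(1L, s - buffer):min(L, s + w - 1L + buffer)
      if (!any(occ[span])) {
        occ[span] <- TRUE
        starts[k] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  list(starts = starts, occ = occ)
}

apply_subs <- function(seq_chars_vec, pos, repl) {
  seq_chars_vec[pos] <- repl
  seq_chars_vec
}

#' Build a synthetic five-haplotype panel
#'
#' Deterministic per `seed`; edit placement is retried (with a derived
#' sub-seed per attempt) until every panel invariant verifies, and an error
#' names the violated constraint if `max_attempts` is exhausted.
#'
#' @param seed integer RNG seed.
#' @param length ungapped length of the pectinata-type-A base sequence
#'   (>= 600; default 700, the natural size of the locus).
#' @param max_attempts bound on placement retries.
#' @return A `haplotype_panel`: list with `seqs` (tibble `id`, `taxon`,
#'   `seq`, ungapped), `alignment` (the construction-true master alignment,
#'   vaginata insertions as gap columns in the other rows), `edits`
#'   (tibble of every planted event in base coordinates), `diagnostics`
#'   (base-coordinate positions of the dinucleotide, subgroup position and
#'   the two motifs), `key` (the matching [diagnostic_key()]) and `seed`.
#' @export
build_haplotype_panel <- function(seed = 1L, length = 700L,
                                  max_attempts = 100L) {
  stopifnot(length >= 600L)
  L <- as.integer(length)
  for (attempt in seq_len(max_attempts)) {
    set.seed((seed * 1009L + attempt) %% 2147483647L)
    panel <- try_build_panel(L, seed)
    if (is.null(panel)) next
    problems <- validate_panel(panel)
    if (!length(problems)) return(panel)
  }
  stop("panel generation failed after ", max_attempts,
       " attempts; last unsatisfied constraint: ",
       if (exists("problems") && length(problems)) problems[1]
       else "edit placement", call. = FALSE)
}

try_build_panel <- function(L, seed) {
  occ <- logical(L)
  # fixed-purpose intervals first
  pl <- place_intervals(L, widths = c(4L, 4L, 2L, 1L), occ = occ)
  if (is.null(pl)) return(NULL)
  m1 <- pl$starts[1]; m2 <- pl$starts[2]
  d <- pl$starts[3]; cpos <- pl$starts[4]
  occ <- pl$occ
  # A/B separator edits: 5 singles + 1 double
  pl <- place_intervals(L, widths = c(rep(1L, 5L), 2L), occ = occ)
  if (is.null(pl)) return(NULL)
  ab_pos <- pl$starts; occ <- pl$occ
  # vaginata substitutions: 15 free singles (the 16th hits motif2 base 3)
  # and 2 doubles
  pl <- place_intervals(L, widths = c(rep(1L, 15L), 2L, 2L), occ = occ)
  if (is.null(pl)) return(NULL)
  vg_pos <- pl$starts; occ <- pl$occ
  # vaginata insertion junctions (insert after these base positions);
  # the 9-nt block must keep >= 20 nt away from diagnostics and motifs
  pl <- place_intervals(L, widths = c(1L, 1L, 1L), occ = occ, buffer = 3L)
  if (is.null(pl)) return(NULL)
  ins_j <- pl$starts
  ins_len <- c(1L, 1L, 9L)
  guard <- c(m1:(m1 + 3L), m2:(m2 + 3L), d, d + 1L, cpos)
  if (min(abs(outer(ins_j[3], guard, `-`))) < 20L) return(NULL)

  base <- sample(BASES, L, replace = TRUE)
  base[m1:(m1 + 3L)] <- c("G", "C", "G", "C")
  base[m2:(m2 + 3L)] <- c("G", "C", "G", "C")
  base[d] <- "G"; base[d + 1L] <- "C"
  base[cpos] <- "T"
  # scrub accidental GCGC occurrences (a random 700-mer carries 2-3 of
  # them) so only the two planted sites remain; the diagnostic positions
  # themselves are never rewritten
  fixed_pos <- c(m1:(m1 + 3L), m2:(m2 + 3L), d, d + 1L, cpos)
  for (it in 1:50) {
    hits <- gregexpr("(?=GCGC)", paste(base, collapse = ""), perl = TRUE)[[1]]
    hits <- setdiff(hits[hits > 0L], c(m1, m2))
    if (!length(hits)) break
    for (s in hits) {
      p <- setdiff(s:(s + 3L), fixed_pos)[1]
      if (is.na(p)) return(NULL)
      base[p] <- rand_other_base(base[p])
    }
  }

  # pectinata A is the base; B carries the A/B edits
  ab_repl <- lapply(seq_along(ab_pos), function(k) {
    w <- if (k == 6L) 2L else 1L
    vapply(base[ab_pos[k] + seq_len(w) - 1L], rand_other_base, character(1))
  })
  pecB <- base
  for (k in seq_along(ab_pos)) {
    w <- length(ab_repl[[k]])
    pecB[ab_pos[k] + seq_len(w) - 1L] <- ab_repl[[k]]
  }
  macro <- pecB
  macro[d] <- "T"; macro[d + 1L] <- "A"
  chak <- pecB
  chak[cpos] <- "C"

  # vaginata substitutions relative to the base (= type A), incl. the forced
  # one destroying motif 2
  vg_sub_pos <- c(vg_pos[1:15], m2 + 2L)
  vg_dbl_pos <- vg_pos[16:17]
  vagi <- base
  for (p in vg_sub_pos) vagi[p] <- rand_other_base(base[p])
  for (p in vg_dbl_pos) {
    vagi[p] <- rand_other_base(base[p])
    vagi[p + 1L] <- rand_other_base(base[p + 1L])
  }
  ins_seq <- lapply(ins_len, function(l) sample(BASES, l, replace = TRUE))

  # assemble vaginata with its insertions (right to left)
  ordj <- order(ins_j, decreasing = TRUE)
  vagi_full <- vagi
  for (k in ordj) {
    j <- ins_j[k]
    vagi_full <- append(vagi_full, ins_seq[[k]], after = j)
  }

  # construction-true master alignment: gap blocks in the non-vaginata rows
  gap_row <- function(s) {
    out <- s
    for (k in order(ins_j, decreasing = TRUE)) {
      out <- append(out, rep("-", ins_len[k]), after = ins_j[k])
    }
    paste(out, collapse = "")
  }
  taxa <- names(TAXON_NAMES)
  hap <- list(vaginata = vagi_full, pectinata_A = base, pectinata_B = pecB,
              macrocarpa = macro, chakassiensis = chak)
  aln <- tibble::tibble(
    id = taxa,
    seq = unname(c(paste(vagi_full, collapse = ""),
                   vapply(hap[taxa[-1]], gap_row, character(1))))
  )
  seqs <- tibble::tibble(
    id = taxa,
    taxon = unname(TAXON_NAMES[taxa]),
    seq = unname(vapply(hap[taxa], function(x) paste(x, collapse = ""),
                        character(1)))
  )

  edits <- dplyr::bind_rows(
    tibble::tibble(taxon = "pectinata_B", kind = "substitution",
                   position = ab_pos,
                   length = vapply(ab_repl, length, integer(1))),
    tibble::tibble(taxon = "vaginata", kind = "substitution",
                   position = vg_sub_pos, length = 1L),
    tibble::tibble(taxon = "vaginata", kind = "substitution",
                   position = vg_dbl_pos, length = 2L),
    tibble::tibble(taxon = "vaginata", kind = "insertion",
                   position = ins_j, length = ins_len),
    tibble::tibble(taxon = "macrocarpa", kind = "substitution",
                   position = d, length = 2L),
    tibble::tibble(taxon = "chakassiensis", kind = "substitution",
                   position = cpos, length = 1L)
  )

  key <- panel_key(base, pecB, vagi, d, cpos, vg_sub_pos, ab_pos, ab_repl)
  structure(list(seqs = seqs, alignment = aln, edits = edits,
                 diagnostics = list(dinucleotide = d, subgroup = cpos,
                                    motifs = c(m1, m2),
                                    insertions = ins_j,
                                    insertion_lengths = ins_len),
                 key = key, base_length = L, seed = seed),
            class = "haplotype_panel")
}

# build the diagnostic key off the constructed haplotypes
panel_key <- function(base, pecB, vagi, d, cpos, vg_sub_pos, ab_pos, ab_repl) {
  refseq <- paste(pecB, collapse = "")
  anchor_at <- function(p) substr(refseq, p - 10L, p - 1L)
  all_taxa <- unname(TAXON_NAMES)
  states_at <- function(vagi_ch, a_ch, b_ch, macro_ch = b_ch, chak_ch = b_ch) {
    stats::setNames(c(vagi_ch, a_ch, b_ch, macro_ch, chak_ch), all_taxa)
  }
  vg_rules <- sort(vg_sub_pos)[1:3]
  ab_single <- sort(ab_pos[vapply(ab_repl, length, integer(1)) == 1L])[1:2]
  rules <- dplyr::bind_rows(
    purrr::map_dfr(seq_along(vg_rules), function(i) {
      p <- vg_rules[i]
      tibble::tibble(name = paste0("vag", i), role = "vaginata",
                     anchor = anchor_at(p), offset = 1L,
                     nominal_position = NA_integer_,
                     states = list(states_at(vagi[p], base[p], pecB[p])))
    }),
    purrr::map_dfr(seq_along(ab_single), function(i) {
      p <- ab_single[i]
      tibble::tibble(name = paste0("ab", i), role = "ab",
                     anchor = anchor_at(p), offset = 1L,
                     nominal_position = NA_integer_,
                     states = list(states_at(base[p], base[p], pecB[p])))
    }),
    tibble::tibble(name = "pos102", role = "dinucleotide",
                   anchor = anchor_at(d), offset = 1L,
                   nominal_position = 102L,
                   states = list(states_at("G", "G", "G", macro_ch = "T"))),
    tibble::tibble(name = "pos103", role = "dinucleotide",
                   anchor = anchor_at(d), offset = 2L,
                   nominal_position = 103L,
                   states = list(states_at("C", "C", "C", macro_ch = "A"))),
    tibble::tibble(name = "pos524", role = "subgroup",
                   anchor = anchor_at(cpos), offset = 1L,
                   nominal_position = 524L,
                   states = list(states_at("T", "T", "T", chak_ch = "C")))
  )
  motif_expected <- stats::setNames(c(1L, 2L, 2L, 2L, 2L), all_taxa)
  diagnostic_key(reference = "pectinata_B", rules = rules,
                 motif = "GCGC", motif_expected = motif_expected)
}

#' Verify a panel against its construction invariants
#'
#' Re-measures everything through the public profiling operations instead of
#' trusting the generator's bookkeeping: strict GCGC counts (2/2/2/2 for
#' the pectinata clade, 1 for vaginata), the vaginata-vs-type-A and
#' A-vs-B difference inventories, the single-event differences defining
#' *S. macrocarpa* and *S. chakassiensis*, and unique anchoring of every
#' key rule.
#'
#' @param panel a `haplotype_panel`.
#' @return character vector of violated constraints (empty when valid).
#' @export
validate_panel <- function(panel) {
  problems <- character()
  seqs <- panel$seqs
  gc <- count_motif(seqs, "GCGC", mode = "strict")
  want <- c(vaginata = 1L, pectinata_A = 2L, pectinata_B = 2L,
            macrocarpa = 2L, chakassiensis = 2L)
  bad <- gc$count != unname(want[gc$id])
  if (any(bad)) {
    problems <- c(problems, paste0("GCGC count for ", gc$id[bad][1], " is ",
                                   gc$count[bad][1], ", expected ",
                                   want[gc$id[bad][1]]))
  }
  aln <- panel$alignment

  inv <- function(a, b) summarize_diff_events(diff_events(aln, a, b))
  chk <- function(obs, kind, len, n, label) {
    hit <- obs$n[obs$kind == kind & obs$length == len]
    if (!length(hit)) hit <- 0L
    if (hit != n) {
      paste0(label, ": ", kind, " runs of length ", len, " = ", hit,
             ", expected ", n)
    } else character()
  }
  va <- inv("vaginata", "pectinata_A")
  problems <- c(problems,
                chk(va, "substitution", 1L, 16L, "vaginata vs type A"),
                chk(va, "substitution", 2L, 2L, "vaginata vs type A"),
                chk(va, "indel", 1L, 2L, "vaginata vs type A"),
                chk(va, "indel", 9L, 1L, "vaginata vs type A"))
  if (sum(va$n) != 21L) {
    problems <- c(problems, "vaginata vs type A: stray extra events")
  }
  ab <- inv("pectinata_A", "pectinata_B")
  problems <- c(problems,
                chk(ab, "substitution", 1L, 5L, "type A vs type B"),
                chk(ab, "substitution", 2L, 1L, "type A vs type B"))
  if (any(ab$kind == "indel") || sum(ab$n) != 6L) {
    problems <- c(problems, "type A vs type B: unexpected events")
  }
  bm <- inv("pectinata_B", "macrocarpa")
  if (!(nrow(bm) == 1L && bm$kind == "substitution" && bm$length == 2L)) {
    problems <- c(problems, "type B vs macrocarpa: not a single 2-nt substitution")
  }
  bc <- inv("pectinata_B", "chakassiensis")
  if (!(nrow(bc) == 1L && bc$kind == "substitution" && bc$length == 1L)) {
    problems <- c(problems, "type B vs chakassiensis: not a single 1-nt substitution")
  }
  loc <- tryCatch(locate_rules(aln, panel$key), error = function(e) e)
  if (inherits(loc, "error")) {
    problems <- c(problems, paste0("key anchoring: ", conditionMessage(loc)))
  }
  problems
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<synthetic haplotype panel>\n base length:", x$base_length,
      "nt, alignment columns:", alignment_length(x$alignment),
      "\n seed:", x$seed, "\n")
  print(x$seqs[, c("id", "taxon")])
  invisible(x)
}

#' Default simulated study composition
#'
#' Mirrors the published sampling design for this locus: 28 specimens whose
#' morphology-based labels split 7 pectinata / 7 vaginata / 9 macrocarpa /
#' 5 chakassiensis, while their true molecular identities are 2 vaginata,
#' 2 pectinata A, 7 pectinata B, 8 macrocarpa, 3 type-B x macrocarpa
#' hybrids and 6 chakassiensis — including the misidentified specimens the
#' discordance report is meant to expose.
#'
#' @return tibble with one row per sample: `true_taxon` (panel taxon id or
#'   `"hybrid"`) and `morphology_label`.
#' @export
default_composition <- function() {
  tibble::tibble(
    true_taxon = c(rep("vaginata", 2), rep("pectinata_A", 2),
                   rep("pectinata_B", 7), rep("macrocarpa", 8),
                   rep("hybrid", 3), rep("chakassiensis", 6)),
    morphology_label = c(
      rep("S. vaginata", 2),
      rep("S. pectinata", 2),
      c(rep("S. vaginata", 4), rep("S. pectinata", 3)),
      c(rep("S. macrocarpa", 7), "S. pectinata"),
      c("S. pectinata", "S. macrocarpa", "S. macrocarpa"),
      c(rep("S. chakassiensis", 5), "S. vaginata")
    )
  )
}

#' Simulate a sample set from a haplotype panel
#'
#' Noiseless samples equal their panel haplotype exactly; hybrid samples are
#' the position-wise IUPAC union of the type-B and macrocarpa parents
#' (ambiguity codes exactly at the diagnostic dinucleotide). Substitution
#' noise and extra ambiguity injection (the "polymorphic sample" signature
#' of a messy Sanger consensus) never touch diagnostic or motif positions,
#' so the simulated truth stays well-defined.
#'
#' @param panel a [build_haplotype_panel()] result.
#' @param composition per-sample tibble with `true_taxon` (a panel taxon id
#'   or `"hybrid"`) and optional `morphology_label`; defaults to
#'   [default_composition()].
#' @param noise_rate per-site substitution miscall rate in \[0, 0.05\].
#' @param ambiguity_extra_rate per-site rate of injected ambiguity codes for
#'   the `n_polymorphic` flagged samples, in \[0, 0.05\].
#' @param n_polymorphic how many samples receive extra ambiguities (chosen
#'   among the type-B samples when possible).
#' @param seed integer RNG seed.
#' @return A tibble with `sample_id`, `true_taxon` (display call name),
#'   `morphology_label`, `seq`, `n_noise`, `n_extra_ambiguity`,
#'   `polymorphic_truth`; this doubles as the truth table.
#' @export
simulate_samples <- function(panel, composition = default_composition(),
                             noise_rate = 0, ambiguity_extra_rate = 0.01,
                             n_polymorphic = 0L, seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 0.05,
            ambiguity_extra_rate >= 0, ambiguity_extra_rate <= 0.05)
  set.seed(seed %% 2147483647L)
  composition <- tibble::as_tibble(composition)
  if (!"morphology_label" %in% names(composition)) {
    composition$morphology_label <- "unknown"
  }
  hapseq <- stats::setNames(panel$seqs$seq, panel$seqs$id)
  hybrid_seq <- iupac_union(hapseq[["pectinata_B"]], hapseq[["macrocarpa"]])

  dg <- panel$diagnostics
  protected_base <- unique(c(
    locate_rules(panel$alignment, panel$key)$residue_index,  # reference frame
    dg$dinucleotide + 0:1, dg$subgroup,
    dg$motifs[1] + 0:3, dg$motifs[2] + 0:3
  ))

  n <- nrow(composition)
  which_poly <- integer(0)
  if (n_polymorphic > 0L) {
    cand <- which(composition$true_taxon == "pectinata_B")
    if (!length(cand)) cand <- seq_len(n)
    which_poly <- sort(sample(cand, min(n_polymorphic, length(cand))))
  }

  out <- purrr::map_dfr(seq_len(n), function(i) {
    taxon <- composition$true_taxon[i]
    if (taxon == "hybrid") {
      s <- hybrid_seq
      prot <- protected_base
    } else {
      s <- hapseq[[taxon]]
      prot <- if (taxon == "vaginata") {
        vapply(protected_base, shift_coord, integer(1),
               junctions = dg$insertions, lengths = dg$insertion_lengths)
      } else protected_base
    }
    ch <- seq_chars(s)
    free <- setdiff(which(is_unambiguous_base(ch)), prot)
    hit <- free[stats::runif(length(free)) < noise_rate]
    for (p in hit) ch[p] <- rand_other_base(ch[p])
    n_amb <- 0L
    if (i %in% which_poly) {
      free2 <- setdiff(free, hit)
      amb_hit <- free2[stats::runif(length(free2)) < ambiguity_extra_rate]
      for (p in amb_hit) {
        ch[p] <- seq_chars(iupac_union(ch[p], rand_other_base(ch[p])))
      }
      n_amb <- length(amb_hit)
    }
    tibble::tibble(
      sample_id = sprintf("sample_%02d", i),
      true_taxon = if (taxon == "hybrid") HYBRID_CALL else
        unname(TAXON_NAMES[[taxon]]),
      morphology_label = composition$morphology_label[i],
      seq = paste(ch, collapse = ""),
      n_noise = length(hit),
      n_extra_ambiguity = n_amb,
      polymorphic_truth = i %in% which_poly
    )
  })
  out
}

#' Write a reusable fixture directory
#'
#' Emits `samples.fasta`, `panel.fasta`, `metadata.tsv`, `truth.tsv` and
#' `key.txt`, all re-loadable by [read_fasta()], [read_metadata()] and
#' [read_key()].
#'
#' @param panel a `haplotype_panel`.
#' @param samples tibble from [simulate_samples()] (may have zero rows for a
#'   panel-only fixture).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(panel, samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dplyr::transmute(panel$seqs, id = .data$id, seq = .data$seq),
              file.path(dir, "panel.fasta"))
  if (nrow(samples)) {
    write_fasta(dplyr::transmute(samples, id = .data$sample_id,
                                 seq = .data$seq),
                file.path(dir, "samples.fasta"))
    readr::write_tsv(dplyr::select(samples, "sample_id", "morphology_label"),
                     file.path(dir, "metadata.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::select(samples, "sample_id", "true_taxon",
                                   "morphology_label", "polymorphic_truth"),
                     file.path(dir, "truth.tsv"), progress = FALSE)
  }
  write_key(panel$key, file.path(dir, "key.txt"))
  invisible(dir)
}
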