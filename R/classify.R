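# Species calling from the diagnostic key, hybrid detection from IUPAC
# additivity, group partitioning and morphology/molecule discordance.

#' Per-sequence ambiguity profile
#'
#' Proportion and positions (1-based, ungapped) of residues outside
#' A/C/G/T. Samples above the threshold are flagged polymorphic — the
#' signature of superimposed chromatogram peaks well beyond what a single
#' hybrid dinucleotide produces.
#'
#' @param seqs sequence data frame (`id`, `seq`) or character vector.
#' @param threshold ambiguity fraction above which a sample is flagged.
#' @return tibble with `id`, `n_ambiguous`, `ambiguity_fraction`,
#'   `positions` (list column), `polymorphic`.
#' @export
ambiguity_profile <- function(seqs, threshold = 0.005) {
  if (is.character(seqs)) seqs <- tibble::tibble(id = seq_along(seqs), seq = seqs)
  purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    ch <- seq_chars(degap(toupper(s)))
    pos <- which(!is_unambiguous_base(ch))
    tibble::tibble(id = id, n_ambiguous = length(pos),
                   ambiguity_fraction = length(pos) / length(ch),
                   positions = list(pos),
                   polymorphic = length(pos) / length(ch) > threshold)
  })
}

# expected state of `taxon` under a rule's states vector
rule_state <- function(states, taxon) unname(states[[taxon]])

# observed characters of one row at the located rule columns
observed_states <- function(aln, id, loc) {
  ch <- seq_chars(aln_row(aln, id))
  ch[loc$column]
}

classify_one <- function(sample_id, aln, key, loc, ambiguity_threshold) {
  obs <- observed_states(aln, sample_id, loc)
  rules <- key$rules
  taxa <- unname(TAXON_NAMES)

  evidence <- purrr::map_dfr(seq_len(nrow(rules)), function(k) {
    st <- rules$states[[k]]
    matched <- names(st)[st == obs[k]]
    tibble::tibble(rule = rules$name[k], column = loc$column[k],
                   observed = obs[k],
                   matched = paste(matched, collapse = ";"))
  })
  conflicts <- character()
  seq_ungapped <- degap(aln_row(aln, sample_id))
  motif_count <- count_motif(seq_ungapped, key$motif, mode = "strict")

  matches_all <- function(role, taxon) {
    k <- which(rules$role == role)
    length(k) > 0L &&
      all(vapply(k, function(i) obs[i] == rule_state(rules$states[[i]], taxon),
                 logical(1)))
  }
  some_match <- function(role, taxon) {
    k <- which(rules$role == role)
    any(vapply(k, function(i) obs[i] == rule_state(rules$states[[i]], taxon),
               logical(1)))
  }

  call <- NULL
  # (1) vaginata separator: the large difference set is primary evidence,
  #     the CfoI count corroborates
  if (matches_all("vaginata", TAXON_NAMES[["vaginata"]])) {
    call <- TAXON_NAMES[["vaginata"]]
  } else if (some_match("vaginata", TAXON_NAMES[["vaginata"]])) {
    conflicts <- c(conflicts,
                   "partial S. vaginata signal at the vaginata-diagnostic positions")
  }
  # (2) pectinata A vs B separator
  if (is.null(call) && matches_all("ab", TAXON_NAMES[["pectinata_A"]])) {
    call <- TAXON_NAMES[["pectinata_A"]]
  }
  # (3) B-like clade: diagnostic dinucleotide, then the subgroup position
  if (is.null(call)) {
    di <- which(rules$role == "dinucleotide")
    p1 <- key$hybrid_parents[1]
    p2 <- key$hybrid_parents[2]
    di_state <- function(i, taxon) rule_state(rules$states[[di[i]]], taxon)
    additive <- vapply(1:2, function(i) {
      obs[di[i]] == iupac_union(di_state(i, p1), di_state(i, p2))
    }, logical(1))
    b_state <- vapply(1:2, function(i) obs[di[i]] == di_state(i, p1), logical(1))
    m_state <- vapply(1:2, function(i) obs[di[i]] == di_state(i, p2), logical(1))
    if (all(b_state)) {
      sg <- which(rules$role == "subgroup")
      sg_obs <- obs[sg]
      if (length(sg) && all(vapply(seq_along(sg), function(i) {
        sg_obs[i] == rule_state(rules$states[[sg[i]]],
                                TAXON_NAMES[["chakassiensis"]])
      }, logical(1)))) {
        call <- TAXON_NAMES[["chakassiensis"]]
      } else {
        call <- TAXON_NAMES[["pectinata_B"]]
        bad <- which(vapply(seq_along(sg), function(i) {
          sg_obs[i] != rule_state(rules$states[[sg[i]]],
                                  TAXON_NAMES[["pectinata_B"]])
        }, logical(1)))
        if (length(bad)) {
          conflicts <- c(conflicts, paste0("unexpected state '",
                                           sg_obs[bad[1]], "' at subgroup rule ",
                                           rules$name[sg[bad[1]]]))
        }
      }
    } else if (all(m_state)) {
      call <- TAXON_NAMES[["macrocarpa"]]
    } else if (all(additive)) {
      call <- HYBRID_CALL
    } else if (any(additive)) {
      call <- UNRESOLVED_CALL
      conflicts <- c(conflicts, "partial hybrid signal: additivity at only one dinucleotide position")
    } else {
      call <- UNRESOLVED_CALL
      conflicts <- c(conflicts,
                     paste0("dinucleotide states '", obs[di[1]], obs[di[2]],
                            "' match no taxon or hybrid pattern"))
    }
  }
  # (4) motif corroboration: disagreement is recorded, never silently dropped
  expected_count <- if (call %in% names(key$motif_expected)) {
    key$motif_expected[[call]]
  } else if (call == HYBRID_CALL) {
    # both parents share the count; a hybrid should show it too
    key$motif_expected[[key$hybrid_parents[1]]]
  } else {
    NA_integer_
  }
  if (!is.na(expected_count) && motif_count != expected_count) {
    conflicts <- c(conflicts,
                   paste0("strict ", key$motif, " count ", motif_count,
                          " differs from the ", expected_count,
                          " expected for ", call))
  }

  amb <- ambiguity_profile(seq_ungapped, threshold = ambiguity_threshold)
  tibble::tibble(
    sample_id = sample_id,
    call = call,
    motif_count = motif_count,
    ambiguity_fraction = amb$ambiguity_fraction,
    polymorphic = amb$polymorphic,
    evidence = list(evidence),
    conflicts = list(conflicts)
  )
}

#' Call species for aligned samples using a diagnostic key
#'
#' Decision order, mirroring the dual sequence-class + restriction-site
#' argument used for this locus:
#' 1. all vaginata-diagnostic positions in the *S. vaginata* state ->
#'    *S. vaginata*;
#' 2. all A/B separator positions in the type-A state -> *S. pectinata*
#'    type A;
#' 3. otherwise the diagnostic dinucleotide decides within the B-like
#'    clade: type-B state -> the subgroup position separates *S. pectinata*
#'    type B from *S. chakassiensis*; macrocarpa state -> *S. macrocarpa*;
#'    the exact IUPAC additivity pattern at **both** positions -> hybrid;
#'    additivity at only one position -> unresolved with a partial-hybrid
#'    flag;
#' 4. anything else -> unresolved, with all partial evidence retained.
#'
#' The strict motif (CfoI) count is computed for every sample and any
#' disagreement with the called taxon's expectation is recorded as a
#' conflict. Gaps at non-diagnostic positions never block a call.
#'
#' @param aln alignment tibble containing the key's reference row and the
#'   samples.
#' @param key a [diagnostic_key()].
#' @param samples ids to classify; defaults to every row except the
#'   reference.
#' @param ambiguity_threshold passed to [ambiguity_profile()].
#' @return A tibble with one row per sample: `sample_id`, `call`,
#'   `motif_count`, `ambiguity_fraction`, `polymorphic`, `evidence`
#'   (list of per-rule observations) and `conflicts` (list of strings).
#' @export
classify_samples <- function(aln, key, samples = NULL,
                             ambiguity_threshold = 0.005) {
  aln <- check_alignment(aln)
  if (is.null(samples)) samples <- setdiff(aln$id, key$reference)
  missing <- setdiff(samples, aln$id)
  if (length(missing)) {
    stop("sample(s) absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  loc <- locate_rules(aln, key)
  purrr::map_dfr(samples, classify_one, aln = aln, key = key, loc = loc,
                 ambiguity_threshold = ambiguity_threshold)
}

#' Partition species calls into the tree groups
#'
#' Group I gathers the *S. vaginata* calls, group II *S. pectinata* type A,
#' subgroup III-I the type B + *S. macrocarpa* + hybrid calls, and subgroup
#' III-II *S. chakassiensis*. Unresolved samples receive `NA` and are
#' reported separately by [summarize_run()].
#'
#' @param calls tibble from [classify_samples()].
#' @return tibble with `sample_id`, `call`, `group`.
#' @export
partition_groups <- function(calls) {
  grp <- dplyr::case_when(
    calls$call == TAXON_NAMES[["vaginata"]] ~ "I",
    calls$call == TAXON_NAMES[["pectinata_A"]] ~ "II",
    calls$call %in% c(TAXON_NAMES[["pectinata_B"]], TAXON_NAMES[["macrocarpa"]],
                      HYBRID_CALL) ~ "III-I",
    calls$call == TAXON_NAMES[["chakassiensis"]] ~ "III-II",
    TRUE ~ NA_character_
  )
  tibble::tibble(sample_id = calls$sample_id, call = calls$call, group = grp)
}

# species epithets compatible with a molecular call (hybrids match either
# parent)
call_epithets <- function(call) {
  switch(call,
    "S. vaginata" = "vaginata",
    "S. pectinata type A" = "pectinata",
    "S. pectinata type B" = "pectinata",
    "S. macrocarpa" = "macrocarpa",
    "S. chakassiensis" = "chakassiensis",
    if (call == HYBRID_CALL) c("pectinata", "macrocarpa") else character()
  )
}

#' Morphology/molecule discordance report
#'
#' Joins molecular calls with morphology-based labels and flags each sample
#' concordant or discordant. Genus synonymy is ignored (Stuckenia and
#' Potamogeton combinations are equivalent), the two *S. pectinata*
#' haplotype types both count as *S. pectinata*, and a hybrid call is
#' concordant with either parent's label. Ids present on only one side are
#' not fatal: they are returned in attribute `"orphans"`.
#'
#' @param calls tibble from [classify_samples()].
#' @param metadata tibble from [read_metadata()].
#' @return tibble with `sample_id`, `morphology_label`, `call`,
#'   `concordant` (`NA` for unresolved calls); orphan ids in
#'   `attr(, "orphans")`.
#' @export
discordance_report <- function(calls, metadata) {
  joined <- dplyr::inner_join(
    dplyr::select(calls, "sample_id", "call"),
    dplyr::select(metadata, "sample_id", "morphology_label"),
    by = "sample_id"
  )
  out <- dplyr::mutate(
    joined,
    morphology_epithet = normalize_species_label(.data$morphology_label),
    concordant = purrr::map2_lgl(.data$call, .data$morphology_epithet,
                                 function(cl, ep) {
      if (cl == UNRESOLVED_CALL || ep == "unknown") return(NA)
      ep %in% call_epithets(cl)
    })
  )
  out <- dplyr::select(out, "sample_id", "morphology_label", "call",
                       "concordant")
  orphans <- c(setdiff(calls$sample_id, metadata$sample_id),
               setdiff(metadata$sample_id, calls$sample_id))
  attr(out, "orphans") <- orphans
  out
}
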