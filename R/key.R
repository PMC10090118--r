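# The diagnostic key: context-anchored diagnostic positions, expected
# states per taxon, and restriction-motif count expectations.
#
# Diagnostic positions are anchored by a 10-nt 5' context string taken from
# a named reference haplotype, not by absolute alignment column numbers:
# column numbering is an artifact of a particular alignment run, while the
# flanking sequence context travels with the data. The historically used
# column numbers (102, 103, 524) are retained as nominal metadata only.

#' Display names of the recognised taxa and calls
#' @noRd
TAXON_NAMES <- c(
  vaginata      = "S. vaginata",
  pectinata_A   = "S. pectinata type A",
  pectinata_B   = "S. pectinata type B",
  macrocarpa    = "S. macrocarpa",
  chakassiensis = "S. chakassiensis"
)
HYBRID_CALL <- "hybrid(S. pectinata type B x S. macrocarpa)"
UNRESOLVED_CALL <- "unresolved"

RULE_ROLES <- c("vaginata", "ab", "dinucleotide", "subgroup")

#' Construct a diagnostic key
#'
#' @param reference id of the reference haplotype whose (ungapped) sequence
#'   the rule anchors are taken from; this row must be present in any
#'   alignment the key is applied to.
#' @param rules tibble with columns `name`, `role` (one of `"vaginata"`,
#'   `"ab"`, `"dinucleotide"`, `"subgroup"`), `anchor` (5' context string in
#'   the reference, unique there), `offset` (residues downstream of the
#'   anchor end, usually 1), `nominal_position` (historical column number or
#'   `NA`) and `states` (list column of named single-letter expected states,
#'   names being taxon display names).
#' @param motif recognition motif counted as corroboration (CfoI: `GCGC`).
#' @param motif_expected named integer vector, expected strict motif count
#'   per taxon display name.
#' @param hybrid_parents length-2 character, the two taxa whose ambiguity
#'   additivity at the `dinucleotide` rules defines a hybrid call.
#' @return A `diagnostic_key` object.
#' @export
diagnostic_key <- function(reference, rules, motif = "GCGC",
                           motif_expected,
                           hybrid_parents = c("S. pectinata type B",
                                              "S. macrocarpa")) {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("name", "role", "anchor", "offset", "states") %in% names(rules)),
            all(rules$role %in% RULE_ROLES),
            !anyDuplicated(rules$name),
            length(hybrid_parents) == 2L)
  if (!"nominal_position" %in% names(rules)) rules$nominal_position <- NA_integer_
  for (st in rules$states) {
    stopifnot(all(nchar(st) == 1L), all(unlist(st) %in% IUPAC_LETTERS))
  }
  stopifnot(sum(rules$role == "dinucleotide") == 2L)
  structure(list(reference = reference, rules = rules, motif = toupper(motif),
                 motif_expected = motif_expected,
                 hybrid_parents = hybrid_parents),
            class = "diagnostic_key")
}

#' @export
print.diagnostic_key <- function(x, ...) {
  cat("<diagnostic key>\n reference:", x$reference, "\n motif:", x$motif,
      "expected:", paste(names(x$motif_expected), x$motif_expected,
                         sep = "=", collapse = ", "), "\n")
  print(dplyr::select(x$rules, -"states"))
  invisible(x)
}

#' Write a diagnostic key to a human-editable text file
#'
#' Serialized as YAML; see [read_key()].
#'
#' @param key a [diagnostic_key()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_key <- function(key, path) {
  obj <- list(
    reference = key$reference,
    motif = key$motif,
    motif_expected = as.list(key$motif_expected),
    hybrid_parents = key$hybrid_parents,
    rules = purrr::pmap(key$rules, function(name, role, anchor, offset,
                                            nominal_position, states) {
      list(name = name, role = role, anchor = anchor, offset = offset,
           nominal_position = nominal_position, states = as.list(states))
    })
  )
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' Read a diagnostic key from file
#' @param path path to a key file written by [write_key()].
#' @return A [diagnostic_key()].
#' @export
read_key <- function(path) {
  if (!file.exists(path)) stop("key file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(obj$rules, function(r) {
    tibble::tibble(name = r$name, role = r$role, anchor = r$anchor,
                   offset = as.integer(r$offset),
                   nominal_position = if (is.null(r$nominal_position))
                     NA_integer_ else as.integer(r$nominal_position),
                   states = list(unlist(r$states)))
  })
  diagnostic_key(reference = obj$reference, rules = rules, motif = obj$motif,
                 motif_expected = unlist(obj$motif_expected),
                 hybrid_parents = obj$hybrid_parents)
}

#' Resolve diagnostic rules to alignment columns
#'
#' Each rule's anchor must occur exactly once in the degapped reference row;
#' the rule's target is the residue `offset` positions after the anchor end,
#' mapped into alignment-column coordinates with [map_position()].
#'
#' @param aln alignment tibble containing the key's reference row.
#' @param key a [diagnostic_key()].
#' @return tibble with `name`, `role`, `residue_index` (reference ungapped
#'   coordinate) and `column` (alignment column).
#' @export
locate_rules <- function(aln, key) {
  ref <- degap(aln_row(aln, key$reference))
  purrr::pmap_dfr(key$rules, function(name, role, anchor, offset, ...) {
    hits <- gregexpr(anchor, ref, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      stop("anchor for rule '", name, "' not found in reference '",
           key$reference, "'", call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop("anchor for rule '", name, "' occurs ", length(hits),
           " times in reference '", key$reference, "'", call. = FALSE)
    }
    idx <- hits[1] + nchar(anchor) - 1L + offset
    tibble::tibble(name = name, role = role, residue_index = idx,
                   column = map_position(aln, key$reference, idx))
  })
}
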