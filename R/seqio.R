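# Sequence and metadata I/O.
#
# Sequences travel through the package as tibbles with columns
#   id   - unique record identifier (FASTA header up to first whitespace)
#   note - remainder of the FASTA header, kept opaque ("" when absent)
#   seq  - uppercase IUPAC residues, gapped only in alignment mode
# so every downstream verb is a plain data-frame-in / tibble-out function.

#' Controlled morphology vocabulary of the Stuckenia panel
#'
#' Species epithets recognised by the diagnostic key, under either generic
#' name (*Stuckenia* or the older *Potamogeton* combinations).
#' @noRd
PANEL_EPITHETS <- c("vaginata", "pectinata", "macrocarpa", "chakassiensis")

#' Normalize a morphology label to its species epithet
#'
#' Strips the generic name (Stuckenia and Potamogeton binomials are treated
#' as synonyms) and Latin gender endings, so "S. pectinata", "Stuckenia
#' pectinata" and "P. pectinatus" all normalize to "pectinata".
#'
#' @param x character vector of labels.
#' @return lowercase species epithets ("unknown" passes through).
#' @export
normalize_species_label <- function(x) {
  out <- tolower(trimws(x))
  out[is.na(out) | out == ""] <- "unknown"
  # drop generic name or its abbreviation
  out <- sub("^(stuckenia|potamogeton|s\\.|p\\.)\\s*", "", out)
  out <- trimws(out)
  # masculine Potamogeton combinations (pectinatus, vaginatus, macrocarpus)
  out <- sub("us$", "a", out)
  out
}

#' Read sequences from a FASTA file
#'
#' Residues are validated against the 15-letter IUPAC nucleotide alphabet and
#' stored uppercase. In the default unaligned mode any gap characters are
#' stripped with a warning; with `aligned = TRUE` gaps (`-`, with `.`
#' normalized to `-`) are preserved and all records must share one length.
#'
#' @param path path to a FASTA file (UTF-8).
#' @param aligned logical; read as an alignment, keeping gap columns.
#' @return A tibble with columns `id`, `note`, `seq`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "acgt", ">s2", "ACGA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  notes <- character()
  seqs <- character()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (!nzchar(cur$seq)) {
      stop("empty record '", cur$id, "' (header at line ", cur$line, ")",
           call. = FALSE)
    }
    ids <<- c(ids, cur$id)
    notes <<- c(notes, cur$note)
    seqs <<- c(seqs, cur$seq)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i], which = "right")
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      if (!nzchar(trimws(header))) {
        stop("malformed FASTA header at line ", i, ": empty id", call. = FALSE)
      }
      id <- sub("\\s.*$", "", header)
      note <- sub("^\\S+\\s*", "", header)
      cur <- list(id = id, note = note, seq = "", line = i)
    } else {
      if (is.null(cur)) {
        stop("sequence data before any FASTA header at line ", i, call. = FALSE)
      }
      chunk <- gsub("\\s", "", ln)
      bad <- regexpr(sprintf("[^%s.\\-]", paste(IUPAC_LETTERS, collapse = "")),
                     toupper(chunk))
      if (bad > 0L) {
        stop("illegal character '", substr(chunk, bad, bad), "' at line ", i,
             ", position ", bad, " (record '", cur$id, "')", call. = FALSE)
      }
      cur$seq <- paste0(cur$seq, chunk)
    }
  }
  flush()
  if (!length(ids)) stop("no FASTA records in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- validate_residues(seqs, allow_gap = TRUE, ids = ids)
  if (aligned) {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("aligned mode requires equal-length records", call. = FALSE)
    }
  } else if (any(grepl("-", seqs, fixed = TRUE))) {
    warning("gap characters stripped from unaligned input", call. = FALSE)
    seqs <- gsub("-", "", seqs, fixed = TRUE)
    seqs <- validate_residues(seqs, ids = ids)  # re-check non-empty
  }
  tibble::tibble(id = ids, note = notes, seq = seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs data frame with columns `id` and `seq` (an optional `note`
#'   column is appended to the header after a space).
#' @param path output path.
#' @param wrap positive line width for sequence wrapping.
#' @return `path`, invisibly. Round-trips through [read_fasta()] on
#'   (`id`, `seq`).
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  stopifnot(is.data.frame(seqs), wrap >= 1L)
  if (!nrow(seqs)) {
    warning("writing an empty FASTA file", call. = FALSE)
    writeLines(character(), path)
    return(invisible(path))
  }
  notes <- if ("note" %in% names(seqs)) seqs$note else rep("", nrow(seqs))
  headers <- ifelse(nzchar(notes) & !is.na(notes),
                    paste0(">", seqs$id, " ", notes),
                    paste0(">", seqs$id))
  chunks <- purrr::map2(seqs$seq, headers, function(s, h) {
    starts <- seq(1L, nchar(s), by = wrap)
    c(h, substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Expects a UTF-8 TSV with a header row containing at least `sample_id` and
#' `morphology_label`. Labels outside the controlled Stuckenia panel
#' vocabulary (the four species under either generic name, or "unknown") are
#' kept but flagged `in_panel = FALSE` with a warning — exposing
#' misidentification is part of the pipeline's job, so odd labels are never
#' fatal.
#'
#' @param path path to the TSV file.
#' @return A tibble with columns `sample_id`, `morphology_label`,
#'   `species_epithet` (normalized), `in_panel`, plus any extra columns
#'   (e.g. `accession`, provenance notes) passed through.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample_id", "morphology_label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  tab <- dplyr::mutate(
    tab,
    species_epithet = normalize_species_label(.data$morphology_label),
    in_panel = .data$species_epithet %in% c(PANEL_EPITHETS, "unknown")
  )
  if (any(!tab$in_panel)) {
    warning("morphology label(s) outside the panel vocabulary: ",
            paste(unique(tab$morphology_label[!tab$in_panel]), collapse = ", "),
            call. = FALSE)
  }
  tab
}
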