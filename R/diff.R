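# Pairwise difference profiling: the inventory of indel and
# substitution-run events separating two aligned sequences, as used to
# characterize the Stuckenia ITS1-ITS2 haplotype classes (e.g. S. vaginata
# vs S. pectinata: three indels of 1/1/9 nt plus sixteen 1-nt and two 2-nt
# substitution runs).

#' Extract maximal difference events between two alignment rows
#'
#' Each alignment column of the pair is classified as identical,
#' substitution (both rows a residue, different character), insertion (gap
#' in row `a`) or deletion (gap in row `b`); adjacent columns of the same
#' kind are merged into one maximal event. Character identity is literal,
#' so an ambiguity code differing from a base counts as a substitution.
#' Columns gapped in both rows (possible when a pair is projected out of a
#' larger alignment) are transparent: they are skipped and do not split a
#' run. Event kinds are oriented as edits transforming row `a` into row
#' `b`.
#'
#' @param aln alignment tibble containing rows `a` and `b`.
#' @param a,b row ids; default the first two rows.
#' @return A tibble with columns `kind` (`substitution`/`insertion`/
#'   `deletion`), `column` (1-based alignment column of the run start),
#'   `length` (columns in the run), `a`, `b` (the two run strings, gaps
#'   included).
#' @export
diff_events <- function(aln, a = aln$id[1], b = aln$id[2]) {
  ra <- seq_chars(aln_row(aln, a))
  rb <- seq_chars(aln_row(aln, b))
  stopifnot(length(ra) == length(rb))
  keep <- !(ra == "-" & rb == "-")
  cols <- which(keep)
  ca <- ra[keep]
  cb <- rb[keep]
  kind <- rep(NA_character_, length(ca))
  kind[ca == "-" & cb != "-"] <- "insertion"
  kind[ca != "-" & cb == "-"] <- "deletion"
  kind[ca != "-" & cb != "-" & ca != cb] <- "substitution"

  diffpos <- which(!is.na(kind))
  if (!length(diffpos)) {
    return(tibble::tibble(kind = character(), column = integer(),
                          length = integer(), a = character(),
                          b = character()))
  }
  # split into maximal runs: same kind and consecutive (in the compacted frame)
  brk <- c(TRUE, diff(diffpos) > 1L |
             kind[diffpos[-1]] != kind[diffpos[-length(diffpos)]])
  run <- cumsum(brk)
  purrr::map_dfr(split(diffpos, run), function(p) {
    tibble::tibble(kind = kind[p[1]],
                   column = cols[p[1]],
                   length = length(p),
                   a = paste(ca[p], collapse = ""),
                   b = paste(cb[p], collapse = ""))
  })
}

#' Replay difference events onto a sequence
#'
#' Applies the events from [diff_events()] for the pair (`a`, `b`) to the
#' gapped row `a` and returns the ungapped result, which equals the degapped
#' row `b` — the round-trip property of the event inventory.
#'
#' @param aln alignment tibble.
#' @param a id of the source row.
#' @param events tibble from [diff_events()] oriented a -> b.
#' @return Ungapped sequence string.
#' @export
apply_diff_events <- function(aln, a, events) {
  ch <- seq_chars(aln_row(aln, a))
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    # the b-run may skip transparent both-gap columns; write char by char
    tgt <- seq_chars(ev$b)
    pos <- ev$column
    written <- 0L
    while (written < length(tgt)) {
      if (!(ch[pos] == "-" && ev$kind == "substitution")) {
        written <- written + 1L
        ch[pos] <- tgt[written]
      }
      pos <- pos + 1L
    }
  }
  degap(paste(ch, collapse = ""))
}

#' Summarize a difference-event inventory
#'
#' Counts events by kind and run length — the shape in which haplotype
#' differences are reported for this locus (e.g. "three indels (1/1/9 nt),
#' sixteen 1-nt and two 2-nt substitutions").
#'
#' @param events tibble from [diff_events()].
#' @return tibble with `kind`, `length`, `n`.
#' @export
summarize_diff_events <- function(events) {
  ev <- dplyr::mutate(events,
                      kind = ifelse(.data$kind %in% c("insertion", "deletion"),
                                    "indel", .data$kind))
  dplyr::count(ev, .data$kind, .data$length, name = "n")
}
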