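# End-to-end orchestration: read -> align (or import) -> distance matrices
# -> NJ + bootstrap -> difference profiling vs references -> classification
# -> grouping -> discordance -> summary, with every artifact written as
# plain text and the whole run bit-reproducible under a fixed seed.

#' Pipeline run configuration
#'
#' All paths are checked up front, before any stage runs; the configuration
#' is echoed verbatim into `run.log`.
#'
#' @param fasta sample FASTA path.
#' @param key key file path (see [read_key()]) or a [diagnostic_key()].
#' @param out_dir output directory for run artifacts.
#' @param metadata optional morphology metadata TSV path.
#' @param reference_fasta optional FASTA of reference haplotypes to be
#'   co-aligned (must contain the key's reference id unless it is already
#'   among the samples).
#' @param aligned optional aligned-FASTA path; when given, this external
#'   alignment (e.g. a ClustalW product) is imported instead of running the
#'   internal progressive aligner, and it must contain every sample and
#'   reference id.
#' @param scheme [scoring_scheme()] for the internal aligner.
#' @param deletion distance deletion policy (`"pairwise"`/`"complete"`).
#' @param model distance model for the tree (`"tn93"`/`"p"`).
#' @param bootstrap bootstrap replicate count (study default 1000).
#' @param seed single RNG seed for every stochastic stage.
#' @param support_min bootstrap display threshold (percent).
#' @param ambiguity_threshold polymorphic-sample flag threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, key, out_dir, metadata = NULL,
                       reference_fasta = NULL, aligned = NULL,
                       scheme = scoring_scheme(),
                       deletion = c("pairwise", "complete"),
                       model = c("tn93", "p"),
                       bootstrap = 1000L, seed = 42L, support_min = 50,
                       ambiguity_threshold = 0.005) {
  deletion <- match.arg(deletion)
  model <- match.arg(model)
  for (p in c(fasta, metadata, reference_fasta, aligned,
              if (is.character(key)) key)) {
    if (!file.exists(p)) stop("config error: path not found: ", p, call. = FALSE)
  }
  structure(list(fasta = fasta, key = key, out_dir = out_dir,
                 metadata = metadata, reference_fasta = reference_fasta,
                 aligned = aligned, scheme = scheme, deletion = deletion,
                 model = model, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed), support_min = support_min,
                 ambiguity_threshold = ambiguity_threshold),
            class = "run_config")
}

flatten_calls <- function(calls) {
  dplyr::mutate(
    dplyr::select(calls, -"evidence", -"conflicts"),
    evidence = vapply(calls$evidence, function(e) {
      paste(paste0(e$rule, ":", e$observed), collapse = ",")
    }, character(1)),
    conflicts = vapply(calls$conflicts, paste, character(1), collapse = "; ")
  )
}

#' Run the full identification pipeline
#'
#' Executes every stage in order and writes `aligned.fasta`,
#' `distances.csv`, `distances_tn93.csv`, `tree.nwk`, `diffs.tsv`,
#' `calls.tsv`, `groups.tsv`, `discordance.tsv` (when metadata is given),
#' `summary.txt` and `run.log` into the output directory. A stage failure
#' propagates as an error naming the stage; artifacts of completed stages
#' are retained.
#'
#' @param config a [run_config()].
#' @return A `stuckenia_run` object (list with the in-memory alignment,
#'   distance matrices, tree, calls, groups, discordance and `dir`),
#'   invisibly printable; artifacts live in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("stuckenia ", as.character(utils::packageVersion("stuckenia")),
           " | R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("seed: ", config$seed),
    "config:",
    paste0("  ", utils::capture.output(utils::str(config[
      !vapply(config, is.function, logical(1))], give.attr = FALSE)))
  )
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage '", name, "': ",
                                     conditionMessage(e))),
                 file.path(config$out_dir, "run.log"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-14s %.2fs", name,
                                       proc.time()[["elapsed"]] - s))
    out
  }

  key <- if (is.character(config$key)) read_key(config$key) else config$key
  inp <- stage("read", {
    samples <- read_fasta(config$fasta)
    refs <- if (!is.null(config$reference_fasta)) {
      read_fasta(config$reference_fasta)
    } else NULL
    meta <- if (!is.null(config$metadata)) read_metadata(config$metadata) else NULL
    list(samples = samples, refs = refs, meta = meta)
  })
  all_ids <- c(if (!is.null(inp$refs)) inp$refs$id, inp$samples$id)
  if (anyDuplicated(all_ids)) {
    stop("stage 'read' failed: sample and reference ids overlap", call. = FALSE)
  }

  aln <- stage("align", {
    if (!is.null(config$aligned)) {
      ext <- read_fasta(config$aligned, aligned = TRUE)
      missing <- setdiff(all_ids, ext$id)
      if (length(missing)) {
        stop("external alignment lacks id(s): ",
             paste(missing, collapse = ", "))
      }
      check_alignment(ext[match(all_ids, ext$id), ])
    } else {
      pool <- dplyr::bind_rows(
        if (!is.null(inp$refs)) inp$refs[c("id", "seq")],
        inp$samples[c("id", "seq")]
      )
      align_progressive(pool, scheme = config$scheme)
    }
  })
  stage("write-alignment", {
    write_fasta(aln, file.path(config$out_dir, "aligned.fasta"))
  })

  dists <- stage("distances", {
    dp <- p_distances(aln, deletion = config$deletion)
    dt <- suppressWarnings(tn93_distances(aln, deletion = config$deletion))
    write_distances(dp, file.path(config$out_dir, "distances.csv"))
    write_distances(dt, file.path(config$out_dir, "distances_tn93.csv"))
    list(p = dp, tn93 = dt)
  })

  tree <- stage("tree", {
    tr <- bootstrap_support(aln, replicates = config$bootstrap,
                            seed = config$seed, model = config$model,
                            deletion = config$deletion)
    write_newick(tr, file.path(config$out_dir, "tree.nwk"),
                 support_min = config$support_min)
    tr
  })

  diffs <- stage("diff-profile", {
    ref_ids <- if (!is.null(inp$refs)) inp$refs$id else key$reference
    ref_ids <- intersect(ref_ids, aln$id)
    out <- purrr::map_dfr(inp$samples$id, function(sid) {
      purrr::map_dfr(ref_ids, function(rid) {
        ev <- diff_events(aln, rid, sid)
        if (!nrow(ev)) return(NULL)
        dplyr::mutate(ev, sample_id = sid, reference = rid, .before = 1)
      })
    })
    readr::write_tsv(out, file.path(config$out_dir, "diffs.tsv"),
                     progress = FALSE)
    out
  })

  calls <- stage("classify", {
    cl <- classify_samples(aln, key, samples = inp$samples$id,
                           ambiguity_threshold = config$ambiguity_threshold)
    readr::write_tsv(flatten_calls(cl), file.path(config$out_dir, "calls.tsv"),
                     progress = FALSE)
    cl
  })

  groups <- stage("group", {
    g <- partition_groups(calls)
    readr::write_tsv(g, file.path(config$out_dir, "groups.tsv"),
                     progress = FALSE)
    g
  })

  disc <- if (!is.null(inp$meta)) {
    stage("discordance", {
      dr <- discordance_report(calls, inp$meta)
      readr::write_tsv(dr, file.path(config$out_dir, "discordance.tsv"),
                       progress = FALSE)
      dr
    })
  } else NULL

  run <- structure(list(config = config, alignment = aln, distances = dists,
                        tree = tree, diffs = diffs, calls = calls,
                        groups = groups, discordance = disc,
                        dir = config$out_dir),
                   class = "stuckenia_run")
  stage("summary", {
    writeLines(summarize_run(run), file.path(config$out_dir, "summary.txt"))
  })
  log_lines <- c(log_lines,
                 sprintf("total %.2fs", proc.time()[["elapsed"]] - t0))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(run)
}

#' Summarize a pipeline run
#'
#' Counts per species call and per tree group, plus the hybrid, discordant,
#' unresolved and polymorphic-flagged sample lists.
#'
#' @param run a `stuckenia_run` object or a run directory path.
#' @return character vector of summary lines.
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    if (!file.exists(file.path(run, "calls.tsv"))) {
      stop("incomplete run: no calls.tsv under ", run, call. = FALSE)
    }
    calls <- readr::read_tsv(file.path(run, "calls.tsv"),
                             col_types = readr::cols(), progress = FALSE)
    groups <- readr::read_tsv(file.path(run, "groups.tsv"),
                              col_types = readr::cols(), progress = FALSE)
    disc_path <- file.path(run, "discordance.tsv")
    disc <- if (file.exists(disc_path)) {
      readr::read_tsv(disc_path, col_types = readr::cols(), progress = FALSE)
    } else NULL
    partial <- !file.exists(file.path(run, "summary.txt"))
  } else {
    calls <- run$calls
    groups <- run$groups
    disc <- run$discordance
    partial <- FALSE
  }
  lines <- c(sprintf("samples: %d", nrow(calls)), "calls:")
  tab <- dplyr::count(calls, .data$call)
  lines <- c(lines, sprintf("  %-45s %d", tab$call, tab$n), "groups:")
  gt <- dplyr::count(dplyr::filter(groups, !is.na(.data$group)), .data$group)
  lines <- c(lines, sprintf("  %-8s %d", gt$group, gt$n))
  hyb <- calls$sample_id[calls$call == HYBRID_CALL]
  lines <- c(lines, paste0("hybrids: ",
                           if (length(hyb)) paste(hyb, collapse = ", ")
                           else "none"))
  unres <- calls$sample_id[calls$call == UNRESOLVED_CALL]
  lines <- c(lines, paste0("unresolved: ",
                           if (length(unres)) paste(unres, collapse = ", ")
                           else "none"))
  poly <- calls$sample_id[calls$polymorphic]
  lines <- c(lines, paste0("flagged polymorphic: ",
                           if (length(poly)) paste(poly, collapse = ", ")
                           else "none"))
  if (!is.null(disc)) {
    bad <- disc$sample_id[!is.na(disc$concordant) & !disc$concordant]
    lines <- c(lines, paste0("morphology/molecule discordant: ",
                             if (length(bad)) paste(bad, collapse = ", ")
                             else "none"))
  }
  if (partial) lines <- c("PARTIAL SUMMARY (run incomplete)", lines)
  lines
}

#' @export
print.stuckenia_run <- function(x, ...) {
  cat("<stuckenia pipeline run>\n dir:", x$dir, "\n")
  cat(summarize_run(x), sep = "\n")
  invisible(x)
}

#' Simulate a fixture and analyze it in one call
#'
#' Chains the generator and the pipeline under a single seed: builds a
#' panel, simulates the default study composition, writes the fixture under
#' `out_dir/fixture`, and analyzes it into `out_dir/run`.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving generator and bootstrap (sub-seeds are
#'   derived deterministically).
#' @param bootstrap bootstrap replicate count.
#' @param noise_rate,n_polymorphic forwarded to [simulate_samples()].
#' @return the `stuckenia_run`, invisibly.
#' @export
run_demo <- function(out_dir, seed = 42L, bootstrap = 1000L,
                     noise_rate = 0, n_polymorphic = 1L) {
  panel <- build_haplotype_panel(seed = seed)
  samples <- simulate_samples(panel, noise_rate = noise_rate,
                              n_polymorphic = n_polymorphic,
                              seed = seed + 1L)
  fix_dir <- file.path(out_dir, "fixture")
  write_fixture(panel, samples, fix_dir)
  cfg <- run_config(
    fasta = file.path(fix_dir, "samples.fasta"),
    key = file.path(fix_dir, "key.txt"),
    reference_fasta = file.path(fix_dir, "panel.fasta"),
    metadata = file.path(fix_dir, "metadata.tsv"),
    out_dir = file.path(out_dir, "run"),
    bootstrap = bootstrap, seed = seed
  )
  run_pipeline(cfg)
}

#' Tidy the calls of a pipeline run
#' @param x a `stuckenia_run`.
#' @param ... unused.
#' @return the calls tibble joined with group assignments.
#' @export
tidy.stuckenia_run <- function(x, ...) {
  dplyr::left_join(flatten_calls(x$calls),
                   dplyr::select(x$groups, "sample_id", "group"),
                   by = "sample_id")
}

#' One-row summary of a pipeline run
#' @param x a `stuckenia_run`.
#' @param ... unused.
#' @return one-row tibble with sample, group, hybrid, unresolved,
#'   discordant counts and the run parameters.
#' @export
glance.stuckenia_run <- function(x, ...) {
  disc <- x$discordance
  tibble::tibble(
    n_samples = nrow(x$calls),
    n_hybrid = sum(x$calls$call == HYBRID_CALL),
    n_unresolved = sum(x$calls$call == UNRESOLVED_CALL),
    n_polymorphic = sum(x$calls$polymorphic),
    n_discordant = if (is.null(disc)) NA_integer_ else
      sum(!is.na(disc$concordant) & !disc$concordant),
    bootstrap = x$config$bootstrap,
    seed = x$config$seed
  )
}
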