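# Pipeline driver: parse -> filter -> match -> place -> consensus ->
# (recombine + second pass) -> profile -> report.

#' Run the full assembly pipeline
#'
#' Executes every stage of a batch run: read parsing and filtering,
#' template matching, unique/shared placement, per-template consensus with
#' I/L resolution, optional recombination of the top-scoring V/J/C segments
#' with CDR(H)3 junction reconstruction and a decoy-aware second matching
#' pass, repertoire profiling (cladograms, summaries, CDR tables) and
#' report generation. Reruns with identical inputs reproduce identical
#' machine-readable outputs.
#'
#' @param config a `run_config` from [parse_config()], or a path to a batch
#'   configuration file.
#' @param write_artifacts write TSV/FASTA/Newick/JSON artifacts and the HTML
#'   report under the configured output directory.
#' @return object of class `ab_assembly` with elements `config`, `reads`
#'   (filtered `read_set`), `db`, `matches` (`match_set`), `summary`,
#'   `consensus` (first-pass, named by template id), `cladograms` (per
#'   group/class, with placements), `cdr_reads`, and if recombination was
#'   requested `selection`, `recombined`, `second_pass` (per chain group).
#' @export
run_pipeline <- function(config, write_artifacts = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else parse_config(config)

  # -- templates ------------------------------------------------------------
  segs <- list()
  for (k in names(cfg$template_files)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (parts[1] == "decoy") {
      segs <- c(segs, read_template_fasta(cfg$template_files[[k]],
                                          "decoy", "contaminant"))
    } else {
      segs <- c(segs, read_template_fasta(cfg$template_files[[k]],
                                          parts[1], toupper(parts[2])))
    }
  }
  ann <- if (!is.null(cfg$annotations)) read_region_tsv(cfg$annotations)
         else NULL
  db <- template_database(segs, annotations = ann)

  # -- reads ----------------------------------------------------------------
  sets <- lapply(cfg$reads.file, function(p) {
    if (cfg$reads.dialect == "fasta") read_fasta_reads(p)
    else parse_denovo_csv(p, cfg$reads.dialect, delimiter = cfg$reads.delimiter)
  })
  reads <- sets[[1]]
  if (length(sets) > 1) {
    for (s in sets[-1]) {
      reads$reads <- c(reads$reads, s$reads)
      reads$provenance <- c(reads$provenance, s$provenance)
    }
    reads <- new_read_set(reads$reads, reads$provenance, reads$filter_log)
  }
  reads <- filter_reads(reads, cfg$min_global_conf, cfg$min_len, cfg$max_len)

  alphabet <- if (identical(cfg$alphabet, "default")) default_alphabet()
              else read_alphabet_tsv(cfg$alphabet, cfg$gap_open, cfg$gap_extend)

  result <- structure(list(config = cfg, reads = reads, db = db,
                           alphabet = alphabet),
                      class = "ab_assembly")
  if (length(reads$reads) == 0L) {
    warning("no reads passed the filters; producing empty summaries",
            call. = FALSE)
    result$matches <- structure(list(alignments = align_reads_to_segments(
      list(), db_segments(db), alphabet, cfg$cutoff, cfg$normalize),
      cutoff = cfg$cutoff, normalize = cfg$normalize, mode = cfg$placement),
      class = "match_set")
    result$summary <- summarize_matches(result$matches)
    result$consensus <- list()
    result$cladograms <- list()
    result$cdr_reads <- collect_cdr_reads(result$matches, db, reads)
    if (write_artifacts) write_run_artifacts(result)
    return(result)
  }

  # -- first matching pass --------------------------------------------------
  ms <- match_reads(reads, db, alphabet, cfg$cutoff, cfg$normalize)
  ms <- assign_placement(ms, cfg$placement)
  result$matches <- ms
  result$summary <- summarize_matches(ms)
  result$cdr_reads <- collect_cdr_reads(ms, db, reads)

  # first-pass consensus for every matched template
  cons <- list()
  for (tid in unique(ms$alignments$template_id)) {
    seg <- db_find(db, tid)
    rows <- ms$alignments[ms$alignments$template_id == tid, , drop = FALSE]
    cr <- build_consensus(seg, rows, reads)
    cons[[tid]] <- resolve_il(cr, seg)
  }
  result$consensus <- cons

  # -- profiling: cladogram per (group, class) ------------------------------
  clades <- list()
  for (g in names(db$groups)) {
    for (klass in names(db$groups[[g]])) {
      tr <- build_cladogram(db$groups[[g]][[klass]], alphabet)
      sub <- ms
      sub$alignments <- ms$alignments[
        ms$alignments$group == g & ms$alignments$segment_class == klass, ,
        drop = FALSE]
      clades[[paste(g, klass, sep = "_")]] <- place_reads(tr, sub)
    }
  }
  result$cladograms <- clades

  # -- recombination + second pass ------------------------------------------
  if (isTRUE(cfg$recombine)) {
    plan <- recombination_plan(
      order = strsplit(cfg$recombine.order, "[[:space:]]+")[[1]],
      n_per_segment = cfg$recombine.n,
      forced_templates = cfg$forced_templates,
      use_decoys = cfg$decoy)
    result$selection <- list()
    result$recombined <- list()
    result$second_pass <- list()
    for (g in names(db$groups)) {
      sel <- rank_and_select(ms, plan, db, group = g)
      # consensus for forced templates may not exist yet
      for (tid in unlist(sel)) {
        if (is.null(cons[[tid]])) {
          seg <- db_find(db, tid)
          rows <- ms$alignments[ms$alignments$template_id == tid, ,
                                drop = FALSE]
          cons[[tid]] <- resolve_il(build_consensus(seg, rows, reads), seg)
        }
      }
      rec <- recombine_templates(sel, cons, reads, alphabet, plan,
                                 cutoff = cfg$cutoff,
                                 normalize = cfg$normalize, group = g,
                                 ms = ms)
      sp <- second_pass(rec, db, reads, alphabet, cfg$cutoff, cfg$normalize,
                        use_decoys = plan$use_decoys,
                        selected_ids = unlist(sel), mode = "best")
      result$selection[[g]] <- sel
      result$recombined[[g]] <- rec
      result$second_pass[[g]] <- sp
    }
    result$consensus <- cons
  }

  if (write_artifacts) write_run_artifacts(result)
  result
}

# Write the machine-readable artifact bundle + HTML report.
write_run_artifacts <- function(result) {
  cfg <- result$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  write_tsv_file(result$summary, out("summary.tsv"))
  fl <- result$reads$filter_log
  write_tsv_file(data.frame(criterion = names(fl) %||% character(0),
                            dropped = as.integer(fl)),
                 out("filter_log.tsv"))
  jsonlite::write_json(config_as_list(cfg), out("config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (length(result$consensus) > 0) {
    ids <- names(result$consensus)
    write_fasta_file(vapply(result$consensus, `[[`, "", "consensus"),
                     ids, out("consensus_first_pass.fasta"))
    depth_rows <- do.call(rbind, lapply(ids, function(tid) {
      cr <- result$consensus[[tid]]
      data.frame(template_id = tid, position = seq_along(cr$depth),
                 template_res = chars(cr$template),
                 depth = cr$depth, stringsAsFactors = FALSE)
    }))
    write_tsv_file(depth_rows, out("depth_first_pass.tsv"))
  }
  write_tsv_file(result$cdr_reads, out("cdr_reads.tsv"))

  for (nm in names(result$cladograms)) {
    writeLines(cladogram_newick(result$cladograms[[nm]]$tree),
               out(paste0("cladogram_", nm, ".nwk")))
  }

  if (!is.null(result$second_pass)) {
    rec_info <- list()
    seqs <- character(0)
    ids <- character(0)
    for (g in names(result$second_pass)) {
      sp <- result$second_pass[[g]]
      for (tid in names(sp$consensus)) {
        ids <- c(ids, paste0(g, "|", tid))
        seqs <- c(seqs, sp$consensus[[tid]]$consensus)
      }
      rec_info[[g]] <- list(
        selection = result$selection[[g]],
        templates = lapply(result$recombined[[g]], function(r)
          list(id = r$id, components = as.list(r$components),
               junction = r$junction[c("overlap_len", "gap_inserted",
                                       "window_score", "v_overhang",
                                       "j_overhang")])),
        n_decoy_excluded = sp$n_decoy_excluded)
    }
    write_fasta_file(seqs, ids, out("recombined_consensus.fasta"))
    jsonlite::write_json(rec_info, out("recombination.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  render_report(result, out("report"))
  invisible(cfg$out_dir)
}

#' @export
print.ab_assembly <- function(x, ...) {
  cat("Antibody template assembly run\n")
  cat("  reads:", length(x$reads$reads), "after filtering\n")
  cat("  placements:", nrow(x$matches$alignments), "on",
      length(unique(x$matches$alignments$template_id)), "templates\n")
  if (!is.null(x$second_pass)) {
    for (g in names(x$second_pass)) {
      for (tid in names(x$second_pass[[g]]$consensus)) {
        cr <- x$second_pass[[g]]$consensus[[tid]]
        cat(sprintf("  %s chain: %s (%d aa, mean depth %.1f)\n", g, tid,
                    nchar(cr$consensus), mean(cr$depth)))
      }
    }
  }
  invisible(x)
}

#' @export
summary.ab_assembly <- function(object, ...) {
  cat("Top templates by total alignment score:\n")
  print(utils::head(object$summary, 10))
  if (!is.null(object$second_pass)) {
    cat("\nRecombination:\n")
    for (g in names(object$second_pass)) {
      sel <- object$selection[[g]]
      cat(" ", g, ":", paste(vapply(names(sel), function(k)
        paste0(k, "=", paste(sel[[k]], collapse = "/")), ""),
        collapse = ", "))
      sp <- object$second_pass[[g]]
      cat(";", sp$n_decoy_excluded, "reads excluded by decoys\n")
    }
  }
  invisible(object$summary)
}
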