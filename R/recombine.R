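# Recombination of top-scoring V/J/C consensus segments into full-chain
# templates, with CDRH3 junction reconstruction from overhanging reads and a
# decoy-aware second matching pass.

#' Define a recombination plan
#'
#' @param order segment classes in recombination order, with `"*"` marking
#'   the junction between V and J where overhanging reads reconstruct CDR3
#'   (default `c("V", "*", "J", "C")`).
#' @param n_per_segment how many top-scoring templates to keep per class
#'   (N = 1 for monoclonal antibodies).
#' @param forced_templates named character vector mapping a segment class to
#'   a template id that overrides the ranking for that class.
#' @param use_decoys add all nonselected germline templates as decoys in the
#'   second matching pass.
#' @return object of class `recombination_plan`.
#' @export
recombination_plan <- function(order = c("V", "*", "J", "C"),
                               n_per_segment = 1,
                               forced_templates = character(0),
                               use_decoys = FALSE) {
  if (n_per_segment < 1) validation_error("n_per_segment must be >= 1")
  classes <- setdiff(order, "*")
  if (!all(classes %in% SEGMENT_CLASSES))
    validation_error("unknown segment class in recombination order")
  structure(list(order = order, n_per_segment = as.integer(n_per_segment),
                 forced_templates = forced_templates,
                 use_decoys = isTRUE(use_decoys)),
            class = "recombination_plan")
}

#' Rank templates and select the top N per segment class
#'
#' Templates are ranked within each (group, segment class) by total
#' alignment score (ties broken by unique score, then id) and truncated to
#' the plan's N. A forced template id overrides the ranking for its class.
#'
#' @param ms a `match_set` (see [match_reads()]).
#' @param plan a [recombination_plan()].
#' @param db the `template_database` (used to validate forced ids).
#' @param group restrict to one group (e.g. `"heavy"`); `NULL` for all.
#' @return named list: per segment class, the selected template ids in rank
#'   order.
#' @export
rank_and_select <- function(ms, plan, db, group = NULL) {
  summ <- summarize_matches(ms)
  if (!is.null(group)) summ <- summ[summ$group == group, , drop = FALSE]
  for (k in names(plan$forced_templates)) {
    if (is.null(db_find(db, plan$forced_templates[[k]])))
      config_error("forced template '", plan$forced_templates[[k]],
                   "' not in the database")
  }
  classes <- setdiff(plan$order, "*")
  out <- list()
  for (k in classes) {
    if (k %in% names(plan$forced_templates)) {
      out[[k]] <- unname(plan$forced_templates[[k]])
      next
    }
    sk <- summ[summ$segment_class == k, , drop = FALSE]
    if (nrow(sk) == 0L) { out[[k]] <- character(0); next }
    ord <- order(-sk$total_score, -sk$unique_score, sk$template_id)
    out[[k]] <- utils::head(sk$template_id[ord], plan$n_per_segment)
  }
  out
}

#' Extend V and J consensus sequences with overhanging-read consensus
#'
#' The V consensus is extended C-terminally and the J consensus N-terminally
#' by 20 `X` placeholder positions, reads are re-matched against the
#' extended templates (alignments continue diagonally through the
#' zero-scoring X region), and the X region's weighted consensus is kept up
#' to the first uncovered X column. This recovers the junction residues
#' (the missing D region and non-templated additions) flanking CDR(H)3.
#'
#' @param v_consensus,j_consensus consensus strings of the selected V and J
#'   templates.
#' @param rs the `read_set`.
#' @param alphabet a [scoring_alphabet()].
#' @param cutoff normalized-score cutoff for re-matching.
#' @param normalize see [smith_waterman()].
#' @param v_read_ids,j_read_ids optional read id vectors restricting which
#'   reads may contribute overhang residues on each side. The pipeline
#'   passes the reads whose best first-pass placement was the selected V
#'   (resp. J) template: a short spurious boundary anchor from an unrelated
#'   read would otherwise drag its unaligned tail into the placeholder
#'   region. `NULL` admits every read.
#' @return list with `v_ext`, `j_ext` (extended sequences, no X), and the
#'   recovered overhang lengths `v_overhang`, `j_overhang`.
#' @export
extend_with_overhangs <- function(v_consensus, j_consensus, rs, alphabet,
                                  cutoff = 8, normalize = "read_length",
                                  v_read_ids = NULL, j_read_ids = NULL) {
  x20 <- strrep("X", 20)
  v_seg <- template_segment("v_ext", paste0(v_consensus, x20), "heavy", "V")
  j_seg <- template_segment("j_ext", paste0(x20, j_consensus), "heavy", "J")
  v_reads <- if (is.null(v_read_ids)) rs$reads else
    Filter(function(r) r$id %in% v_read_ids, rs$reads)
  j_reads <- if (is.null(j_read_ids)) rs$reads else
    Filter(function(r) r$id %in% j_read_ids, rs$reads)
  v_rows <- align_reads_to_segments(v_reads, list(v_seg), alphabet, cutoff,
                                    normalize, extend_side = list("right"))
  j_rows <- align_reads_to_segments(j_reads, list(j_seg), alphabet, cutoff,
                                    normalize, extend_side = list("left"))
  v_cons <- build_consensus(v_seg, v_rows, rs)
  j_cons <- build_consensus(j_seg, j_rows, rs)

  nv <- nchar(v_consensus)
  v_over <- character(0)
  for (j in (nv + 1L):(nv + 20L)) {  # X columns, junction side outward
    if (v_cons$depth[j] == 0L) break
    ci <- v_cons$col_to_cons[j]
    if (!is.na(ci)) v_over <- c(v_over, substr(v_cons$consensus, ci, ci))
  }
  j_over <- character(0)
  for (j in 20:1) {
    if (j_cons$depth[j] == 0L) break
    ci <- j_cons$col_to_cons[j]
    if (!is.na(ci)) j_over <- c(substr(j_cons$consensus, ci, ci), j_over)
  }
  list(v_ext = paste0(v_consensus, paste(v_over, collapse = "")),
       j_ext = paste0(paste(j_over, collapse = ""), j_consensus),
       v_overhang = length(v_over), j_overhang = length(j_over))
}

#' Find the junction between extended V and J sequences
#'
#' The overlap between the V-side and J-side overhangs is sought within a
#' sliding window of at most 40 amino acids: each candidate overlap length
#' scores the V suffix against the J prefix position-wise under the
#' alphabet (no gaps inside the window). The maximum positively scoring
#' overlap is merged (the V side takes precedence on conflicting residues);
#' if no overlap scores positively, the sequences are concatenated and a
#' single gap is recorded (`gap_inserted`).
#'
#' @param v_ext,j_ext extended sequences from [extend_with_overhangs()].
#' @param alphabet a [scoring_alphabet()].
#' @param v_overhang,j_overhang lengths of the read-derived overhangs within
#'   `v_ext`/`j_ext` (as reported by [extend_with_overhangs()]). When both
#'   are 0 no overhanging reads cover the junction, so no overlap can be
#'   claimed and a gap is recorded; leave `NULL` when the inputs are not
#'   overhang-extended.
#' @return list with `sequence` (merged junction sequence), `overlap_len`,
#'   `gap_inserted`, `window_score` and `v_trimmed` (V-side overhang spill
#'   past the J end removed on merge).
#' @export
reconstruct_junction <- function(v_ext, j_ext, alphabet,
                                 v_overhang = NULL, j_overhang = NULL) {
  if (!is.null(v_overhang) && !is.null(j_overhang) &&
      v_overhang == 0L && j_overhang == 0L) {
    return(list(sequence = paste0(v_ext, j_ext), overlap_len = 0L,
                gap_inserted = TRUE, window_score = 0, v_trimmed = 0L))
  }
  nv <- nchar(v_ext)
  nj <- nchar(j_ext)
  vs_all <- chars(v_ext)
  js_all <- chars(j_ext)
  m <- alphabet$matrix
  # offset k: the J side starts k positions before the V end (k = 1 means
  # the last V residue pairs with the first J residue). When k > nj the
  # whole of j_ext lies inside v_ext and the V residues past the J end
  # (overhang spill, typically read coverage running into the next segment)
  # are trimmed on merge. When overhang lengths are known, a candidate
  # overlap must touch read-derived overhang residues on at least one side:
  # an overlap supported only by template residues is a coincidental
  # homology, not junction evidence.
  best_k <- 0L
  best_score <- 0
  best_ov <- 0L
  for (k in seq_len(min(40L, nv))) {
    p <- nv - k + 1L
    ov <- min(k, nj)
    if (!is.null(v_overhang) && !is.null(j_overhang)) {
      # the read-derived overhangs bound the possible true overlap: the V
      # extension ends v_overhang past the V end and the J extension starts
      # j_overhang before the J start, so no junction arrangement can
      # overlap by more than their sum
      if (k > v_overhang + j_overhang) next
      touches_v <- v_overhang > max(0L, k - nj)
      touches_j <- j_overhang > 0L
      if (!touches_v && !touches_j) next
    }
    sc <- sum(m[cbind(vs_all[p:(p + ov - 1L)], js_all[seq_len(ov)])])
    if (sc > best_score || (sc == best_score && sc > 0 && ov > best_ov)) {
      best_score <- sc
      best_k <- k
      best_ov <- ov
    }
  }
  if (best_k > 0L && best_score > 0) {
    p <- nv - best_k + 1L
    merged <- paste0(substr(v_ext, 1L, p - 1L + best_ov),  # V precedence
                     substr(j_ext, best_ov + 1L, nj))
    list(sequence = merged, overlap_len = best_ov, gap_inserted = FALSE,
         window_score = best_score, v_trimmed = max(best_k - nj, 0L))
  } else {
    list(sequence = paste0(v_ext, j_ext), overlap_len = 0L,
         gap_inserted = TRUE, window_score = 0, v_trimmed = 0L)
  }
}

# Reads whose maximum raw score within the template's (group, class) pool is
# attained on `template_id` (ties included).
reads_best_on <- function(ms, template_id) {
  df <- ms$alignments
  if (nrow(df) == 0L) return(character(0))
  key <- paste(df$group, df$segment_class, df$read_id, sep = "\r")
  mx <- tapply(df$raw_score, key, max)[key]
  unique(df$read_id[df$template_id == template_id & df$raw_score == mx])
}

#' Build recombined full-chain templates
#'
#' For each combination of selected segments (cartesian product when N > 1),
#' reconstructs the junction between the V and J consensus (extended with
#' overhanging reads) and concatenates the remaining classes in plan order
#' into one recombined template.
#'
#' @param selection named list from [rank_and_select()].
#' @param consensus named list of `consensus_result` keyed by template id
#'   (first-pass consensus of every selected segment).
#' @param rs,alphabet,cutoff,normalize as in [extend_with_overhangs()].
#' @param plan a [recombination_plan()].
#' @param group group label for the recombined templates.
#' @param ms optional first-pass `match_set`; when given, only reads whose
#'   best placement was the selected V (resp. J) template contribute
#'   junction overhangs (see [extend_with_overhangs()]).
#' @return list of `template_segment`-like objects (class
#'   `recombined_template`) with `components` and `junction` metadata.
#' @export
recombine_templates <- function(selection, consensus, rs, alphabet, plan,
                                cutoff = 8, normalize = "read_length",
                                group = "heavy", ms = NULL) {
  classes <- setdiff(plan$order, "*")
  has_junction <- "*" %in% plan$order
  for (k in classes) {
    if (length(selection[[k]]) == 0L)
      config_error("no template selected for class ", k, " in group ", group)
  }
  combos <- expand.grid(lapply(selection[classes], seq_along),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ids <- vapply(classes, function(k) selection[[k]][combos[[k]][i]], "")
    names(ids) <- classes
    seqs <- vapply(ids, function(id) consensus[[id]]$consensus, "")
    junction <- NULL
    if (has_junction && all(c("V", "J") %in% classes)) {
      v_ids <- if (is.null(ms)) NULL else reads_best_on(ms, ids[["V"]])
      j_ids <- if (is.null(ms)) NULL else reads_best_on(ms, ids[["J"]])
      ext <- extend_with_overhangs(seqs[["V"]], seqs[["J"]], rs, alphabet,
                                   cutoff, normalize,
                                   v_read_ids = v_ids, j_read_ids = j_ids)
      junction <- reconstruct_junction(ext$v_ext, ext$j_ext, alphabet,
                                       ext$v_overhang, ext$j_overhang)
      junction$v_overhang <- ext$v_overhang
      junction$j_overhang <- ext$j_overhang
      body <- junction$sequence
      rest <- setdiff(classes, c("V", "J"))
      for (k in classes[classes %in% rest]) body <- paste0(body, seqs[[k]])
      seqc <- body
    } else {
      seqc <- paste(seqs[classes], collapse = "")
    }
    rec <- template_segment(paste(ids, collapse = "+"), seqc, group, "V")
    rec$segment_class <- "recombined"
    rec$components <- ids
    rec$junction <- junction
    class(rec) <- c("recombined_template", class(rec))
    out[[i]] <- rec
  }
  out
}

#' Second template-matching pass on recombined templates
#'
#' All reads are re-matched against the recombined full-chain templates;
#' with `use_decoys`, every nonselected germline template (plus any
#' contaminant decoy database) is added as a decoy, and a read whose best
#' score lies strictly on a decoy is excluded from every recombined-template
#' consensus. Placement between recombined templates follows `mode`.
#'
#' @param recombined list of recombined templates from
#'   [recombine_templates()].
#' @param db the `template_database`.
#' @param rs the `read_set`.
#' @param alphabet,cutoff,normalize as in [match_reads()].
#' @param use_decoys logical.
#' @param selected_ids character vector of template ids selected for
#'   recombination (these are NOT used as decoys).
#' @param mode placement mode among recombined templates (`"best"` or
#'   `"all"`).
#' @return list with `consensus` (named list of `consensus_result` per
#'   recombined template, I/L resolved), `match_set` (the recombined-template
#'   placements) and `n_decoy_excluded`.
#' @export
second_pass <- function(recombined, db, rs, alphabet, cutoff = 8,
                        normalize = "read_length", use_decoys = FALSE,
                        selected_ids = character(0), mode = "best") {
  if (length(recombined) == 0L)
    config_error("no recombined templates for the second pass")
  decoys <- list()
  if (use_decoys) {
    all_segs <- c(db_segments(db), db$decoys)
    decoys <- Filter(function(s) !(s$id %in% selected_ids), all_segs)
  }
  rows_rec <- align_reads_to_segments(rs$reads, recombined, alphabet, cutoff,
                                      normalize)
  excluded <- character(0)
  if (length(decoys) > 0 && nrow(rows_rec) > 0) {
    matched_ids <- unique(rows_rec$read_id)
    matched_reads <- Filter(function(r) r$id %in% matched_ids, rs$reads)
    best_dec <- best_raw_scores(matched_reads, decoys, alphabet)
    best_rec <- tapply(rows_rec$raw_score, rows_rec$read_id, max)
    common <- intersect(names(best_dec), names(best_rec))
    excluded <- common[best_dec[common] > best_rec[common]]
    rows_rec <- rows_rec[!(rows_rec$read_id %in% excluded), , drop = FALSE]
  }
  ms <- structure(list(alignments = rows_rec, cutoff = cutoff,
                       normalize = normalize, mode = "all"),
                  class = "match_set")
  ms <- assign_placement(ms, mode)
  cons <- list()
  for (rec in recombined) {
    rows <- ms$alignments[ms$alignments$template_id == rec$id, , drop = FALSE]
    cr <- build_consensus(rec, rows, rs)
    cons[[rec$id]] <- resolve_il(cr, rec)
  }
  list(consensus = cons, match_set = ms, n_decoy_excluded = length(excluded),
       excluded_reads = excluded)
}
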