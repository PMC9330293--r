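# Local alignment of reads onto templates, score normalization, and
# unique/shared placement of reads across homologous templates.

#' Optimal local alignment of a read against a template
#'
#' Affine-gap Smith-Waterman alignment under a [scoring_alphabet()]. The
#' returned score is normalized by the square root of the aligned read
#' length (or template length, see `normalize`), so a single cutoff is
#' meaningful across the 5-40 aa read-length range.
#'
#' @param read_seq,template_seq amino-acid strings over the alphabet symbols.
#' @param alphabet a [scoring_alphabet()].
#' @param normalize `"read_length"` (default) divides the raw score by
#'   `sqrt(nchar(read_seq))`, so one cutoff adapts across the 5-40 aa read
#'   length range and an incidental few-residue anchor inside a long read
#'   cannot pass it; `"template_length"` divides by
#'   `sqrt(nchar(template_seq))`.
#' @return a list of class `read_alignment` with elements `raw_score`,
#'   `norm_score`, `read_start`, `read_end`, `tmpl_start`, `tmpl_end`
#'   (1-based, inclusive; 0 if the best local score is 0) and `path`, a
#'   string over `M` (aligned pair), `D` (template residue deleted from the
#'   read) and `I` (read residue inserted relative to the template).
#' @examples
#' al <- smith_waterman("ACDEFG", "ACDEFG", default_alphabet())
#' al$raw_score  # 36 = 4 + 9 + 6 + 5 + 6 + 6 on the BLOSUM62 diagonal
#' @export
smith_waterman <- function(read_seq, template_seq, alphabet,
                           normalize = c("read_length", "template_length")) {
  normalize <- match.arg(normalize)
  if (!nzchar(read_seq) || !nzchar(template_seq))
    validation_error("sequences must be nonempty")
  a <- encode_seq(read_seq, alphabet)
  b <- encode_seq(template_seq, alphabet)
  res <- .cpp_sw_align(a, b, alphabet$matrix, alphabet$gap_open,
                       alphabet$gap_extend)
  finish_alignment(res, read_seq, template_seq, normalize)
}

finish_alignment <- function(res, read_seq, template_seq, normalize) {
  aligned_read_len <- if (res$score > 0) res$read_end - res$read_start + 1L else 0L
  denom <- if (normalize == "read_length") sqrt(nchar(read_seq))
           else sqrt(nchar(template_seq))
  structure(list(raw_score = res$score,
                 norm_score = res$score / denom,
                 read_start = res$read_start, read_end = res$read_end,
                 tmpl_start = res$tmpl_start, tmpl_end = res$tmpl_end,
                 aligned_read_len = aligned_read_len,
                 path = res$path),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: raw %g (norm %.2f), read %d-%d vs template %d-%d, path %s\n",
              x$raw_score, x$norm_score, x$read_start, x$read_end,
              x$tmpl_start, x$tmpl_end, x$path))
  invisible(x)
}

#' Match a read set against a template database
#'
#' Every read is aligned against every template of every group; a read is
#' matched to a template iff its normalized alignment score reaches
#' `cutoff`. Groups are scored independently (a read may match templates in
#' both the heavy and the light group).
#'
#' @param rs a `read_set` (see [parse_denovo_csv()]).
#' @param db a `template_database` (see [template_database()]).
#' @param alphabet a [scoring_alphabet()].
#' @param cutoff nonnegative normalized-score cutoff (default 8).
#' @param normalize score normalization, see [smith_waterman()].
#' @return an object of class `match_set`: a list with `alignments` (one
#'   data.frame row per above-cutoff read-template placement), `cutoff`,
#'   `normalize` and `mode` (placement mode; `"all"` until
#'   [assign_placement()] is applied).
#' @export
match_reads <- function(rs, db, alphabet, cutoff = 8,
                        normalize = c("read_length", "template_length")) {
  normalize <- match.arg(normalize)
  if (cutoff < 0) validation_error("cutoff must be nonnegative")
  segs <- db_segments(db)
  if (length(segs) == 0L) config_error("template database is empty")
  rows <- align_reads_to_segments(rs$reads, segs, alphabet, cutoff, normalize)
  ms <- structure(list(alignments = rows, cutoff = cutoff,
                       normalize = normalize, mode = "all"),
                  class = "match_set")
  flag_unique(ms)
}

# Core read x segment alignment loop shared by both matching passes.
# segs: list of template_segment; returns the alignment data.frame
# (columnar accumulation: one data.frame construction at the end).
align_reads_to_segments <- function(reads, segs, alphabet, cutoff, normalize,
                                    extend_side = NULL) {
  enc_t <- lapply(segs, function(s) encode_seq(s$sequence, alphabet))
  cap <- max(16L, length(reads) * length(segs) %/% 4L)
  col <- list(read_id = character(cap), template_id = character(cap),
              group = character(cap), segment_class = character(cap),
              read_start = integer(cap), read_end = integer(cap),
              tmpl_start = integer(cap), tmpl_end = integer(cap),
              path = character(cap), raw_score = numeric(cap),
              norm_score = numeric(cap), ms1_area = numeric(cap))
  k <- 0L
  grow <- function(col, cap2) {
    lapply(col, function(v) { length(v) <- cap2; v })
  }
  for (r in reads) {
    a <- encode_seq(r$sequence, alphabet)
    area <- if (is.na(r$ms1_area)) 0 else r$ms1_area
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      res <- .cpp_sw_align(a, enc_t[[si]], alphabet$matrix,
                           alphabet$gap_open, alphabet$gap_extend)
      al <- finish_alignment(res, r$sequence, s$sequence, normalize)
      if (!is.null(extend_side) && !is.null(extend_side[[si]]) &&
          extend_side[[si]] != "none" && al$raw_score > 0) {
        al <- extend_through_x(al, r$sequence, s$sequence, extend_side[[si]])
      }
      if (al$raw_score > 0 && al$norm_score >= cutoff) {
        k <- k + 1L
        if (k > cap) { cap <- cap * 2L; col <- grow(col, cap) }
        col$read_id[k] <- r$id; col$template_id[k] <- s$id
        col$group[k] <- s$group; col$segment_class[k] <- s$segment_class
        col$read_start[k] <- al$read_start; col$read_end[k] <- al$read_end
        col$tmpl_start[k] <- al$tmpl_start; col$tmpl_end[k] <- al$tmpl_end
        col$path[k] <- al$path; col$raw_score[k] <- al$raw_score
        col$norm_score[k] <- al$norm_score; col$ms1_area[k] <- area
      }
    }
  }
  col <- lapply(col, function(v) v[seq_len(k)])
  col$is_unique <- logical(k)
  do.call(data.frame, c(col, stringsAsFactors = FALSE))
}

# Best raw local-alignment score of each read against any of `segs`
# (score-only kernel; no traceback). Named by read id.
best_raw_scores <- function(reads, segs, alphabet) {
  enc_t <- lapply(segs, function(s) encode_seq(s$sequence, alphabet))
  out <- numeric(length(reads))
  for (i in seq_along(reads)) {
    a <- encode_seq(reads[[i]]$sequence, alphabet)
    best <- 0
    for (et in enc_t) {
      sc <- .cpp_sw_score(a, et, alphabet$matrix, alphabet$gap_open,
                          alphabet$gap_extend)
      if (sc > best) best <- sc
    }
    out[i] <- best
  }
  names(out) <- vapply(reads, `[[`, "", "id")
  out
}

extend_through_x <- function(al, read_seq, template_seq, side) {
  tchars <- chars(template_seq)
  n_read <- nchar(read_seq)
  if (side == "right") {
    while (al$read_end < n_read && al$tmpl_end < length(tchars) &&
           tchars[al$tmpl_end + 1L] == "X") {
      al$read_end <- al$read_end + 1L
      al$tmpl_end <- al$tmpl_end + 1L
      al$path <- paste0(al$path, "M")
    }
  } else if (side == "left") {
    while (al$read_start > 1L && al$tmpl_start > 1L &&
           tchars[al$tmpl_start - 1L] == "X") {
      al$read_start <- al$read_start - 1L
      al$tmpl_start <- al$tmpl_start - 1L
      al$path <- paste0("M", al$path)
    }
  }
  al$aligned_read_len <- al$read_end - al$read_start + 1L
  al
}

# Set is_unique per read within each (group, segment class): each class is
# its own template pool, so a read is unique iff exactly one template of
# that pool attains its maximum raw score. A junction-spanning read can
# therefore be unique on a V and on a J template simultaneously.
flag_unique <- function(ms) {
  df <- ms$alignments
  if (nrow(df) == 0L) return(ms)
  key <- paste(df$group, df$segment_class, df$read_id, sep = "\r")
  mx <- tapply(df$raw_score, key, max)[key]
  at_max <- df$raw_score == mx
  n_max <- tapply(at_max, key, sum)[key]
  df$is_unique <- at_max & n_max == 1L
  ms$alignments <- df
  ms
}

#' Restrict placements to each read's best-scoring template
#'
#' With `mode = "all"` every above-cutoff placement is kept. With
#' `mode = "best"` only the placements tied for a read's maximum score (per
#' group) are kept; a read tied across several templates is placed on all of
#' them simultaneously and is not unique.
#'
#' @param ms a `match_set` from [match_reads()].
#' @param mode `"all"` or `"best"`.
#' @return the `match_set` with `is_unique` flags set and, for
#'   `mode = "best"`, non-maximal placements dropped.
#' @export
assign_placement <- function(ms, mode = c("all", "best")) {
  mode <- match.arg(mode)
  ms <- flag_unique(ms)
  if (mode == "best" && nrow(ms$alignments) > 0L) {
    df <- ms$alignments
    key <- paste(df$group, df$segment_class, df$read_id, sep = "\r")
    mx <- tapply(df$raw_score, key, max)[key]
    ms$alignments <- df[df$raw_score == mx, , drop = FALSE]
    rownames(ms$alignments) <- NULL
  }
  ms$mode <- mode
  ms
}

#' @export
print.match_set <- function(x, ...) {
  df <- x$alignments
  cat(sprintf("Match set: %d placements of %d reads on %d templates (cutoff %g, mode %s)\n",
              nrow(df), length(unique(df$read_id)),
              length(unique(df$template_id)), x$cutoff, x$mode))
  invisible(x)
}

# Global-alignment identity fraction between two sequences (for homology
# distances in the cladogram module).
nw_identity <- function(a_seq, b_seq, alphabet) {
  res <- .cpp_nw_align(encode_seq(a_seq, alphabet), encode_seq(b_seq, alphabet),
                       alphabet$matrix, alphabet$gap_open, alphabet$gap_extend)
  res$identical / res$columns
}
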