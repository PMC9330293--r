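# Germline template segments: loading, validation, deduplication and CDR
# region annotation.

SEGMENT_CLASSES <- c("V", "J", "C", "contaminant")
GROUPS <- c("heavy", "light", "decoy")
REGION_LABELS <- list(V = c("CDR1", "CDR2", "CDR3-anchor"),
                      J = "CDR3-anchor",
                      C = character(0),
                      contaminant = character(0))

#' Construct a template segment
#'
#' @param id unique identifier.
#' @param sequence uppercase amino-acid string (20 standard residues plus X).
#' @param group `"heavy"`, `"light"` or `"decoy"`.
#' @param segment_class `"V"`, `"J"`, `"C"` or `"contaminant"`.
#' @param regions data.frame with columns `label`, `start`, `end`
#'   (0-based half-open intervals into `sequence`).
#' @param organism optional organism label.
#' @param merged_ids ids of duplicate segments merged into this one.
#' @return an object of class `template_segment`.
#' @export
template_segment <- function(id, sequence, group, segment_class,
                             regions = NULL, organism = NA_character_,
                             merged_ids = character(0)) {
  group <- match.arg(group, GROUPS)
  segment_class <- match.arg(segment_class, SEGMENT_CLASSES)
  if (!nzchar(sequence)) validation_error("segment '", id, "' has empty sequence")
  bad <- setdiff(unique(chars(sequence)), c(AA20, "X"))
  if (length(bad) > 0)
    format_error("segment '", id, "' contains invalid residue '", bad[1], "'")
  seg <- structure(list(id = id, sequence = sequence, group = group,
                        segment_class = segment_class,
                        regions = empty_regions(), organism = organism,
                        merged_ids = merged_ids),
                   class = "template_segment")
  if (!is.null(regions) && nrow(regions) > 0) seg <- annotate_regions(seg, regions)
  seg
}

empty_regions <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Load germline template segments from a FASTA file
#'
#' Sequences are uppercased; `*` and `.` characters (common in germline
#' reference exports) are stripped; the header token before the first
#' whitespace becomes the id, and ids of previously merged duplicates may
#' follow a `|` separator (they are restored into `merged_ids`). The
#' ambiguity codes B and Z are mapped to D and Q with a warning; any other
#' non-standard residue is a format error naming the record.
#'
#' @param path FASTA file path.
#' @inheritParams template_segment
#' @return list of `template_segment`.
#' @export
read_template_fasta <- function(path, group, segment_class) {
  seqs <- read_fasta_file(path)
  if (length(seqs) == 0L) format_error("empty FASTA file: ", path)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    token <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
    parts <- strsplit(token, "|", fixed = TRUE)[[1]]
    id <- parts[1]
    merged <- if (length(parts) > 1 && nzchar(parts[2]))
      strsplit(parts[2], ",", fixed = TRUE)[[1]] else character(0)
    s <- unname(toupper(gsub("[*.]", "", seqs[[i]])))
    if (!nzchar(s)) format_error("record '", id, "' in ", path, " has empty sequence")
    if (grepl("[BZ]", s)) {
      warning("record '", id, "': ambiguity codes B/Z mapped to D/Q",
              call. = FALSE)
      s <- chartr("BZ", "DQ", s)
    }
    bad <- setdiff(unique(chars(s)), c(AA20, "X"))
    if (length(bad) > 0)
      format_error("record '", id, "' in ", path,
                   " contains invalid character '", bad[1], "'")
    out[[i]] <- template_segment(id, s, group, segment_class,
                                 merged_ids = merged)
  }
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids))
    format_error("duplicate segment id '", ids[duplicated(ids)][1],
                 "' in ", path)
  out
}

#' Remove duplicate template sequences
#'
#' Keeps the first occurrence of each distinct amino-acid sequence; later
#' duplicates are dropped and their ids recorded in the survivor's
#' `merged_ids`. Input order is otherwise preserved. Idempotent.
#'
#' @param segments list of `template_segment`.
#' @return deduplicated list of `template_segment`.
#' @export
deduplicate_templates <- function(segments) {
  seqs <- vapply(segments, `[[`, "", "sequence")
  first <- !duplicated(seqs)
  kept <- segments[first]
  kept_seq <- seqs[first]
  for (i in which(!first)) {
    j <- match(seqs[i], kept_seq)
    kept[[j]]$merged_ids <- c(kept[[j]]$merged_ids, segments[[i]]$id,
                              segments[[i]]$merged_ids)
  }
  kept
}

#' Attach CDR region annotations to a segment
#'
#' @param segment a `template_segment`.
#' @param annotations data.frame with columns `label`, `start`, `end`
#'   (0-based half-open). Labels must be valid for the segment class
#'   (`CDR1`/`CDR2`/`CDR3-anchor` for V, `CDR3-anchor` for J, none for
#'   C/contaminant). Intervals must lie within the sequence and must not
#'   overlap.
#' @return the segment with `regions` set.
#' @export
annotate_regions <- function(segment, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(segment)
  ann <- annotations[, c("label", "start", "end")]
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  len <- nchar(segment$sequence)
  ok_labels <- REGION_LABELS[[segment$segment_class]]
  for (i in seq_len(nrow(ann))) {
    if (!(ann$label[i] %in% ok_labels))
      validation_error("label '", ann$label[i], "' not allowed on a ",
                       segment$segment_class, " segment ('", segment$id, "')")
    if (ann$start[i] < 0 || ann$end[i] > len || ann$start[i] >= ann$end[i])
      validation_error("interval [", ann$start[i], ",", ann$end[i],
                       ") out of bounds for segment '", segment$id,
                       "' (length ", len, ")")
  }
  ord <- order(ann$start)
  ann <- ann[ord, , drop = FALSE]
  if (nrow(ann) > 1 && any(ann$start[-1] < ann$end[-nrow(ann)]))
    validation_error("overlapping region intervals on segment '",
                     segment$id, "'")
  segment$regions <- ann
  rownames(segment$regions) <- NULL
  segment
}

#' Default CDR3 anchor: the conserved cysteine preceding CDR3
#'
#' For a V segment lacking an explicit `CDR3-anchor` annotation, flags the
#' last cysteine of the sequence as the anchor (region from that position to
#' the segment end).
#'
#' @param segment a V `template_segment`.
#' @return the segment, annotated if a cysteine exists.
#' @export
flag_cdr3_anchor <- function(segment) {
  if (segment$segment_class != "V") return(segment)
  if ("CDR3-anchor" %in% segment$regions$label) return(segment)
  pos <- gregexpr("C", segment$sequence, fixed = TRUE)[[1]]
  if (pos[1] == -1) return(segment)
  anchor <- max(pos) - 1L  # 0-based
  add <- data.frame(label = "CDR3-anchor", start = anchor,
                    end = nchar(segment$sequence), stringsAsFactors = FALSE)
  annotate_regions(segment, rbind(segment$regions, add))
}

#' Read a CDR annotation sidecar table
#'
#' TSV with columns `id`, `label`, `start`, `end` (0-based half-open).
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_region_tsv <- function(path) {
  if (!file.exists(path)) format_error("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "label", "start", "end")
  if (!all(need %in% names(df)))
    format_error("annotation TSV must have columns id, label, start, end: ", path)
  df
}

#' Assemble a template database
#'
#' @param segments list of `template_segment` (any mix of groups/classes).
#' @param annotations optional annotation data.frame from [read_region_tsv()],
#'   applied by id.
#' @param deduplicate deduplicate within each (group, class) list.
#' @return object of class `template_database`: nested list
#'   `groups[[group]][[segment_class]]` of segments, plus `decoys` (the
#'   decoy/contaminant group).
#' @export
template_database <- function(segments, annotations = NULL,
                              deduplicate = TRUE) {
  if (!is.null(annotations)) {
    segments <- lapply(segments, function(s) {
      ann <- annotations[annotations$id == s$id, , drop = FALSE]
      if (nrow(ann) > 0) annotate_regions(s, ann) else s
    })
  }
  groups <- list()
  decoys <- list()
  for (s in segments) {
    if (s$group == "decoy") { decoys[[length(decoys) + 1L]] <- s; next }
    g <- s$group; k <- s$segment_class
    if (is.null(groups[[g]])) groups[[g]] <- list()
    if (is.null(groups[[g]][[k]])) groups[[g]][[k]] <- list()
    groups[[g]][[k]][[length(groups[[g]][[k]]) + 1L]] <- s
  }
  if (deduplicate) {
    groups <- lapply(groups, function(g) lapply(g, deduplicate_templates))
    if (length(decoys) > 0) decoys <- deduplicate_templates(decoys)
  }
  for (g in names(groups)) for (k in names(groups[[g]]))
    if (length(groups[[g]][[k]]) == 0L)
      validation_error("empty template list for group ", g, ", class ", k)
  db <- structure(list(groups = groups, decoys = decoys),
                  class = "template_database")
  ids <- vapply(c(db_segments(db), db$decoys), function(s) s$id, character(1))
  if (anyDuplicated(ids))
    validation_error("duplicate template id across database: '",
                     ids[duplicated(ids)][1], "'")
  db
}

# Flat list of all non-decoy segments (optionally one group / class).
db_segments <- function(db, group = NULL, segment_class = NULL) {
  out <- list()
  for (g in names(db$groups)) {
    if (!is.null(group) && g != group) next
    for (k in names(db$groups[[g]])) {
      if (!is.null(segment_class) && k != segment_class) next
      out <- c(out, db$groups[[g]][[k]])
    }
  }
  out
}

db_find <- function(db, id) {
  for (s in c(db_segments(db), db$decoys)) if (s$id == id) return(s)
  NULL
}

#' Write cleaned templates to FASTA
#'
#' Headers carry merged-duplicate provenance after a `|` separator:
#' `>id|dup1,dup2`.
#'
#' @param segments list of `template_segment`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_template_fasta <- function(segments, path) {
  headers <- vapply(segments, function(s) {
    if (length(s$merged_ids) > 0)
      paste0(s$id, "|", paste(s$merged_ids, collapse = ","))
    else s$id
  }, character(1))
  seqs <- vapply(segments, `[[`, "", "sequence")
  write_fasta_file(seqs, headers, path)
}

#' @export
print.template_database <- function(x, ...) {
  for (g in names(x$groups)) {
    counts <- vapply(x$groups[[g]], length, integer(1))
    cat(g, ": ", paste(names(counts), counts, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$decoys) > 0) cat("decoys: ", length(x$decoys), "\n", sep = "")
  invisible(x)
}

#' @export
print.template_segment <- function(x, ...) {
  cat(sprintf("<%s/%s> %s (%d aa", x$group, x$segment_class, x$id,
              nchar(x$sequence)))
  if (length(x$merged_ids) > 0)
    cat("; merged:", paste(x$merged_ids, collapse = ","))
  if (nrow(x$regions) > 0)
    cat("; regions:", paste(x$regions$label, collapse = ","))
  cat(")\n")
  invisible(x)
}
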