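# De novo peptide read parsing: PEAKS-style CSV, Novor-style CSV and plain
# FASTA, modification stripping, confidence normalization and quality
# filtering.

#' Strip inline modification annotations from a peptide string
#'
#' De novo engines annotate modified residues with parenthesized mass deltas
#' (`"(+15.99)"`, `"(-0.98)"`) or substitutions (`"(sub X)"`) attached to the
#' preceding residue, or to the peptide N-terminus. Scoring uses the
#' unmodified residues, so annotations are stripped and recorded.
#'
#' @param peptide annotated peptide string.
#' @return list with `sequence` (bare residue string) and `modifications`
#'   (data.frame of 0-based `position`, `annotation`); an N-terminal
#'   annotation is recorded at position 0.
#' @examples
#' strip_modifications("M(+15.99)PEPT")
#' @export
strip_modifications <- function(peptide) {
  cc <- chars(peptide)
  seq_chars <- character(0)
  pos <- integer(0)
  ann <- character(0)
  i <- 1L
  n <- length(cc)
  while (i <= n) {
    ch <- cc[i]
    if (ch == "(") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (cc[j] == "(") depth <- depth + 1L
        if (cc[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L) format_error("unbalanced parentheses in peptide '",
                                   peptide, "'")
      pos <- c(pos, max(length(seq_chars) - 1L, 0L))
      ann <- c(ann, paste(cc[(i + 1L):(j - 2L)], collapse = ""))
      i <- j
    } else if (ch == ")") {
      format_error("unbalanced parentheses in peptide '", peptide, "'")
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  sequence <- paste(seq_chars, collapse = "")
  if (grepl("[^A-Za-z]", sequence))
    format_error("peptide '", peptide,
                 "' contains non-residue characters after stripping")
  list(sequence = toupper(sequence),
       modifications = data.frame(position = pos, annotation = ann,
                                  stringsAsFactors = FALSE))
}

new_read <- function(id, sequence, local_conf, global_conf,
                     ms1_area = NA_real_, modifications = NULL,
                     source = "") {
  stopifnot(length(local_conf) == nchar(sequence))
  list(id = id, sequence = sequence,
       local_conf = as.numeric(local_conf),
       global_conf = as.numeric(global_conf),
       ms1_area = as.numeric(ms1_area),
       modifications = modifications %||%
         data.frame(position = integer(), annotation = character(),
                    stringsAsFactors = FALSE),
       source = source)
}

new_read_set <- function(reads, provenance = character(0),
                         filter_log = integer(0)) {
  ids <- vapply(reads, `[[`, "", "id")
  if (anyDuplicated(ids)) {  # disambiguate collisions by suffixing
    for (i in seq_along(reads)) {
      n_before <- sum(ids[seq_len(i - 1L)] == ids[i])
      if (n_before > 0)
        reads[[i]]$id <- paste0(ids[i], "_", n_before + 1L)
    }
  }
  structure(list(reads = reads, provenance = provenance,
                 filter_log = filter_log),
            class = "read_set")
}

# Default export column names per dialect; overridable via column_map.
DIALECT_COLUMNS <- list(
  peaks = list(peptide = "Peptide", alc = "ALC (%)",
               local_conf = "local confidence (%)", area = "Area",
               source = "Source File", conf_sep = " "),
  novor = list(peptide = "Peptide", alc = "Score",
               local_conf = "AA Score", area = "Area",
               source = "Source File", conf_sep = "-"))

#' Parse a de novo peptide read table
#'
#' Reads a PEAKS- or Novor-style CSV export: one row per de novo peptide
#' with an ALC-like global confidence percentage (0-100), an optional
#' per-residue local confidence list, an optional MS1 peak area and an
#' optional source file. Peptide strings are passed through
#' [strip_modifications()]; percentages are scaled to fractions in `[0, 1]`.
#' Rows whose local-confidence count does not match the stripped peptide
#' length are skipped with a warning. Missing local confidence defaults to
#' the global confidence replicated per residue.
#'
#' @param path CSV path.
#' @param dialect `"peaks"` or `"novor"` (sets default column names and the
#'   separator of the local-confidence list).
#' @param column_map named list overriding the default column names
#'   (`peptide`, `alc`, `local_conf`, `area`, `source`, `conf_sep`).
#' @param delimiter field delimiter, `","` (default) or `";"`.
#' @return a `read_set`.
#' @export
parse_denovo_csv <- function(path, dialect = c("peaks", "novor"),
                             column_map = list(), delimiter = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error("read file not found: ", path)
  cols <- utils::modifyList(DIALECT_COLUMNS[[dialect]], column_map)
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!(cols$peptide %in% names(df)))
    format_error("missing peptide column '", cols$peptide, "' in ", path)
  reads <- vector("list", nrow(df))
  kept <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    stripped <- strip_modifications(df[[cols$peptide]][i])
    sq <- stripped$sequence
    if (!nzchar(sq)) { skipped <- skipped + 1L; next }
    gconf <- if (cols$alc %in% names(df)) as.numeric(df[[cols$alc]][i]) / 100 else 1
    if (cols$local_conf %in% names(df) &&
        nzchar(as.character(df[[cols$local_conf]][i]))) {
      lc <- as.numeric(strsplit(trimws(as.character(df[[cols$local_conf]][i])),
                                cols$conf_sep, fixed = TRUE)[[1]]) / 100
      if (length(lc) != nchar(sq)) {
        warning("row ", i, ": local confidence count (", length(lc),
                ") does not match peptide length (", nchar(sq),
                "); row skipped", call. = FALSE)
        skipped <- skipped + 1L
        next
      }
    } else {
      lc <- rep(gconf, nchar(sq))
    }
    area <- if (cols$area %in% names(df)) {
      a <- suppressWarnings(as.numeric(df[[cols$area]][i]))
      if (is.na(a)) NA_real_ else a
    } else NA_real_
    if (!is.na(area) && area < 0)
      validation_error("row ", i, ": negative MS1 area")
    src <- if (cols$source %in% names(df)) as.character(df[[cols$source]][i]) else ""
    kept <- kept + 1L
    reads[[kept]] <- new_read(sprintf("read%05d", i), sq, lc, gconf, area,
                              stripped$modifications, src)
  }
  new_read_set(reads[seq_len(kept)], provenance = path,
               filter_log = c(malformed = skipped))
}

#' Parse plain FASTA reads
#'
#' FASTA reads carry no quality metadata: they receive global and local
#' confidence 1.0 and no MS1 area.
#'
#' @param path FASTA path.
#' @return a `read_set`.
#' @export
read_fasta_reads <- function(path) {
  seqs <- read_fasta_file(path)
  reads <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- strsplit(trimws(names(seqs)[i]), "[[:space:]]+")[[1]][1]
    stripped <- strip_modifications(seqs[[i]])
    reads[[i]] <- new_read(id, stripped$sequence,
                           rep(1, nchar(stripped$sequence)), 1,
                           source = path)
  }
  new_read_set(reads, provenance = path)
}

#' Filter reads by global confidence and length
#'
#' Retains reads with `global_conf >= min_global_conf` (the ALC cutoff,
#' non-strict, default 0.85) and length within `[min_len, max_len]`
#' (default 5-40 aa, the range typical of de novo reads from LC-MS/MS).
#' Dropped counts are accumulated per criterion in `filter_log`.
#'
#' @param rs a `read_set`.
#' @param min_global_conf fraction in `[0, 1]`.
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered `read_set`, order preserved.
#' @export
filter_reads <- function(rs, min_global_conf = 0.85, min_len = 5,
                         max_len = 40) {
  if (min_global_conf < 0 || min_global_conf > 1)
    validation_error("min_global_conf must be in [0, 1]")
  if (min_len > max_len) validation_error("min_len must be <= max_len")
  gc <- vapply(rs$reads, `[[`, 0, "global_conf")
  len <- vapply(rs$reads, function(r) nchar(r$sequence), 0L)
  keep_conf <- gc >= min_global_conf
  keep_len <- len >= min_len & len <= max_len
  log_add <- c(low_confidence = sum(!keep_conf),
               length_out_of_range = sum(keep_conf & !keep_len))
  rs$reads <- rs$reads[keep_conf & keep_len]
  rs$filter_log <- c(rs$filter_log, log_add)
  rs
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", length(x$reads), "reads")
  if (length(x$filter_log) > 0)
    cat(" (dropped:", paste(names(x$filter_log), x$filter_log, sep = "=",
                            collapse = ", "), ")")
  cat("\n")
  invisible(x)
}
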