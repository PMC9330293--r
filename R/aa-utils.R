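# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "abassembly_error")))
}

format_error <- function(...) abort(..., class = "abassembly_format_error")
config_error <- function(...) abort(..., class = "abassembly_config_error")
validation_error <- function(...) abort(..., class = "abassembly_validation_error")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# FASTA I/O through seqinr; headers keep everything after '>'.
read_fasta_file <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       whole.header = TRUE),
    error = function(e) format_error("empty or malformed FASTA file: ", path))
  out <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  out
}

write_fasta_file <- function(seqs, headers, path) {
  seqinr::write.fasta(as.list(seqs), names = headers, file.out = path,
                      nbchar = 60)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
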