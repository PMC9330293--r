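# Shared fixtures and independent oracles for the test suite.

AA_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_str <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AA_TEST, exclude), n, replace = TRUE), collapse = "")
}

make_read <- function(id, seq, lc = 1, gc = 1, area = NA_real_) {
  if (length(lc) == 1L) lc <- rep(lc, nchar(seq))
  abassembly:::new_read(id, seq, lc, gc, area)
}

make_read_set <- function(reads) abassembly:::new_read_set(reads)

# Error-free reads tiling `seq` with fixed length and step; the final read is
# anchored at the end so every position is covered.
tiling_reads <- function(seq, len = 20, step = 10, prefix = "tile") {
  n <- nchar(seq)
  len <- min(len, n)
  starts <- unique(c(seq(1, max(1, n - len + 1), by = step), n - len + 1))
  lapply(seq_along(starts), function(i)
    make_read(sprintf("%s%03d", prefix, i),
              substr(seq, starts[i], starts[i] + len - 1)))
}

one_template_db <- function(seq, id = "T1", group = "heavy", klass = "V") {
  template_database(list(template_segment(id, seq, group, klass)),
                    deduplicate = FALSE)
}

# Independent exhaustive oracle for optimal local alignment score: dynamic
# accumulation over every pair of predecessor aligned columns, with
# closed-form gap-run costs (no affine three-state recurrence). Any local
# alignment decomposes into aligned columns separated by gap runs whose
# costs are gap_open + (len-1) * gap_extend per run; optimal alignments
# start and end on aligned columns, so maximizing over all monotone chains
# of aligned pairs is exhaustive.
oracle_local_score <- function(a, b, alphabet) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  mat <- alphabet$matrix
  gapcost <- function(g)
    if (g > 0) alphabet$gap_open + (g - 1) * alphabet$gap_extend else 0
  best <- matrix(0, n, m)
  overall <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[A[i], B[j]]
    prev <- 0
    if (i > 1 && j > 1) {
      for (pi in seq_len(i - 1)) for (pj in seq_len(j - 1)) {
        cand <- best[pi, pj] - gapcost(i - pi - 1) - gapcost(j - pj - 1)
        if (cand > prev) prev <- cand
      }
    }
    best[i, j] <- s + prev
    overall <- max(overall, best[i, j])
  }
  overall
}

# Re-derive the raw score of an alignment from its path (checks that the
# reported path is consistent with the reported score).
rescore_path <- function(al, read_seq, tmpl_seq, alphabet) {
  if (al$raw_score == 0) return(0)
  steps <- strsplit(al$path, "")[[1]]
  ri <- al$read_start
  ti <- al$tmpl_start
  score <- 0
  prev_gap <- ""
  for (st in steps) {
    if (st == "M") {
      score <- score + alphabet$matrix[substr(read_seq, ri, ri),
                                       substr(tmpl_seq, ti, ti)]
      ri <- ri + 1; ti <- ti + 1
      prev_gap <- ""
    } else {
      score <- score - if (prev_gap == st) alphabet$gap_extend
                       else alphabet$gap_open
      if (st == "D") ti <- ti + 1 else ri <- ri + 1
      prev_gap <- st
    }
  }
  score
}

# Global-alignment identity fraction (I and L distinguished).
seq_identity <- function(a, b, alphabet = default_alphabet()) {
  res <- abassembly:::.cpp_nw_align(
    abassembly:::encode_seq(a, alphabet),
    abassembly:::encode_seq(b, alphabet),
    alphabet$matrix, alphabet$gap_open, alphabet$gap_extend)
  res$identical / res$columns
}

# A small complete synthetic study (database + antibody + reads), written to
# a temporary directory as a runnable fixture.
small_fixture <- function(seed = 1, dir = tempfile("fx"), overrides = c(
                            recombine = "true", decoy = "true",
                            placement = "best")) {
  cfg <- simulation_config(seed = seed)
  gdb <- generate_germline_db(cfg)
  truth <- simulate_antibody(gdb, cfg)
  sim <- simulate_read_set(truth, cfg)
  path <- write_fixture(dir, gdb, truth, sim, config_overrides = overrides)
  list(cfg = cfg, gdb = gdb, truth = truth, sim = sim, dir = dir,
       config = path)
}
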