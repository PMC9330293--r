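# Scoring alphabet, Smith-Waterman engine, cutoff normalization and
# unique/shared placement.

test_that("the default alphabet is BLOSUM62 with I/L and X overrides", {
  ab <- default_alphabet()
  expect_equal(ab$matrix["A", "A"], 4)
  expect_equal(ab$matrix["R", "R"], 5)
  expect_equal(ab$matrix["W", "W"], 11)
  expect_equal(ab$matrix["A", "R"], -1)
  # isobaric I/L scored as identical
  expect_equal(ab$matrix["I", "L"], ab$matrix["L", "L"])
  expect_equal(ab$matrix["I", "L"], 4)
  # X wildcard is neutral
  expect_true(all(ab$matrix["X", ] == 0))
  expect_true(isSymmetric(ab$matrix))
  expect_equal(ab$gap_open, 12)
  expect_equal(ab$gap_extend, 1)
})

test_that("the inlined BLOSUM62 block matches the Biostrings reference", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ref <- get("BLOSUM62", envir = environment())
  ab <- default_alphabet()
  syms <- setdiff(rownames(ab$matrix), "X")
  m <- ab$matrix[syms, syms]
  other <- setdiff(syms, c("I", "L"))
  # everything outside the merged I/L class is plain BLOSUM62
  expect_equal(m[other, other], ref[other, other])
  # the I/L class takes the more favorable BLOSUM62 score per residue
  for (x in other) {
    expect_equal(unname(m["I", x]), max(ref["I", x], ref["L", x]), info = x)
    expect_equal(unname(m["L", x]), unname(m["I", x]), info = x)
  }
})

test_that("local alignment reproduces hand-computed scores and paths", {
  ab <- default_alphabet()
  al <- smith_waterman("ACDEFG", "ACDEFG", ab)
  expect_equal(al$raw_score, 36)  # 4 + 9 + 6 + 5 + 6 + 6
  expect_equal(al$path, "MMMMMM")
  expect_equal(al$norm_score, 36 / sqrt(6))

  al0 <- smith_waterman("AAAA", "PPPP", ab)
  expect_equal(al0$raw_score, 0)
  expect_equal(al0$path, "")

  expect_error(smith_waterman("AC1DE", "ACDE", ab), "'1'")
  expect_error(smith_waterman("", "ACDE", ab), "nonempty")
})

test_that("optimal scores equal the exhaustive enumeration oracle", {
  ab <- default_alphabet()
  set.seed(101)
  for (k in 1:150) {
    a <- random_aa_str(sample(2:8, 1))
    b <- random_aa_str(sample(2:8, 1))
    al <- smith_waterman(a, b, ab)
    expect_equal(al$raw_score, oracle_local_score(a, b, ab),
                 info = paste(a, b))
    # the reported path re-scores to the reported optimum
    expect_equal(rescore_path(al, a, b, ab), al$raw_score,
                 info = paste(a, b, al$path))
  }
})

test_that("alignment score is symmetric and invariant under I<->L", {
  ab <- default_alphabet()
  set.seed(202)
  for (k in 1:40) {
    a <- random_aa_str(sample(5:15, 1))
    b <- random_aa_str(sample(5:15, 1))
    expect_equal(smith_waterman(a, b, ab)$raw_score,
                 smith_waterman(b, a, ab)$raw_score)
    a_il <- chartr("IL", "LI", a)
    expect_equal(smith_waterman(a_il, b, ab)$raw_score,
                 smith_waterman(a, b, ab)$raw_score)
  }
})

two_template_ms <- function(mode = "all") {
  db <- template_database(list(
    template_segment("T1", "ACDEFGHIKLMNPQRSTVWY", "heavy", "V"),
    template_segment("T2", "ACDEFGHIKWWWWWWWWWWW", "heavy", "V"),
    template_segment("T3", "ACDEFGHIKLMNPQRSTVWY", "light", "V")),
    deduplicate = FALSE)
  rs <- make_read_set(list(make_read("r_full", "ACDEFGHIKLMNPQRST"),
                           make_read("r_tie", "ACDEFGHIK")))
  ms <- match_reads(rs, db, default_alphabet(), cutoff = 8)
  assign_placement(ms, mode)
}

test_that("matching applies the sqrt-length-normalized cutoff", {
  db <- one_template_db("ACDEFGHIKLMNPQRSTVWY")
  rs <- make_read_set(list(make_read("r1", "ACDEFG")))
  ab <- default_alphabet()
  ms <- match_reads(rs, db, ab, cutoff = 8)
  expect_equal(nrow(ms$alignments), 1)          # 36 / sqrt(6) = 14.7 >= 8
  ms15 <- match_reads(rs, db, ab, cutoff = 15)
  expect_equal(nrow(ms15$alignments), 0)        # 14.7 < 15
  expect_error(match_reads(rs, db, ab, cutoff = -1), "nonnegative")
  # raising the cutoff never adds a placement
  prev <- Inf
  for (cut in c(0, 4, 8, 12, 16)) {
    n <- nrow(match_reads(rs, db, ab, cutoff = cut)$alignments)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("best-mode placement keeps score ties and flags unique reads", {
  ms <- two_template_ms("best")
  df <- ms$alignments
  # r_full scores strictly best on T1 within the heavy group: unique there
  full_heavy <- df[df$read_id == "r_full" & df$group == "heavy", ]
  expect_equal(full_heavy$template_id, "T1")
  expect_true(full_heavy$is_unique)
  # r_tie scores equally on T1 and T2: placed on both, not unique
  tie <- df[df$read_id == "r_tie" & df$group == "heavy", ]
  expect_setequal(tie$template_id, c("T1", "T2"))
  expect_false(any(tie$is_unique))

  # mode "all" keeps every above-cutoff placement
  all_ms <- two_template_ms("all")
  expect_gte(nrow(all_ms$alignments), nrow(ms$alignments))
})

test_that("per-template total score equals the sum over its alignments", {
  ms <- two_template_ms("all")
  summ <- summarize_matches(ms)
  for (i in seq_len(nrow(summ))) {
    rows <- ms$alignments[ms$alignments$template_id == summ$template_id[i], ]
    expect_equal(summ$total_score[i], sum(rows$raw_score))
    expect_lte(summ$unique_score[i], summ$total_score[i])
    expect_lte(summ$unique_read_count[i], summ$read_count[i])
  }
  # empty database is a configuration error
  rs <- make_read_set(list(make_read("r1", "ACDEF")))
  empty_db <- structure(list(groups = list(), decoys = list()),
                        class = "template_database")
  expect_error(match_reads(rs, empty_db, default_alphabet()), "empty")
})
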