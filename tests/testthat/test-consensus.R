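# Weighted consensus calling, area/position weights and I/L resolution.

test_that("the MS1 area weight follows 2 - 1/log10(area), clamped to [1, 2]", {
  expect_equal(area_weight(10), 1)
  expect_equal(area_weight(1e4), 1.75)
  expect_equal(area_weight(NA), 1)
  expect_equal(area_weight(0), 1)
  expect_error(area_weight(-5), "nonnegative")
  # nondecreasing and bounded over random areas
  set.seed(7)
  areas <- sort(10^runif(500, -2, 12))
  w <- vapply(areas, area_weight, 0)
  expect_true(all(w >= 1 & w <= 2))
  expect_true(all(diff(w) >= 0))
})

test_that("position weights are multiplicative with an absorbing zero", {
  r <- make_read("r", "ACDEF", lc = c(1, 0.5, 0, 1, 1), gc = 0.9,
                 area = 1e4)
  expect_equal(position_weight(r, 1), 0.9 * 1.75)
  expect_equal(position_weight(r, 2), 0.5 * 0.9 * 1.75)
  expect_equal(position_weight(r, 3), 0)
  r1 <- make_read("r1", "A", lc = 1, gc = 1)
  expect_equal(position_weight(r1, 1), 1)
  expect_error(position_weight(r, 9), "out of range")
})

# Align a list of reads onto a single-template database and build the
# consensus through the public matching interface.
consensus_of <- function(template_seq, reads, cutoff = 8) {
  db <- one_template_db(template_seq)
  rs <- make_read_set(reads)
  ms <- match_reads(rs, db, default_alphabet(), cutoff)
  build_consensus(db$groups$heavy$V[[1]], ms$alignments, rs)
}

test_that("the consensus residue is the weighted majority per column", {
  tmpl <- "GGGGGGGGGG"
  # three reads vote A at column 5, one votes G; elsewhere reads agree
  reads <- list(make_read("a1", "GGGGAGGGGG"),
                make_read("a2", "GGGGAGGGGG"),
                make_read("a3", "GGGGAGGGGG"),
                make_read("g1", "GGGGGGGGGG"))
  cr <- consensus_of(tmpl, reads)
  expect_equal(substr(cr$consensus, 5, 5), "A")
  # weight conservation: deposited weight equals the summed position weights
  total_deposited <- sum(vapply(cr$columns, function(col)
    sum(col$weights), 0))
  expect_equal(total_deposited, 4 * 10)  # unit weights, 10 residues each
})

test_that("uncovered regions default to the template", {
  tmpl <- "ACDEFGHIKLMNPQRSTVWY"
  cr <- consensus_of(tmpl, list())
  expect_equal(cr$consensus, tmpl)
  expect_equal(cr$template_filled, 1:20)

  # partial coverage: only the uncovered tail is template-filled
  cr2 <- consensus_of(tmpl, list(make_read("r", "ACDEFGHIK")))
  expect_equal(cr2$consensus, tmpl)
  expect_equal(cr2$template_filled, 10:20)
})

test_that("error-free tiling reads reproduce the template exactly", {
  set.seed(11)
  for (k in 1:5) {
    tmpl <- random_aa_str(60)
    cr <- consensus_of(tmpl, tiling_reads(tmpl))
    expect_equal(cr$consensus, tmpl)
    expect_length(cr$template_filled, 0)
    expect_true(all(cr$depth >= 1))
  }
})

test_that("consensus is invariant to read input order", {
  set.seed(12)
  tmpl <- random_aa_str(50)
  reads <- tiling_reads(tmpl, len = 15, step = 5)
  reads[[2]]$sequence <- sub("^(.)", "W", reads[[2]]$sequence)  # a variant
  cr1 <- consensus_of(tmpl, reads)
  cr2 <- consensus_of(tmpl, rev(reads))
  expect_equal(cr1$consensus, cr2$consensus)
  expect_equal(cr1$depth, cr2$depth)
})

test_that("read-supported deletions drop the column; insertions are emitted by weight", {
  tmpl <- "ACDEFGHIKLMNPQRSTVWY"
  # every read skips the F column
  del_read <- paste0(substr(tmpl, 1, 4), substr(tmpl, 6, 20))
  cr <- consensus_of(tmpl, list(make_read("d1", del_read),
                                make_read("d2", del_read)))
  expect_equal(cr$consensus, del_read)
  expect_equal(cr$deleted, 5L)

  # every read carries a W inserted between columns 10 and 11
  ins_read <- paste0(substr(tmpl, 1, 10), "W", substr(tmpl, 11, 20))
  cr2 <- consensus_of(tmpl, list(make_read("i1", ins_read),
                                 make_read("i2", ins_read)))
  expect_equal(cr2$consensus, ins_read)
})

test_that("I/L columns are resolved toward template isoleucine only", {
  tmpl <- "AAIAALAAFA"
  db <- one_template_db(tmpl)
  seg <- db$groups$heavy$V[[1]]
  # reads report L everywhere an I/L is present (isobaric collapse)
  obs <- chartr("I", "L", tmpl)
  rs <- make_read_set(list(make_read("r1", obs), make_read("r2", obs)))
  ms <- match_reads(rs, db, default_alphabet(), 8)
  cr <- build_consensus(seg, ms$alignments, rs)
  out <- resolve_il(cr, seg)
  expect_equal(out$consensus, tmpl)    # I restored at column 3 only
  expect_equal(out$il_resolved, 3L)
  # consensus L with template L stays L; F column untouched
  expect_equal(substr(out$consensus, 6, 6), "L")
  expect_equal(substr(out$consensus, 9, 9), "F")
})

test_that("mixed non-I/L support blocks I/L resolution", {
  tmpl <- "AAIAAAAAAA"
  db <- one_template_db(tmpl)
  seg <- db$groups$heavy$V[[1]]
  rs <- make_read_set(list(make_read("r1", "AALAAAAAAA"),
                           make_read("r2", "AALAAAAAAA"),
                           make_read("r3", "AAFAAAAAAA")))
  ms <- match_reads(rs, db, default_alphabet(), 5)
  cr <- resolve_il(build_consensus(seg, ms$alignments, rs), seg)
  # support includes F, so the column is not an I/L-only column
  expect_length(cr$il_resolved, 0)
})
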