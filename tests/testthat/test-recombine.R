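# Segment ranking, junction overhang extension, sliding-window overlap and
# the decoy-aware second matching pass.

fake_match_set <- function(df) {
  df$is_unique <- df$is_unique %||% FALSE
  structure(list(alignments = df, cutoff = 8, normalize = "read_length",
                 mode = "all"), class = "match_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-N selection ranks by total score with forced overrides", {
  db <- template_database(list(
    template_segment("V1", "ACDEFGHIKL", "heavy", "V"),
    template_segment("V2", "ACDEFGHIKW", "heavy", "V"),
    template_segment("V3", "ACDEFGHIWW", "heavy", "V")),
    deduplicate = FALSE)
  df <- data.frame(
    read_id = c("r1", "r2", "r3"), template_id = c("V1", "V1", "V2"),
    group = "heavy", segment_class = "V",
    read_start = 1L, read_end = 5L, tmpl_start = 1L, tmpl_end = 5L,
    path = "MMMMM", raw_score = c(60, 40, 50), norm_score = 10,
    ms1_area = 0, stringsAsFactors = FALSE)
  ms <- fake_match_set(df)
  plan <- recombination_plan(order = c("V"), n_per_segment = 1)
  expect_equal(rank_and_select(ms, plan, db)$V, "V1")     # 100 > 50
  plan2 <- recombination_plan(order = c("V"), n_per_segment = 2)
  expect_equal(rank_and_select(ms, plan2, db)$V, c("V1", "V2"))
  planf <- recombination_plan(order = c("V"),
                              forced_templates = c(V = "V2"))
  expect_equal(rank_and_select(ms, planf, db)$V, "V2")
  planbad <- recombination_plan(order = c("V"),
                                forced_templates = c(V = "nope"))
  expect_error(rank_and_select(ms, planbad, db), "not in the database")
})

test_that("overhanging reads extend V and J by exactly the covered junction residues", {
  set.seed(31)
  v <- random_aa_str(40, exclude = "I")
  j <- random_aa_str(15, exclude = "I")
  junction <- "WRDGNK"  # 6 junction residues between V and J
  chain <- paste0(v, junction, j)
  ab <- default_alphabet()

  # reads extending 7 residues past the V end (junction + 1 residue of J)
  over_v <- lapply(1:3, function(i)
    make_read(paste0("ov", i), substr(chain, 26, 47)))   # 40 + 7
  ext <- extend_with_overhangs(v, j, make_read_set(over_v), ab)
  expect_equal(ext$v_overhang, 7)
  expect_equal(ext$v_ext, substr(chain, 1, 47))
  expect_equal(ext$j_overhang, 0)

  # no read extends past the V end: nothing is gained
  inside <- lapply(1:3, function(i)
    make_read(paste0("in", i), substr(v, 10, 30)))
  ext0 <- extend_with_overhangs(v, j, make_read_set(inside), ab)
  expect_equal(ext0$v_overhang, 0)
  expect_equal(ext0$v_ext, v)

  # the extension never exceeds the 20 placeholder positions
  long_tail <- make_read_set(list(
    make_read("lt", paste0(substr(v, 21, 40), random_aa_str(30)))))
  extl <- extend_with_overhangs(v, j, long_tail, ab)
  expect_lte(extl$v_overhang, 20)
  expect_equal(extl$v_overhang, 20)
})

test_that("the sliding window finds the junction overlap and merges with V precedence", {
  ab <- default_alphabet()
  jx <- reconstruct_junction("QQQQCARDRS", "DRSWGQGTLV", ab)
  expect_equal(jx$overlap_len, 3)            # "DRS"
  expect_false(jx$gap_inserted)
  expect_equal(jx$sequence, "QQQQCARDRSWGQGTLV")

  # identical 40-mers overlap across the whole window
  s40 <- random_aa_str(40)
  jx40 <- reconstruct_junction(s40, s40, ab)
  expect_equal(jx40$overlap_len, 40)
  expect_equal(jx40$sequence, s40)

  # no positive score anywhere: single gap
  jxg <- reconstruct_junction("AAAAAA", "PPPPPP", ab)
  expect_true(jxg$gap_inserted)
  expect_equal(jxg$overlap_len, 0)
  expect_equal(jxg$sequence, "AAAAAAPPPPPP")

  # zero overhang coverage on both sides: gap regardless of homology
  jxz <- reconstruct_junction("QQQQCARDRS", "DRSWGQGTLV", ab,
                              v_overhang = 0, j_overhang = 0)
  expect_true(jxz$gap_inserted)

  # V-side spill past the J end is trimmed (containment case)
  v_ext <- paste0("QQQQQQQQQQ", "WGQGTLVTVSS", "AST")  # runs 3 into C
  jx_c <- reconstruct_junction(v_ext, "WGQGTLVTVSS", ab)
  expect_equal(jx_c$sequence, "QQQQQQQQQQWGQGTLVTVSS")
  expect_equal(jx_c$v_trimmed, 3)
})

test_that("reads best-scoring on a decoy are excluded from the second pass", {
  ab <- default_alphabet()
  rec_seq <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL"
  # homologous decoy: four dissimilar substitutions into the target
  dc <- strsplit(rec_seq, "")[[1]]
  dc[c(5, 9, 13, 17)] <- c("P", "D", "W", "D")
  decoy_seq <- paste(dc, collapse = "")
  db <- template_database(list(
    template_segment("sel", rec_seq, "heavy", "V"),
    template_segment("dec", decoy_seq, "heavy", "V")),
    deduplicate = FALSE)
  rec <- recombine_templates(list(V = "sel"),
                             setNames(list(list(consensus = rec_seq)), "sel"),
                             make_read_set(list()), ab,
                             recombination_plan(order = "V"), group = "heavy")
  rs <- make_read_set(list(
    make_read("sig", substr(rec_seq, 3, 18)),      # belongs to the target
    make_read("bg", substr(decoy_seq, 3, 18))))    # belongs to the decoy
  sp_off <- second_pass(rec, db, rs, ab, use_decoys = FALSE,
                        selected_ids = "sel")
  sp_on <- second_pass(rec, db, rs, ab, use_decoys = TRUE,
                       selected_ids = "sel")
  ids_off <- unique(sp_off$match_set$alignments$read_id)
  ids_on <- unique(sp_on$match_set$alignments$read_id)
  expect_true("sig" %in% ids_on)
  expect_false("bg" %in% ids_on)
  # decoy monotonicity: decoys never add contributing reads
  expect_true(all(ids_on %in% ids_off))
  expect_equal(sp_on$n_decoy_excluded, length(setdiff(ids_off, ids_on)))
  # without background reads the two settings agree
  rs_clean <- make_read_set(list(make_read("sig", substr(rec_seq, 3, 18))))
  c_off <- second_pass(rec, db, rs_clean, ab, use_decoys = FALSE,
                       selected_ids = "sel")$consensus[[1]]$consensus
  c_on <- second_pass(rec, db, rs_clean, ab, use_decoys = TRUE,
                      selected_ids = "sel")$consensus[[1]]$consensus
  expect_equal(c_off, c_on)
})

test_that("a clean monoclonal run recombines V-junction-J-C into the true chain", {
  cfg <- simulation_config(seed = 41, shm_rate = 0, read_error_rate = 0,
                           il_collapse = FALSE, depth = 12)
  gdb <- generate_germline_db(cfg)
  truth <- simulate_antibody(gdb, cfg)
  sim <- simulate_read_set(truth, cfg)
  dir <- tempfile("clean")
  p <- write_fixture(dir, gdb, truth, sim,
                     config_overrides = c(recombine = "true",
                                          placement = "best"))
  res <- run_pipeline(p, write_artifacts = FALSE)
  for (g in c("heavy", "light")) {
    sel <- res$selection[[g]]
    ch <- truth$chains[[g]]
    expect_equal(sel$V, ch$v_id)
    expect_equal(sel$J, ch$j_id)
    expect_equal(sel$C, ch$c_id)
    got <- res$second_pass[[g]]$consensus[[1]]$consensus
    expect_equal(got, ch$chain_seq)
  }
  unlink(dir, recursive = TRUE)
})
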