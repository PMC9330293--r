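# Cladogram construction, read placement, summaries and CDR tables.

seg3 <- function() list(
  template_segment("T1", "AAAA", "heavy", "V"),
  template_segment("T2", "AAAT", "heavy", "V"),
  template_segment("T3", "TTTT", "heavy", "V"))

test_that("cladograms follow pairwise identity distances", {
  ab <- default_alphabet()
  single <- build_cladogram(list(template_segment("T1", "ACDE", "heavy", "V")),
                            ab)
  expect_length(single$children, 0)
  expect_equal(single$members, "T1")

  twins <- build_cladogram(list(
    template_segment("A", "ACDEF", "heavy", "V"),
    template_segment("B", "ACDEF", "light", "V")), ab)
  expect_equal(twins$height, 0)

  # AAAA and AAAT (distance 0.25) merge before TTTT (0.75 / 1.0) joins
  tree <- build_cladogram(seg3(), ab)
  expect_setequal(tree$members, c("T1", "T2", "T3"))
  kid_members <- lapply(tree$children, `[[`, "members")
  expect_true(list(c("T1", "T2")) %in% kid_members ||
                any(vapply(kid_members, function(m)
                  setequal(m, c("T1", "T2")), logical(1))))
})

place_fixture <- function() {
  tree <- build_cladogram(seg3(), default_alphabet())
  df <- data.frame(
    read_id = c("u1", "s12", "s12", "sall", "sall", "sall"),
    template_id = c("T1", "T1", "T2", "T1", "T2", "T3"),
    group = "heavy", segment_class = "V",
    read_start = 1L, read_end = 4L, tmpl_start = 1L, tmpl_end = 4L,
    path = "MMMM", raw_score = c(20, 15, 15, 10, 10, 10),
    norm_score = 8, ms1_area = 100, is_unique = FALSE,
    stringsAsFactors = FALSE)
  ms <- structure(list(alignments = df, cutoff = 8,
                       normalize = "read_length", mode = "all"),
                  class = "match_set")
  ms <- assign_placement(ms, "all")
  list(tree = tree, ms = ms)
}

test_that("unique reads land on leaves, shared reads on their lowest common node", {
  fx <- place_fixture()
  out <- place_reads(fx$tree, fx$ms)
  nodes <- abassembly:::clade_nodes(out$tree)
  placed <- lapply(nodes, `[[`, "placed_reads")
  members <- lapply(nodes, `[[`, "members")
  # u1 on the T1 leaf
  leaf1 <- which(vapply(nodes, function(n)
    identical(n$members, "T1"), logical(1)))
  expect_true("u1" %in% placed[[leaf1]])
  # s12 (tied T1/T2) on the node whose members are exactly {T1, T2}
  n12 <- which(vapply(members, function(m)
    setequal(m, c("T1", "T2")), logical(1)))
  expect_true("s12" %in% placed[[n12]])
  # sall (tied on everything) at the root
  expect_true("sall" %in% out$tree$placed_reads)

  # conservation: every matched read placed exactly once
  all_placed <- unlist(placed)
  expect_setequal(all_placed, c("u1", "s12", "sall"))
  expect_equal(length(all_placed), 3)

  # a read sits on a leaf iff it is unique
  df <- out$placements
  expect_equal(df$is_unique[df$read_id == "u1"], TRUE)
  expect_equal(df$is_unique[df$read_id == "s12"], FALSE)
  for (i in seq_along(nodes)) {
    for (rid in placed[[i]]) {
      expect_equal(length(nodes[[i]]$children) == 0,
                   df$is_unique[df$read_id == rid])
    }
  }
})

test_that("summaries count shared reads on every template but unique on none", {
  fx <- place_fixture()
  summ <- summarize_matches(fx$ms)
  expect_equal(summ$template_id[1], "T1")  # highest total score first
  t1 <- summ[summ$template_id == "T1", ]
  expect_equal(t1$read_count, 3)           # u1, s12, sall
  expect_equal(t1$unique_read_count, 1)    # u1 only
  expect_equal(t1$total_score, 45)
  expect_equal(t1$unique_score, 20)
  t3 <- summ[summ$template_id == "T3", ]
  expect_equal(t3$read_count, 1)
  expect_equal(t3$unique_read_count, 0)
  # empty match set
  empty <- structure(list(alignments = fx$ms$alignments[0, ]),
                     class = "match_set")
  expect_equal(nrow(summarize_matches(empty)), 0)
})

test_that("a single unique read yields the singleton summary row", {
  db <- one_template_db("ACDEFGHIKLMNPQRSTVWY")
  rs <- make_read_set(list(make_read("r1", "ACDEFGHIKL", area = 100)))
  ms <- assign_placement(match_reads(rs, db, default_alphabet(), 8), "best")
  summ <- summarize_matches(ms)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$read_count, 1)
  expect_equal(summ$unique_read_count, 1)
  expect_equal(summ$summed_area, 100)
  expect_equal(summ$unique_area, 100)
  expect_equal(summ$total_score, summ$unique_score)
})

test_that("CDR tables list alignments by region intersection", {
  seg <- template_segment("V1", strrep("A", 60), "heavy", "V",
                          regions = data.frame(
                            label = c("CDR1", "CDR2"),
                            start = c(25, 40), end = c(33, 48)))
  db <- template_database(list(seg), deduplicate = FALSE)
  mk_row <- function(id, from, to) data.frame(
    read_id = id, template_id = "V1", group = "heavy", segment_class = "V",
    read_start = 1L, read_end = to - from + 1L,
    tmpl_start = from, tmpl_end = to,
    path = strrep("M", to - from + 1L), raw_score = 10, norm_score = 8,
    ms1_area = 0, is_unique = TRUE, stringsAsFactors = FALSE)
  df <- rbind(mk_row("in_cdr1", 21, 35),    # spans [26, 33] (1-based CDR1)
              mk_row("framework", 1, 20),   # intersects nothing
              mk_row("both", 20, 50))       # spans CDR1 and CDR2
  ms <- structure(list(alignments = df), class = "match_set")
  tab <- collect_cdr_reads(ms, db)
  expect_setequal(tab$read_id[tab$cdr == "CDRH1"], c("in_cdr1", "both"))
  expect_setequal(tab$read_id[tab$cdr == "CDRH2"], "both")
  expect_false("framework" %in% tab$read_id)
  # every listed span intersects the labeled region
  expect_true(all(tab$tmpl_start <= tab$tmpl_end))
})

test_that("Newick export parses and carries the right tips", {
  fx <- place_fixture()
  out <- place_reads(fx$tree, fx$ms)
  nwk <- cladogram_newick(out$tree)
  tr <- ape::read.tree(text = gsub("\\[[0-9]+\\]", "", nwk))
  expect_setequal(tr$tip.label, c("T1", "T2", "T3"))
})
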