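# Synthetic data generation: germline families, antibody simulation,
# in-silico digestion and noisy read sets.

test_that("germline databases are deterministic, sized and nonredundant", {
  cfg <- simulation_config(seed = 9)
  g1 <- generate_germline_db(cfg)
  g2 <- generate_germline_db(cfg)
  s1 <- vapply(abassembly:::db_segments(g1$db), `[[`, "", "sequence")
  s2 <- vapply(abassembly:::db_segments(g2$db), `[[`, "", "sequence")
  expect_identical(s1, s2)
  for (chain in c("heavy", "light")) {
    expect_length(g1$db$groups[[chain]]$V, 20)
    expect_length(g1$db$groups[[chain]]$J, 5)
    expect_length(g1$db$groups[[chain]]$C, 3)
  }
  expect_false(anyDuplicated(s1) > 0)
  # V segments carry the three region annotations
  v1 <- g1$db$groups$heavy$V[[1]]
  expect_setequal(v1$regions$label, c("CDR1", "CDR2", "CDR3-anchor"))
})

test_that("antibody simulation recombines V-junction-J-C with SHM on the variable region", {
  cfg0 <- simulation_config(seed = 9, shm_rate = 0)
  gdb <- generate_germline_db(cfg0)
  truth <- simulate_antibody(gdb, cfg0)
  h <- truth$chains$heavy
  v <- abassembly:::db_find(gdb$db, h$v_id)$sequence
  j <- abassembly:::db_find(gdb$db, h$j_id)$sequence
  cc <- abassembly:::db_find(gdb$db, h$c_id)$sequence
  expect_equal(h$chain_seq, paste0(v, h$junction, j, cc))
  expect_gte(nchar(h$junction), cfg0$d_region_len[1])
  expect_lte(nchar(h$junction), cfg0$d_region_len[2])
  # light chain: direct V-J abutment
  l <- truth$chains$light
  expect_equal(l$junction, "")

  # SHM substitution count behaves binomially (3 sigma over 200 draws)
  cfg5 <- simulation_config(seed = 9, shm_rate = 0.05)
  n_var <- 0
  n_sub <- 0
  for (k in 1:200) {
    t5 <- simulate_antibody(gdb, cfg5, seed_offset = 1000 + k)
    h5 <- t5$chains$heavy
    germ <- paste0(abassembly:::db_find(gdb$db, h5$v_id)$sequence,
                   h5$junction,
                   abassembly:::db_find(gdb$db, h5$j_id)$sequence)
    varseq <- substr(h5$chain_seq, 1, nchar(germ))
    d <- sum(strsplit(germ, "")[[1]] != strsplit(varseq, "")[[1]])
    n_var <- n_var + nchar(germ)
    n_sub <- n_sub + d
  }
  p_hat <- n_sub / n_var
  # observed substitutions can be slightly below the nominal rate because a
  # junction residue mutated onto itself is impossible, but back-to-back
  # criteria: within 3 sigma of binomial expectation
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n_var) + 1e-9)
  # constant region is left germline
  c5 <- abassembly:::db_find(gdb$db, truth$chains$heavy$c_id)$sequence
  expect_equal(substr(truth$chains$heavy$chain_seq,
                      truth$chains$heavy$c_span[1],
                      truth$chains$heavy$c_span[2]), c5)
})

test_that("protease rules cleave as specified and conserve the sequence", {
  d <- digest_in_silico("AKRPGK", "trypsin", 0)
  expect_equal(d$peptide, c("AK", "RPGK"))  # R before P is not cleaved
  expect_equal(digest_in_silico("AAAA", "gluc", 0)$peptide, "AAAA")
  # fragments with 0 missed cleavages concatenate back to the input
  set.seed(21)
  for (p in c("trypsin", "chymotrypsin", "gluc", "aspn", "elastase",
              "thermolysin")) {
    s <- random_aa_str(80)
    frag <- digest_in_silico(s, p, 0)
    expect_equal(paste(frag$peptide, collapse = ""), s)
    expect_true(all(substring(s, frag$start, frag$end) == frag$peptide))
  }
  # missed cleavages add concatenations of <= m+1 adjacent fragments
  base <- digest_in_silico("AKCKDKEK", "trypsin", 0)
  m1 <- digest_in_silico("AKCKDKEK", "trypsin", 1)
  expect_equal(nrow(m1), nrow(base) + (nrow(base) - 1))
  expect_true("AKCK" %in% m1$peptide)
})

test_that("aspN and thermolysin cleave before their target residues", {
  expect_equal(digest_in_silico("AADGGDAA", "aspn", 0)$peptide,
               c("AA", "DGG", "DAA"))
  expect_equal(digest_in_silico("GGFGG", "thermolysin", 0)$peptide,
               c("GG", "FGG"))
})

test_that("read simulation respects error rate, depth and determinism", {
  cfg <- simulation_config(seed = 13, read_error_rate = 0,
                           il_collapse = FALSE)
  gdb <- generate_germline_db(cfg)
  truth <- simulate_antibody(gdb, cfg)
  sim <- simulate_read_set(truth, cfg)
  expect_gt(length(sim$read_set$reads), 100)
  chains <- vapply(truth$chains, `[[`, "", "chain_seq")
  for (r in sim$read_set$reads) {
    expect_true(grepl(r$sequence, chains["heavy"], fixed = TRUE) ||
                  grepl(r$sequence, chains["light"], fixed = TRUE))
  }
  # origins map every read onto the true chain
  org <- sim$origins
  for (i in seq_len(nrow(org))) {
    expect_lte(org$end[i], nchar(chains[[org$chain[i]]]))
  }
  # depth 0 gives an empty read set
  cfg0 <- simulation_config(seed = 13, depth = 0)
  expect_length(simulate_read_set(truth, cfg0)$read_set$reads, 0)
  # byte-identical serialization under a fixed seed
  p1 <- tempfile(); p2 <- tempfile()
  write_reads_csv(simulate_read_set(truth, cfg)$read_set, p1)
  write_reads_csv(simulate_read_set(truth, cfg)$read_set, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("observed mean coverage depth tracks the configured depth", {
  depths <- numeric(40)
  for (k in seq_len(40)) {
    cfg <- simulation_config(seed = 500 + k, n_v = 4, n_j = 2, n_c = 1,
                             family_size = 2)
    gdb <- generate_germline_db(cfg)
    truth <- simulate_antibody(gdb, cfg)
    sim <- simulate_read_set(truth, cfg)
    org <- sim$origins[sim$origins$chain == "heavy", ]
    len <- nchar(truth$chains$heavy$chain_seq)
    depths[k] <- sum(org$end - org$start + 1) / len
  }
  # sampling to the target read count gives mean per-position depth near 10;
  # 3-sigma band from the observed spread
  expect_lt(abs(mean(depths) - 10), 3 * stats::sd(depths) / sqrt(40) + 0.5)
})

test_that("reads with errors carry low local confidence at error positions", {
  cfg <- simulation_config(seed = 17, read_error_rate = 0.2,
                           il_collapse = FALSE)
  gdb <- generate_germline_db(cfg)
  truth <- simulate_antibody(gdb, cfg)
  sim <- simulate_read_set(truth, cfg)
  org <- sim$origins
  reads <- sim$read_set$reads
  ids <- vapply(reads, `[[`, "", "id")
  checked <- 0
  for (i in which(org$n_errors > 0)) {
    r <- reads[[match(org$read_id[i], ids)]]
    tru <- substr(truth$chains[[org$chain[i]]]$chain_seq, org$start[i],
                  org$end[i])
    err_pos <- which(strsplit(r$sequence, "")[[1]] != strsplit(tru, "")[[1]])
    if (length(err_pos) == 0) next
    expect_true(all(r$local_conf[err_pos] <= 0.6))
    expect_true(all(r$local_conf[-err_pos] >= 0.88))
    checked <- checked + 1
    if (checked >= 10) break
  }
  expect_gte(checked, 5)
})
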