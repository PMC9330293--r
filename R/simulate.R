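# Ground-truthed synthetic inputs: germline segment families, a recombined
# and hypermutated antibody, multi-protease in-silico digests and noisy de
# novo reads with confidence scores and MS1 areas.

#' Simulation configuration
#'
#' Defaults reflect a desk-scale antibody sequencing study: 20 V / 5 J / 3 C
#' germline templates per chain organized in homologous families, 5%
#' somatic hypermutation (within the 1-10% range typical of affinity-matured
#' antibodies), a four-protease digest, reads of 5-40 aa with 1%
#' substitution errors, mean coverage depth 10 and log-normal MS1 areas.
#'
#' @param n_v,n_j,n_c number of V/J/C templates per chain.
#' @param v_len,j_len,c_len template lengths (residues).
#' @param family_size germline templates per homologous family.
#' @param family_divergence per-residue substitution rate of a family member
#'   relative to its family ancestor (V and C segments).
#' @param j_divergence family divergence for J segments; the default is
#'   larger than for V/C because germline J genes are short and mutually
#'   quite distinct (human IGHJ genes differ at roughly 40% of positions),
#'   while V genes within a family are far more homologous.
#' @param shm_rate i.i.d. substitution rate over the variable region.
#' @param d_region_len integer range (length-2 vector) of the heavy-chain
#'   junction insert.
#' @param proteases protease names, see [digest_in_silico()].
#' @param missed_cleavages maximum missed cleavages per peptide.
#' @param read_error_rate per-residue substitution error rate of reads.
#' @param depth target mean reads per chain position.
#' @param min_read_len,max_read_len read length bounds (aa).
#' @param area_meanlog,area_sdlog log-normal MS1 area parameters.
#' @param il_collapse emit isoleucine as leucine in reads (as de novo
#'   engines do for the isobaric pair).
#' @param indel_errors also simulate indel read errors (off by default;
#'   substitutions dominate de novo sequencing errors).
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_v = 20, n_j = 5, n_c = 3,
                              v_len = 100, j_len = 16, c_len = 100,
                              family_size = 5, family_divergence = 0.12,
                              j_divergence = 0.3,
                              shm_rate = 0.05, d_region_len = c(3, 10),
                              proteases = c("trypsin", "chymotrypsin",
                                            "gluc", "aspn"),
                              missed_cleavages = 1,
                              read_error_rate = 0.01, depth = 10,
                              min_read_len = 5, max_read_len = 40,
                              area_meanlog = log(1e6), area_sdlog = 1,
                              il_collapse = TRUE, indel_errors = FALSE,
                              seed = 1) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  rates <- c(family_divergence, shm_rate, read_error_rate)
  if (any(rates < 0 | rates > 1)) validation_error("rates must be in [0, 1]")
  cfg
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Substitute each position independently with probability `rate`, skipping
# `protect`ed positions (1-based).
mutate_seq <- function(seq, rate, protect = integer(0)) {
  cc <- chars(seq)
  hit <- which(runif(length(cc)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) cc[i] <- sample(setdiff(AA20, cc[i]), 1)
  paste(cc, collapse = "")
}

#' Generate a synthetic germline template database
#'
#' Segments are generated in homologous families: a random family ancestor
#' is mutated independently per member, emulating allele families, so the
#' database exhibits the within-class homology that makes read placement
#' ambiguous. V segments carry a conserved cysteine anchoring CDR3 and are
#' annotated with CDR1/CDR2/CDR3-anchor intervals. Sequence collisions are
#' regenerated, so the database holds exactly the configured number of
#' distinct templates. Deterministic under the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with `db` (a `template_database`) and `annotations` (the
#'   sidecar data.frame, 0-based half-open intervals).
#' @export
generate_germline_db <- function(cfg) {
  set.seed(cfg$seed)
  anchor <- cfg$v_len - 7L  # conserved Cys preceding CDR3 (1-based)
  ann <- list()
  segs <- list()
  for (chain in c("heavy", "light")) {
    pre <- if (chain == "heavy") "H" else "L"
    for (klass in c("V", "J", "C")) {
      n <- cfg[[paste0("n_", tolower(klass))]]
      len <- cfg[[paste0(tolower(klass), "_len")]]
      made <- character(0)
      fam <- 0L
      while (length(made) < n) {
        fam <- fam + 1L
        ancestor <- chars(random_aa(len))
        if (klass == "V") ancestor[anchor] <- "C"
        ancestor <- paste(ancestor, collapse = "")
        div <- if (klass == "J") cfg$j_divergence else cfg$family_divergence
        for (m in seq_len(min(cfg$family_size, n - length(made)))) {
          repeat {
            s <- mutate_seq(ancestor, div,
                            protect = if (klass == "V") anchor else integer(0))
            if (!(s %in% made)) break
          }
          made <- c(made, s)
          id <- sprintf("%s%s%d-%d", pre, klass, fam, m)
          seg <- template_segment(id, s, chain, klass)
          segs[[length(segs) + 1L]] <- seg
          if (klass == "V") {
            ann[[length(ann) + 1L]] <- data.frame(
              id = id, label = c("CDR1", "CDR2", "CDR3-anchor"),
              start = c(25L, 50L, anchor - 1L),
              end = c(33L, 58L, len), stringsAsFactors = FALSE)
          } else if (klass == "J") {
            ann[[length(ann) + 1L]] <- data.frame(
              id = id, label = "CDR3-anchor", start = 0L,
              end = min(4L, len), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  annotations <- do.call(rbind, ann)
  list(db = template_database(segs, annotations = annotations),
       annotations = annotations)
}

#' Simulate a recombined, hypermutated antibody
#'
#' Draws one V, J and C template per chain, inserts a random junction
#' (D-region plus non-templated additions) of configured length between V
#' and J of the heavy chain, and applies i.i.d. substitutions at the somatic
#' hypermutation rate over the variable region (V + junction + J) only; the
#' constant region is left germline.
#'
#' @param gdb output of [generate_germline_db()] (or a compatible list with
#'   `db`).
#' @param cfg a [simulation_config()].
#' @param seed_offset added to the config seed so that a database and an
#'   antibody drawn from it use distinct RNG streams.
#' @return object of class `ground_truth`: per chain, the drawn segment ids,
#'   the junction insert, the full chain sequence and the coordinates of the
#'   V/junction/J/C blocks within it.
#' @export
simulate_antibody <- function(gdb, cfg, seed_offset = 1) {
  set.seed(cfg$seed + seed_offset)
  db <- gdb$db
  chains <- list()
  for (chain in c("heavy", "light")) {
    pick <- function(klass) {
      segs <- db$groups[[chain]][[klass]]
      segs[[sample(length(segs), 1)]]
    }
    v <- pick("V"); jj <- pick("J"); cc <- pick("C")
    jl <- if (chain == "heavy")
      sample(cfg$d_region_len[1]:cfg$d_region_len[2], 1) else 0L
    junction <- if (jl > 0) random_aa(jl) else ""
    variable <- paste0(v$sequence, junction, jj$sequence)
    variable <- mutate_seq(variable, cfg$shm_rate)
    chain_seq <- paste0(variable, cc$sequence)
    chains[[chain]] <- list(
      v_id = v$id, j_id = jj$id, c_id = cc$id,
      junction = junction,
      chain_seq = chain_seq,
      v_span = c(1L, nchar(v$sequence)),
      junction_span = if (jl > 0)
        c(nchar(v$sequence) + 1L, nchar(v$sequence) + jl) else integer(0),
      j_span = c(nchar(v$sequence) + jl + 1L,
                 nchar(v$sequence) + jl + nchar(jj$sequence)),
      c_span = c(nchar(variable) + 1L, nchar(chain_seq)))
  }
  structure(list(chains = chains, shm_rate = cfg$shm_rate),
            class = "ground_truth")
}

PROTEASE_RULES <- list(
  trypsin      = list(after = c("K", "R"), not_before = "P"),
  chymotrypsin = list(after = c("F", "W", "Y", "L"), not_before = "P"),
  gluc         = list(after = "E", not_before = character(0)),
  aspn         = list(before = "D"),
  elastase     = list(after = c("A", "V", "S", "G", "L", "I"),
                      not_before = character(0)),
  thermolysin  = list(before = c("I", "L", "V", "A", "M", "F")))

#' In-silico protease digestion
#'
#' Cleaves an amino-acid sequence by a named protease rule: trypsin (after
#' K/R not before P), chymotrypsin (after F/W/Y/L not before P), gluC
#' (after E), aspN (before D), elastase (after A/V/S/G/L/I), thermolysin
#' (before I/L/V/A/M/F). With `missed_cleavages = m`, every concatenation
#' of up to `m + 1` adjacent fragments is returned; with 0 the fragments
#' partition the sequence.
#'
#' @param sequence amino-acid string.
#' @param protease one of the built-in rule names.
#' @param missed_cleavages maximum number of missed cleavage sites.
#' @return data.frame with `peptide`, `start`, `end` (1-based, inclusive).
#' @examples
#' digest_in_silico("AKRPGK", "trypsin")  # AK | RPGK (R-P uncut)
#' @export
digest_in_silico <- function(sequence, protease, missed_cleavages = 0) {
  rule <- PROTEASE_RULES[[match.arg(protease, names(PROTEASE_RULES))]]
  cc <- chars(sequence)
  n <- length(cc)
  cut_after <- logical(n)  # cut between i and i+1
  if (!is.null(rule$after)) {
    for (i in seq_len(n - 1)) {
      if (cc[i] %in% rule$after && !(cc[i + 1] %in% rule$not_before))
        cut_after[i] <- TRUE
    }
  } else {
    for (i in seq_len(n - 1)) if (cc[i + 1] %in% rule$before) cut_after[i] <- TRUE
  }
  bounds <- c(0L, which(cut_after), n)
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > k) break
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i], end = ends[j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a noisy de novo read set from an antibody
#'
#' Chains are digested with each configured protease, fragments are filtered
#' to the configured read-length range, and reads are sampled with
#' replacement to the target mean per-position depth. Substitution errors
#' are applied at the configured rate; erroneous residues receive low local
#' confidence (so consensus weighting can suppress them) while correct
#' residues score high. The global confidence is the mean local confidence;
#' MS1 areas are drawn log-normal. With `il_collapse` every isoleucine is
#' emitted as leucine, as in PEAKS-style de novo output. Deterministic under
#' the config seed.
#'
#' @param truth a `ground_truth` from [simulate_antibody()].
#' @param cfg a [simulation_config()].
#' @param seed_offset RNG stream offset (see [simulate_antibody()]).
#' @param read_prefix prefix for read ids (also keeps spiked-in background
#'   read sets distinguishable).
#' @return list with `read_set` (a `read_set`) and `origins` (data.frame
#'   `read_id`, `chain`, `start`, `end`, `n_errors`).
#' @export
simulate_read_set <- function(truth, cfg, seed_offset = 2,
                              read_prefix = "sim") {
  set.seed(cfg$seed + seed_offset)
  reads <- list()
  origins <- list()
  ctr <- 0L
  for (chain in names(truth$chains)) {
    chain_seq <- truth$chains[[chain]]$chain_seq
    frag <- do.call(rbind, lapply(cfg$proteases, function(p)
      digest_in_silico(chain_seq, p, cfg$missed_cleavages)))
    len <- frag$end - frag$start + 1L
    frag <- frag[len >= cfg$min_read_len & len <= cfg$max_read_len, ,
                 drop = FALSE]
    if (nrow(frag) == 0L || cfg$depth <= 0) next
    mean_len <- mean(frag$end - frag$start + 1L)
    n_target <- round(cfg$depth * nchar(chain_seq) / mean_len)
    if (n_target < 1L) next
    idx <- sample(nrow(frag), n_target, replace = TRUE)
    for (i in idx) {
      ctr <- ctr + 1L
      pep <- chars(frag$peptide[i])
      err <- which(runif(length(pep)) < cfg$read_error_rate)
      for (e in err) pep[e] <- sample(setdiff(AA20, pep[e]), 1)
      lc <- round(runif(length(pep), 0.88, 1.00), 2)
      lc[err] <- round(runif(length(err), 0.30, 0.60), 2)
      sq <- paste(pep, collapse = "")
      if (cfg$il_collapse) sq <- chartr("I", "L", sq)
      id <- sprintf("%s%05d", read_prefix, ctr)
      reads[[ctr]] <- new_read(id, sq, lc, round(mean(lc), 4),
                               rlnorm(1, cfg$area_meanlog, cfg$area_sdlog),
                               source = paste0(read_prefix, ".sim"))
      origins[[ctr]] <- data.frame(read_id = id, chain = chain,
                                   start = frag$start[i], end = frag$end[i],
                                   n_errors = length(err),
                                   stringsAsFactors = FALSE)
    }
  }
  list(read_set = new_read_set(reads,
                               provenance = paste0(read_prefix, ".sim")),
       origins = if (length(origins) > 0) do.call(rbind, origins)
                 else data.frame(read_id = character(), chain = character(),
                                 start = integer(), end = integer(),
                                 n_errors = integer()))
}

#' Write a complete synthetic fixture to disk
#'
#' Emits template FASTA files per (group, class), the CDR annotation TSV,
#' the reads CSV in the PEAKS dialect, a ground-truth JSON manifest and a
#' ready-to-run batch configuration.
#'
#' @param dir output directory (created if needed).
#' @param gdb output of [generate_germline_db()].
#' @param truth a `ground_truth`.
#' @param sim output of [simulate_read_set()].
#' @param config_overrides named character vector merged into the emitted
#'   batch configuration.
#' @return path to the batch configuration file, invisibly.
#' @export
write_fixture <- function(dir, gdb, truth, sim, config_overrides = c()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- gdb$db
  cfg_lines <- character(0)
  for (chain in names(db$groups)) {
    for (klass in names(db$groups[[chain]])) {
      fn <- sprintf("templates_%s_%s.fasta", chain, klass)
      write_template_fasta(db$groups[[chain]][[klass]], file.path(dir, fn))
      cfg_lines <- c(cfg_lines,
                     sprintf("templates.%s.%s = %s", chain, tolower(klass), fn))
    }
  }
  write_tsv_file(gdb$annotations, file.path(dir, "annotations.tsv"))
  write_reads_csv(sim$read_set, file.path(dir, "reads.csv"))
  jsonlite::write_json(
    list(chains = truth$chains, shm_rate = truth$shm_rate,
         origins = sim$origins),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- c("reads.file = reads.csv", "reads.dialect = peaks",
           "annotations = annotations.tsv", cfg_lines,
           "out_dir = results")
  for (k in names(config_overrides))
    cfg <- c(cfg, paste(k, "=", config_overrides[[k]]))
  cfg_path <- file.path(dir, "run.txt")
  writeLines(cfg, cfg_path)
  invisible(cfg_path)
}

#' Write a read set as a PEAKS-dialect CSV
#'
#' @param rs a `read_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_reads_csv <- function(rs, path) {
  df <- data.frame(
    Peptide = vapply(rs$reads, `[[`, "", "sequence"),
    `ALC (%)` = vapply(rs$reads, function(r) round(r$global_conf * 100, 1), 0),
    `local confidence (%)` = vapply(rs$reads, function(r)
      paste(round(r$local_conf * 100), collapse = " "), ""),
    Area = vapply(rs$reads, function(r)
      if (is.na(r$ms1_area)) "" else sprintf("%.1f", r$ms1_area), ""),
    `Source File` = vapply(rs$reads, `[[`, "", "source"),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
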