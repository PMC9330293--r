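# Batch configuration: a plain-text key = value file drives a full run.

CONFIG_KEYS <- c(
  "reads.file", "reads.dialect", "reads.delimiter",
  "templates.heavy.v", "templates.heavy.j", "templates.heavy.c",
  "templates.light.v", "templates.light.j", "templates.light.c",
  "templates.decoy",
  "annotations", "alphabet", "gap_open", "gap_extend",
  "cutoff", "min_global_conf", "min_len", "max_len",
  "placement", "normalize",
  "recombine", "recombine.n", "recombine.order",
  "recombine.force.v", "recombine.force.j", "recombine.force.c",
  "decoy", "out_dir", "seed", "log_level")

CONFIG_DEFAULTS <- list(
  reads.dialect = "peaks", reads.delimiter = ",",
  alphabet = "default", gap_open = 12, gap_extend = 1,
  cutoff = 8, min_global_conf = 0.85, min_len = 5, max_len = 40,
  placement = "all", normalize = "read_length",
  recombine = FALSE, recombine.n = 1, recombine.order = "V * J C",
  decoy = FALSE, out_dir = "results", seed = 1, log_level = "info")

#' Parse a batch configuration file
#'
#' The batch file is plain text, one `key = value` per line; `#` starts a
#' comment. Unknown keys are errors (catching typos); all defaults are
#' resolved at parse time so the emitted report can list the complete
#' parameter set. Relative paths are resolved against the config file's
#' directory. Defaults: alignment cutoff 8, ALC cutoff 0.85, read lengths
#' 5-40, placement `all`, no recombination.
#'
#' @param path config file path.
#' @param overrides named list applied over the file's values (CLI flags).
#' @return object of class `run_config`: the fully resolved parameter list,
#'   plus `template_files` (named by `group.class`) and `base_dir`.
#' @export
parse_config <- function(path, overrides = list()) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      config_error("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!(key %in% CONFIG_KEYS))
      config_error("unknown config key '", key, "'")
    vals[[key]] <- val
  }
  for (k in names(overrides)) {
    if (!(k %in% CONFIG_KEYS)) config_error("unknown config key '", k, "'")
    if (!is.null(overrides[[k]])) vals[[k]] <- overrides[[k]]
  }
  if (is.null(vals[["reads.file"]]))
    config_error("missing required key 'reads.file'")
  tmpl_keys <- grep("^templates\\.", names(vals), value = TRUE)
  if (length(tmpl_keys) == 0L)
    config_error("at least one templates.* key is required")

  cfg <- CONFIG_DEFAULTS
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  num_keys <- c("gap_open", "gap_extend", "cutoff", "min_global_conf",
                "min_len", "max_len", "recombine.n", "seed")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in c("recombine", "decoy"))
    cfg[[k]] <- tolower(as.character(cfg[[k]])) %in% c("true", "yes", "1")
  cfg$placement <- match.arg(cfg$placement, c("all", "best"))
  cfg$normalize <- match.arg(cfg$normalize,
                             c("read_length", "template_length"))
  cfg$reads.dialect <- match.arg(cfg$reads.dialect,
                                 c("peaks", "novor", "fasta"))

  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  cfg$reads.file <- resolve(strsplit(cfg$reads.file, ",[[:space:]]*")[[1]])
  for (p in cfg$reads.file)
    if (!file.exists(p)) config_error("reads.file does not exist: ", p)
  template_files <- list()
  for (k in tmpl_keys) {
    p <- resolve(vals[[k]])
    if (!file.exists(p)) config_error(k, " does not exist: ", p)
    template_files[[sub("^templates\\.", "", k)]] <- p
  }
  if (!is.null(cfg$annotations)) {
    cfg$annotations <- resolve(cfg$annotations)
    if (!file.exists(cfg$annotations))
      config_error("annotations file does not exist: ", cfg$annotations)
  }
  if (!identical(cfg$alphabet, "default")) {
    cfg$alphabet <- resolve(cfg$alphabet)
    if (!file.exists(cfg$alphabet))
      config_error("alphabet file does not exist: ", cfg$alphabet)
  }
  if (!grepl("^(/|[A-Za-z]:)", cfg$out_dir))
    cfg$out_dir <- file.path(base_dir, cfg$out_dir)

  forced <- c()
  for (k in c("v", "j", "c")) {
    fk <- paste0("recombine.force.", k)
    if (!is.null(cfg[[fk]])) forced[toupper(k)] <- cfg[[fk]]
  }
  cfg$forced_templates <- forced
  cfg$template_files <- template_files
  cfg$base_dir <- base_dir
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat("  reads:", paste(basename(x$reads.file), collapse = ", "),
      "(", x$reads.dialect, ")\n")
  cat("  templates:", paste(names(x$template_files), collapse = ", "), "\n")
  cat(sprintf("  cutoff %g, ALC >= %g, lengths %g-%g, placement %s\n",
              x$cutoff, x$min_global_conf, x$min_len, x$max_len, x$placement))
  if (x$recombine)
    cat(sprintf("  recombine: N=%g, order '%s', decoys %s\n",
                x$recombine.n, x$recombine.order, x$decoy))
  cat("  out_dir:", x$out_dir, "\n")
  invisible(x)
}

# Serializable view of a run_config (paths flattened; for the report/JSON).
config_as_list <- function(cfg) {
  keep <- setdiff(names(cfg), c("template_files", "base_dir",
                                "forced_templates"))
  out <- cfg[keep]
  out$template_files <- lapply(cfg$template_files, identity)
  if (length(cfg$forced_templates) > 0)
    out$forced_templates <- as.list(cfg$forced_templates)
  out
}
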