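# Repertoire profiling: cladograms of homologous templates, placement of
# unique reads at tips and shared reads at branching points, per-template
# summaries and CDR read tables.

new_clade <- function(members, children = list(), height = 0) {
  structure(list(members = sort(members), children = children,
                 height = height, placed_reads = character(0)),
            class = "cladogram_node")
}

#' Build a cladogram of homologous template segments
#'
#' Pairwise distances are `1 - identity` from global alignments under the
#' alphabet (identical aligned positions over alignment columns);
#' average-linkage agglomeration yields a rooted tree whose leaves are the
#' templates. Merge ties are broken by the lexicographically smallest member
#' id, so the tree is deterministic.
#'
#' @param segments list of `template_segment` (>= 1).
#' @param alphabet a [scoring_alphabet()].
#' @return the root `cladogram_node` (fields: `members`, `children`,
#'   `height`, `placed_reads`).
#' @export
build_cladogram <- function(segments, alphabet) {
  n <- length(segments)
  if (n == 0L) validation_error("at least one segment required")
  ids <- vapply(segments, `[[`, "", "id")
  nodes <- lapply(ids, new_clade)
  if (n == 1L) return(nodes[[1]])
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - nw_identity(segments[[i]]$sequence,
                                          segments[[j]]$sequence, alphabet)
  }
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  repeat {
    act <- which(active)
    if (length(act) == 1L) break
    # find minimum-distance active pair; ties -> smallest member ids
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      i <- act[ii]; j <- act[jj]
      dij <- d[i, j]
      if (dij < best_d - 1e-12) {
        best_d <- dij; best <- c(i, j)
      } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
        cand <- sort(c(nodes[[i]]$members[1], nodes[[j]]$members[1]))
        cur <- sort(c(nodes[[best[1]]]$members[1], nodes[[best[2]]]$members[1]))
        if (paste(cand, collapse = "\r") < paste(cur, collapse = "\r"))
          best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    merged <- new_clade(c(nodes[[i]]$members, nodes[[j]]$members),
                        children = list(nodes[[i]], nodes[[j]]),
                        height = best_d / 2)
    # average linkage update onto slot i
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  nodes[[which(active)]]
}

# All nodes in depth-first order (parents before children).
clade_nodes <- function(node) {
  c(list(node), unlist(lapply(node$children, clade_nodes), recursive = FALSE))
}

is_leaf <- function(node) length(node$children) == 0L

# Lowest node whose members cover `ids` (root covers everything by contract).
lowest_covering <- function(node, ids) {
  if (!all(ids %in% node$members)) return(NULL)
  for (ch in node$children) {
    deeper <- lowest_covering(ch, ids)
    if (!is.null(deeper)) return(deeper)
  }
  node
}

#' Place reads on a cladogram
#'
#' Each matched read is placed at exactly one node: the leaf of its template
#' if it is unique, otherwise the lowest node whose members contain the full
#' set of templates tied for its maximum score (their lowest common
#' ancestor; when the tied set is not a clade this is a higher node, which
#' is logged).
#'
#' @param tree root `cladogram_node`; its leaves must cover all matched
#'   template ids.
#' @param ms a `match_set` restricted to the templates in this tree (one
#'   group and segment class).
#' @return list with `tree` (placed_reads filled in) and `placements`
#'   (data.frame `read_id`, `node_members`, `is_unique`).
#' @export
place_reads <- function(tree, ms) {
  df <- ms$alignments
  if (nrow(df) > 0 && !all(df$template_id %in% tree$members))
    validation_error("match set references templates absent from the tree")
  reads <- unique(df$read_id)
  placements <- data.frame(read_id = character(), node_members = character(),
                           is_unique = logical(), stringsAsFactors = FALSE)
  # collect target member-sets per read, then stamp reads into the tree
  targets <- list()
  for (rid in reads) {
    rows <- df[df$read_id == rid, , drop = FALSE]
    tied <- rows$template_id[rows$raw_score == max(rows$raw_score)]
    tied <- sort(unique(tied))
    targets[[rid]] <- tied
    placements <- rbind(placements, data.frame(
      read_id = rid, node_members = paste(tied, collapse = ","),
      is_unique = length(tied) == 1L, stringsAsFactors = FALSE))
  }
  stamp <- function(node) {
    for (rid in names(targets)) {
      tied <- targets[[rid]]
      if (length(tied) == 1L) {
        if (is_leaf(node) && node$members == tied)
          node$placed_reads <- c(node$placed_reads, rid)
      } else {
        covers <- all(tied %in% node$members)
        child_covers <- any(vapply(node$children,
                                   function(ch) all(tied %in% ch$members),
                                   logical(1)))
        if (covers && !child_covers)
          node$placed_reads <- c(node$placed_reads, rid)
      }
    }
    node$children <- lapply(node$children, stamp)
    node
  }
  list(tree = stamp(tree), placements = placements)
}

#' Per-template match summary
#'
#' One row per matched template: number of matched reads, total alignment
#' score and combined MS1 peak area, plus the same three quantities over the
#' unique reads only. Rows are sorted by total score, descending.
#'
#' @param ms a `match_set`.
#' @return data.frame with columns `template_id`, `group`, `segment_class`,
#'   `read_count`, `total_score`, `summed_area`, `unique_read_count`,
#'   `unique_score`, `unique_area`.
#' @export
summarize_matches <- function(ms) {
  df <- ms$alignments
  if (nrow(df) == 0L) {
    return(data.frame(template_id = character(), group = character(),
                      segment_class = character(), read_count = integer(),
                      total_score = numeric(), summed_area = numeric(),
                      unique_read_count = integer(), unique_score = numeric(),
                      unique_area = numeric(), stringsAsFactors = FALSE))
  }
  sp <- split(df, df$template_id)
  out <- do.call(rbind, lapply(sp, function(x) {
    u <- x[x$is_unique, , drop = FALSE]
    data.frame(template_id = x$template_id[1], group = x$group[1],
               segment_class = x$segment_class[1],
               read_count = nrow(x), total_score = sum(x$raw_score),
               summed_area = sum(x$ms1_area),
               unique_read_count = nrow(u), unique_score = sum(u$raw_score),
               unique_area = sum(u$ms1_area), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_score, out$template_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collect reads overlapping the CDRs
#'
#' Every alignment whose template span intersects an annotated CDR region
#' contributes the read residues aligned within that region. Region labels
#' are reported per chain (`CDRH1` ... `CDRL3`).
#'
#' @param ms a `match_set`.
#' @param db the `template_database` carrying region annotations.
#' @param rs the `read_set` (for the aligned read subsequences); when
#'   omitted, `aligned_seq` reports read coordinates instead of residues.
#' @return data.frame with columns `cdr`, `read_id`, `template_id`,
#'   `tmpl_start`, `tmpl_end` (1-based, clipped to the region) and
#'   `aligned_seq` (read residues aligned inside the region).
#' @export
collect_cdr_reads <- function(ms, db, rs = NULL) {
  df <- ms$alignments
  out <- list()
  seqs <- if (!is.null(rs))
    setNames(vapply(rs$reads, `[[`, "", "sequence"),
             vapply(rs$reads, `[[`, "", "id"))
  else NULL
  chain_letter <- c(heavy = "H", light = "L")
  for (k in seq_len(nrow(df))) {
    row <- df[k, ]
    seg <- db_find(db, row$template_id)
    if (is.null(seg) || nrow(seg$regions) == 0L) next
    for (r in seq_len(nrow(seg$regions))) {
      reg <- seg$regions[r, ]
      reg_start <- reg$start + 1L   # to 1-based inclusive
      reg_end <- reg$end
      if (row$tmpl_end < reg_start || row$tmpl_start > reg_end) next
      sub <- aligned_read_in_span(row, max(row$tmpl_start, reg_start),
                                  min(row$tmpl_end, reg_end),
                                  read_seq = seqs[[row$read_id]] %||% NULL)
      label <- reg$label
      if (label %in% c("CDR1", "CDR2", "CDR3-anchor")) {
        num <- if (label == "CDR3-anchor") "3" else substr(label, 4, 4)
        label <- paste0("CDR", chain_letter[[seg$group]] %||% "", num)
      }
      out[[length(out) + 1L]] <- data.frame(
        cdr = label, read_id = row$read_id, template_id = row$template_id,
        tmpl_start = max(row$tmpl_start, reg_start),
        tmpl_end = min(row$tmpl_end, reg_end),
        aligned_seq = sub, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cdr = character(), read_id = character(),
                      template_id = character(), tmpl_start = integer(),
                      tmpl_end = integer(), aligned_seq = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$cdr, res$template_id, res$read_id), , drop = FALSE]
}

# Read residues aligned to template positions [from, to] along an alignment
# row.
aligned_read_in_span <- function(row, from, to, read_seq = NULL) {
  steps <- chars(row$path)
  ri <- row$read_start
  ti <- row$tmpl_start
  picked <- integer(0)
  for (st in steps) {
    if (st == "M") {
      if (ti >= from && ti <= to) picked <- c(picked, ri)
      ri <- ri + 1L; ti <- ti + 1L
    } else if (st == "D") {
      ti <- ti + 1L
    } else {
      ri <- ri + 1L
    }
  }
  if (length(picked) == 0L) return("")
  if (is.null(read_seq)) paste0("@", picked[1], "-", picked[length(picked)])
  else substr(read_seq, picked[1], picked[length(picked)])
}

#' Export a cladogram (with read counts) to Newick
#'
#' Leaf labels are template ids; internal node labels carry the number of
#' reads placed at that node; branch lengths are merge heights.
#'
#' @param tree root `cladogram_node`.
#' @return single-element character vector (Newick string, semicolon
#'   terminated).
#' @export
cladogram_newick <- function(tree) {
  rec <- function(node, parent_height) {
    bl <- sprintf("%.6g", max(parent_height - node$height, 0))
    if (is_leaf(node)) {
      lab <- node$members
      if (length(node$placed_reads) > 0)
        lab <- paste0(lab, "[", length(node$placed_reads), "]")
      paste0(lab, ":", bl)
    } else {
      inner <- paste(vapply(node$children, rec, "", node$height),
                     collapse = ",")
      paste0("(", inner, ")", length(node$placed_reads), ":", bl)
    }
  }
  if (is_leaf(tree)) return(paste0(tree$members, ";"))
  inner <- paste(vapply(tree$children, rec, "", tree$height), collapse = ",")
  paste0("(", inner, ")", length(tree$placed_reads), ";")
}

#' @export
print.cladogram_node <- function(x, ...) {
  cat("Cladogram:", length(x$members), "templates,",
      sum(vapply(clade_nodes(x), function(n) length(n$placed_reads), 0L)),
      "placed reads\n")
  invisible(x)
}
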