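# Weighted consensus calling: combine overlapping read placements on one
# template into a consensus sequence with depth of coverage, sequence-logo
# weights, template fill-in for uncovered regions and template-guided I/L
# resolution.

#' MS1-area weight factor
#'
#' Scales an MS1 peak area logarithmically to a weight between 1 and 2 via
#' `2 - 1/log10(area)`, clamped to `[1, 2]`. Areas of 10 or less (where the
#' formula leaves `[1, 2]`) and absent areas contribute weight 1, so reads
#' without abundance information still count fully once.
#'
#' @param area nonnegative MS1 peak area, or `NA` when absent.
#' @return weight in `[1, 2]`.
#' @examples
#' area_weight(10)    # 1
#' area_weight(1e4)   # 1.75
#' area_weight(NA)    # 1
#' @export
area_weight <- function(area) {
  if (length(area) != 1L) validation_error("area must be a single value")
  if (is.na(area)) return(1)
  if (area < 0) validation_error("MS1 area must be nonnegative")
  if (area <= 10) return(1)
  min(max(2 - 1 / log10(area), 1), 2)
}

#' Per-residue read weight
#'
#' The weight a read residue deposits into a consensus column: the product
#' of its local confidence, the read's global confidence and the MS1-area
#' factor ([area_weight()]). Multiplicative combination makes any
#' zero-confidence residue inert.
#'
#' @param read a peptide read (element of a `read_set`).
#' @param read_pos 1-based residue index.
#' @return nonnegative weight.
#' @export
position_weight <- function(read, read_pos) {
  if (read_pos < 1 || read_pos > length(read$local_conf))
    validation_error("read_pos out of range")
  read$local_conf[read_pos] * read$global_conf * area_weight(read$ms1_area)
}

#' Build the weighted consensus for one template
#'
#' Each aligned read residue deposits [position_weight()] into its template
#' column; gapped-over template columns accumulate deletion weight;
#' insertions accumulate between columns. Per column the residue with the
#' maximum accumulated weight is called (ties prefer the template residue,
#' then the lexicographically smallest); columns without any coverage emit
#' the template residue and are recorded in `template_filled`. A column won
#' by the deletion event is omitted from the consensus. An insertion is
#' emitted iff its weight exceeds half the mean total weight of the two
#' flanking columns.
#'
#' @param template a `template_segment` (or any object with `id` and
#'   `sequence`).
#' @param alignments data.frame of alignment rows (as produced by
#'   [match_reads()]) referencing this template.
#' @param rs the `read_set` the alignments were computed from.
#' @return object of class `consensus_result`: `consensus` string, per-column
#'   `columns` (weights, depth, insertions), `template_filled` and `deleted`
#'   (1-based template positions), `il_resolved` (filled by [resolve_il()]),
#'   `col_to_cons` (template column to consensus index map) and `logo`
#'   (per-column weight table normalized to sum 1).
#' @export
build_consensus <- function(template, alignments, rs) {
  if (nrow(alignments) > 0 && any(alignments$template_id != template$id))
    validation_error("alignment references another template than '",
                     template$id, "'")
  L <- nchar(template$sequence)
  tchars <- chars(template$sequence)
  weights <- vector("list", L)
  depth <- integer(L)
  insertions <- vector("list", L)
  reads_by_id <- setNames(rs$reads, vapply(rs$reads, `[[`, "", "id"))

  for (k in seq_len(nrow(alignments))) {
    row <- alignments[k, ]
    read <- reads_by_id[[row$read_id]]
    if (is.null(read)) validation_error("unknown read id '", row$read_id, "'")
    aw <- area_weight(read$ms1_area)
    steps <- chars(row$path)
    ri <- row$read_start
    ti <- row$tmpl_start
    covered <- logical(L)
    ins_buf <- character(0)
    ins_w <- numeric(0)
    add_w <- function(tab, key, w) {
      if (key %in% names(tab)) tab[[key]] <- tab[[key]] + w else tab[[key]] <- w
      tab
    }
    for (st in steps) {
      if (st != "I" && length(ins_buf) > 0) {  # close an insertion run
        at <- ti - 1L
        insertions[[at]] <- add_w(insertions[[at]] %||% numeric(0),
                                  paste(ins_buf, collapse = ""), mean(ins_w))
        ins_buf <- character(0)
        ins_w <- numeric(0)
      }
      if (st == "M") {
        res <- substr(read$sequence, ri, ri)
        w <- read$local_conf[ri] * read$global_conf * aw
        weights[[ti]] <- add_w(weights[[ti]] %||% numeric(0), res, w)
        covered[ti] <- TRUE
        ri <- ri + 1L
        ti <- ti + 1L
      } else if (st == "D") {
        # deletion weight: confidence of the read residues flanking the gap
        flank <- c(if (ri > 1) read$local_conf[ri - 1L],
                   if (ri <= length(read$local_conf)) read$local_conf[ri])
        w <- mean(flank) * read$global_conf * aw
        weights[[ti]] <- add_w(weights[[ti]] %||% numeric(0), "-", w)
        covered[ti] <- TRUE
        ti <- ti + 1L
      } else {  # I: read residue between template columns
        res <- substr(read$sequence, ri, ri)
        ins_buf <- c(ins_buf, res)
        ins_w <- c(ins_w, read$local_conf[ri] * read$global_conf * aw)
        ri <- ri + 1L
      }
    }
    depth <- depth + covered
  }

  col_total <- vapply(seq_len(L), function(j) {
    w <- weights[[j]]
    if (is.null(w)) 0 else sum(w)
  }, numeric(1))

  cons_chars <- character(0)
  col_to_cons <- rep(NA_integer_, L)
  template_filled <- integer(0)
  deleted <- integer(0)
  for (j in seq_len(L)) {
    if (depth[j] == 0L) {
      cons_chars <- c(cons_chars, tchars[j])
      col_to_cons[j] <- length(cons_chars)
      template_filled <- c(template_filled, j)
    } else {
      w <- weights[[j]]
      top <- names(w)[w == max(w)]
      pick <- if (tchars[j] %in% top) tchars[j] else sort(top)[1]
      if (pick == "-") {
        deleted <- c(deleted, j)
      } else {
        cons_chars <- c(cons_chars, pick)
        col_to_cons[j] <- length(cons_chars)
      }
    }
    ins <- insertions[[j]]
    if (!is.null(ins) && length(ins) > 0 && j < L) {
      flank_mean <- mean(c(col_total[j], col_total[j + 1L]))
      best <- names(ins)[which.max(ins)]
      if (ins[[best]] > flank_mean / 2)
        cons_chars <- c(cons_chars, chars(best))
    }
  }

  # sequence-logo table: per-column weights normalized to sum 1
  all_res <- sort(unique(unlist(lapply(weights, names))))
  logo <- matrix(0, nrow = L, ncol = length(all_res),
                 dimnames = list(NULL, all_res))
  for (j in seq_len(L)) {
    w <- weights[[j]]
    if (!is.null(w) && sum(w) > 0) logo[j, names(w)] <- w / sum(w)
  }

  structure(list(template_id = template$id,
                 template = template$sequence,
                 consensus = paste(cons_chars, collapse = ""),
                 columns = lapply(seq_len(L), function(j)
                   list(weights = weights[[j]] %||% numeric(0),
                        depth = depth[j],
                        insertions = insertions[[j]] %||% numeric(0))),
                 depth = depth,
                 template_filled = template_filled,
                 deleted = deleted,
                 il_resolved = integer(0),
                 col_to_cons = col_to_cons,
                 logo = logo),
            class = "consensus_result")
}

#' Template-guided isoleucine/leucine resolution
#'
#' De novo reads from standard MS cannot distinguish the isobaric residues I
#' and L, and engines default such positions to L. Where the consensus reads
#' L, the read support at the column consists exclusively of I/L, and the
#' template carries I, the consensus is switched to I and the position is
#' recorded in `il_resolved`. No other column changes.
#'
#' @param result a `consensus_result`.
#' @param template the `template_segment` the consensus was built on.
#' @return the updated `consensus_result`.
#' @export
resolve_il <- function(result, template) {
  if (!identical(template$sequence, result$template))
    validation_error("template does not match the consensus result")
  tchars <- chars(template$sequence)
  cons <- chars(result$consensus)
  for (j in seq_along(tchars)) {
    ci <- result$col_to_cons[j]
    if (is.na(ci) || result$depth[j] == 0L) next
    if (cons[ci] != "L" || tchars[j] != "I") next
    support <- names(result$columns[[j]]$weights)
    if (length(support) > 0 && all(support %in% c("I", "L"))) {
      cons[ci] <- "I"
      result$il_resolved <- c(result$il_resolved, j)
    }
  }
  result$consensus <- paste(cons, collapse = "")
  result
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus for %s: %d aa, mean depth %.1f, %d uncovered, %d I/L resolved\n",
              x$template_id, nchar(x$consensus), mean(x$depth),
              length(x$template_filled), length(x$il_resolved)))
  invisible(x)
}
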