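# Static HTML report: an index page with the run summary, resolved
# parameters and cladograms, plus one detail page per matched (recombined)
# template with consensus, CDR highlighting, depth track, logo data and the
# stacked read alignment overview. Every number shown is taken from the same
# structures that feed the TSV artifacts.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>",
         html_escape(title), "</title>\n<style>",
         "body{font-family:sans-serif;margin:2em;}",
         "table{border-collapse:collapse;}",
         "td,th{border:1px solid #999;padding:2px 6px;font-size:90%;}",
         "pre{font-family:monospace;}",
         ".cdr{background:#fdd;font-weight:bold;}",
         ".fill{color:#999;}",
         "</style></head><body>", body, "</body></html>\n")
}

html_table <- function(df) {
  if (nrow(df) == 0L) return("<p>(empty)</p>")
  hdr <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                               collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, ], function(v)
      paste0("<td>", html_escape(format(v)), "</td>"), "")
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, "")
  paste0("<table>", hdr, paste(rows, collapse = "\n"), "</table>")
}

safe_file <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

# Consensus string with CDR regions highlighted and template-filled
# positions dimmed, as 60-residue blocks.
consensus_html <- function(cr, regions = NULL) {
  cc <- chars(cr$consensus)
  classes <- rep("", length(cc))
  for (j in cr$template_filled) {
    ci <- cr$col_to_cons[j]
    if (!is.na(ci)) classes[ci] <- "fill"
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      span <- (regions$start[r] + 1L):regions$end[r]
      for (j in span) {
        ci <- cr$col_to_cons[j]
        if (!is.na(ci) && ci <= length(classes)) classes[ci] <- "cdr"
      }
    }
  }
  spans <- vapply(seq_along(cc), function(i) {
    if (nzchar(classes[i]))
      paste0("<span class=\"", classes[i], "\">", cc[i], "</span>")
    else cc[i]
  }, "")
  blocks <- split(spans, (seq_along(spans) - 1L) %/% 60L)
  paste0("<pre>", paste(vapply(blocks, paste, "", collapse = ""),
                        collapse = "\n"), "</pre>")
}

depth_track_html <- function(cr) {
  d <- cr$depth
  bars <- vapply(d, function(x)
    paste(rep("#", min(x, 40)), collapse = ""), "")
  df <- data.frame(position = seq_along(d), depth = d, coverage = bars)
  html_table(df[df$depth > 0 | seq_along(d) %% 10 == 1, , drop = FALSE])
}

logo_html <- function(cr) {
  lg <- cr$logo
  if (is.null(lg) || ncol(lg) == 0L) return("<p>(no coverage)</p>")
  top <- vapply(seq_len(nrow(lg)), function(i) {
    w <- lg[i, ]
    w <- sort(w[w > 0], decreasing = TRUE)
    if (length(w) == 0L) return("")
    paste(sprintf("%s:%.2f", names(w), w), collapse = " ")
  }, "")
  html_table(data.frame(position = seq_len(nrow(lg)),
                        weights = top)[nzchar(top), , drop = FALSE])
}

reads_overview_html <- function(alignments) {
  if (nrow(alignments) == 0L) return("<p>(no reads)</p>")
  df <- alignments[order(alignments$tmpl_start),
                   c("read_id", "tmpl_start", "tmpl_end", "raw_score",
                     "norm_score", "is_unique")]
  df$norm_score <- round(df$norm_score, 2)
  html_table(df)
}

template_page <- function(tid, cr, alignments, regions) {
  body <- paste0(
    "<h1>", html_escape(tid), "</h1>",
    "<p><a href=\"index.html\">back to summary</a></p>",
    if (all(cr$depth == 0)) "<p>No coverage: template-only consensus.</p>" else "",
    "<h2>Consensus</h2>", consensus_html(cr, regions),
    "<p>", length(cr$template_filled), " positions filled from the template; ",
    length(cr$il_resolved), " I/L positions resolved to template isoleucine",
    if (length(cr$il_resolved) > 0)
      paste0(" (positions ", paste(cr$il_resolved, collapse = ", "), ")")
    else "", ".</p>",
    "<h2>Depth of coverage</h2>", depth_track_html(cr),
    "<h2>Sequence logo weights</h2>", logo_html(cr),
    "<h2>Aligned reads</h2>", reads_overview_html(alignments))
  html_page(tid, body)
}

#' Render the static HTML report
#'
#' Index page: resolved parameter dump, per-template summary table with
#' links, cladogram Newick strings and the CDR read overview grouped by
#' CDR label. Detail pages: consensus with CDR highlighting and
#' template-fill dimming, depth-of-coverage track, per-position logo
#' weights and the stacked read alignment overview. All numbers equal the
#' corresponding TSV cells.
#'
#' @param result an `ab_assembly` from [run_pipeline()].
#' @param dir output directory for the HTML bundle.
#' @return `dir`, invisibly.
#' @export
render_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- result$summary
  pages <- character(0)

  page_for <- function(tid, cr, alignments, regions) {
    fn <- paste0("tmpl_", safe_file(tid), ".html")
    writeLines(template_page(tid, cr, alignments, regions), file.path(dir, fn))
    fn
  }

  links <- character(nrow(summ))
  for (i in seq_len(nrow(summ))) {
    tid <- summ$template_id[i]
    cr <- result$consensus[[tid]]
    if (is.null(cr)) { links[i] <- html_escape(tid); next }
    seg <- db_find(result$db, tid)
    fn <- page_for(tid, cr,
                   result$matches$alignments[
                     result$matches$alignments$template_id == tid, ,
                     drop = FALSE],
                   if (!is.null(seg)) seg$regions else NULL)
    links[i] <- paste0("<a href=\"", fn, "\">", html_escape(tid), "</a>")
  }
  summ_disp <- summ
  summ_disp$template_id <- links
  summ_html <- {
    if (nrow(summ_disp) == 0L) "<p>(no matches)</p>"
    else {
      hdr <- paste0("<tr>", paste0("<th>", html_escape(names(summ_disp)),
                                   "</th>", collapse = ""), "</tr>")
      rows <- vapply(seq_len(nrow(summ_disp)), function(i) {
        cells <- c(paste0("<td>", summ_disp$template_id[i], "</td>"),
                   vapply(summ_disp[i, -1], function(v)
                     paste0("<td>", html_escape(format(v)), "</td>"), ""))
        paste0("<tr>", paste(cells, collapse = ""), "</tr>")
      }, "")
      paste0("<table>", hdr, paste(rows, collapse = "\n"), "</table>")
    }
  }

  rec_html <- ""
  if (!is.null(result$second_pass)) {
    parts <- character(0)
    for (g in names(result$second_pass)) {
      sp <- result$second_pass[[g]]
      for (tid in names(sp$consensus)) {
        rec <- Filter(function(r) r$id == tid, result$recombined[[g]])[[1]]
        fn <- page_for(paste0(g, "_", tid), sp$consensus[[tid]],
                       sp$match_set$alignments[
                         sp$match_set$alignments$template_id == tid, ,
                         drop = FALSE],
                       NULL)
        jx <- rec$junction
        parts <- c(parts, paste0(
          "<li><a href=\"", fn, "\">", html_escape(paste(g, tid)), "</a>",
          if (!is.null(jx)) paste0(
            " &mdash; junction overlap ", jx$overlap_len,
            if (jx$gap_inserted) " (gap inserted)" else "",
            ", overhangs V+", jx$v_overhang, " / J+", jx$j_overhang)
          else "",
          "</li>"))
      }
      parts <- c(parts, paste0("<li>", sp$n_decoy_excluded,
                               " reads excluded by decoys (", g, ")</li>"))
    }
    rec_html <- paste0("<h2>Recombined templates</h2><ul>",
                       paste(parts, collapse = "\n"), "</ul>")
  }

  clado_html <- ""
  if (length(result$cladograms) > 0) {
    items <- vapply(names(result$cladograms), function(nm) {
      paste0("<h3>", html_escape(nm), "</h3><pre>",
             html_escape(cladogram_newick(result$cladograms[[nm]]$tree)),
             "</pre>")
    }, "")
    clado_html <- paste0("<h2>Cladograms</h2>", paste(items, collapse = "\n"))
  }

  cdr_html <- if (nrow(result$cdr_reads) > 0)
    paste0("<h2>Reads overlapping the CDRs</h2>", html_table(result$cdr_reads))
  else ""

  cfg_dump <- jsonlite::toJSON(config_as_list(result$config),
                               auto_unbox = TRUE, pretty = TRUE)
  body <- paste0(
    "<h1>Antibody template assembly report</h1>",
    "<h2>Template summary</h2>", summ_html,
    rec_html, clado_html, cdr_html,
    "<h2>Resolved parameters</h2><pre>", html_escape(cfg_dump), "</pre>")
  writeLines(html_page("Assembly report", body), file.path(dir, "index.html"))
  invisible(dir)
}
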