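# BED and summary-table writers for candidate loci.

best_forward <- function(locus) {
  if (nrow(locus$forward_hits) == 0L) return(NULL)
  locus$forward_hits[hit_order(locus$forward_hits)[1], , drop = FALSE]
}

sort_loci <- function(loci) {
  ord <- order(vapply(loci, `[[`, character(1), "contig"),
               vapply(loci, `[[`, integer(1), "canon_start"),
               vapply(loci, `[[`, integer(1), "canon_end"))
  loci[ord]
}

#' Write candidate loci as BED6
#'
#' 0-based half-open intervals; score is the bitscore of the best forward
#' hit; strand `both` is written as `.`.
#'
#' @param loci list of `candidate_locus` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  loci <- sort_loci(loci)
  lines <- vapply(loci, function(l) {
    if (l$canon_start >= l$canon_end) {
      stop("locus with start >= end: ", l$locus_id)
    }
    bf <- best_forward(l)
    score <- if (is.null(bf)) 0 else bf$bitscore
    strand <- if (l$strand %in% c("+", "-")) l$strand else "."
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", l$contig, l$canon_start,
            l$canon_end, l$locus_id, format(score, trim = TRUE), strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

SUMMARY_COLUMNS <- c("locus_id", "contig", "start", "end", "strand",
                     "category", "fired_rule", "best_forward",
                     "best_forward_bitscore", "best_rvdb", "best_nr",
                     "n_stops", "n_insertions", "n_deletions",
                     "n_frameshifts", "pident", "protein_coverage",
                     "intact", "n_orfs")

#' Summarize loci as a data.frame
#'
#' One row per locus with coordinates, category, best hits per table,
#' reconstruction counts and the ORF count, in deterministic
#' (contig, start, end) order.
#'
#' @param loci list of `candidate_locus` objects.
#' @return data.frame with the columns in `SUMMARY_COLUMNS`.
#' @export
summarize_loci <- function(loci) {
  loci <- sort_loci(loci)
  rows <- lapply(loci, function(l) {
    if (l$canon_start >= l$canon_end) {
      stop("locus with start >= end: ", l$locus_id)
    }
    bf <- best_forward(l)
    best_of <- function(hits) {
      if (nrow(hits) == 0L) return(NA_character_)
      hits$sseqid[hit_order(hits)[1]]
    }
    rec <- l$reconstruction
    data.frame(
      locus_id = l$locus_id, contig = l$contig, start = l$canon_start,
      end = l$canon_end, strand = l$strand,
      category = if (is.na(l$category)) "unset" else l$category,
      fired_rule = l$fired_rule,
      best_forward = if (is.null(bf)) NA_character_ else bf$qseqid,
      best_forward_bitscore = if (is.null(bf)) NA_real_ else bf$bitscore,
      best_rvdb = best_of(l$rvdb_hits), best_nr = best_of(l$nr_hits),
      n_stops = if (is.null(rec)) NA_integer_ else rec$n_stops,
      n_insertions = if (is.null(rec)) NA_integer_ else rec$n_insertions,
      n_deletions = if (is.null(rec)) NA_integer_ else rec$n_deletions,
      n_frameshifts = if (is.null(rec)) NA_integer_ else rec$n_frameshifts,
      pident = if (is.null(rec)) NA_real_ else round(rec$pident, 2),
      protein_coverage = if (is.null(rec)) NA_real_ else
        round(rec$protein_coverage, 4),
      intact = if (is.null(rec)) NA else rec$intact,
      n_orfs = if (is.null(l$orfs)) 0L else nrow(l$orfs),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    df <- as.data.frame(setNames(
      lapply(SUMMARY_COLUMNS, function(x) character(0)), SUMMARY_COLUMNS),
      stringsAsFactors = FALSE)
    return(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the locus summary table
#'
#' Tab-separated with a fixed documented header; zero loci give a
#' header-only file.
#'
#' @param loci list of `candidate_locus` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(loci, path) {
  df <- summarize_loci(loci)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
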