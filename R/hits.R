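# Tabular search-hit I/O and filtering.
#
# A hit table is a data.frame with one row per alignment, mirroring the
# 14-column BLAST/DIAMOND tabular dialect
#   qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#   evalue bitscore stitle staxids
# plus three derived columns added at the parse boundary:
#   strand      '+' / '-', from subject coordinate orientation
#   canon_start 0-based half-open start on the subject (genome) axis
#   canon_end   0-based half-open end
# Source coordinates are 1-based inclusive and orientation-encoded; the
# canonical columns are the only coordinates downstream code uses.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "stitle", "staxids")
HIT_NUMERIC <- c("pident", "evalue", "bitscore")
HIT_INTEGER <- c("length", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send")

#' Construct a hit table
#'
#' Fills the derived columns (`strand`, `canon_start`, `canon_end`) from the
#' source-dialect subject coordinates: a hit is on the minus strand iff
#' `sstart > send`, and canonical coordinates are the 0-based half-open
#' interval `[min(sstart, send) - 1, max(sstart, send))`.
#'
#' @param df data.frame with at least the columns
#'   qseqid, sseqid, pident, length, qstart, qend, sstart, send, evalue,
#'   bitscore. Missing optional columns (mismatch, gapopen, stitle, staxids)
#'   are filled with defaults.
#' @return a data.frame of class `hit_table`.
#' @export
hit_table <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(qseqid = character(), sseqid = character(),
                     pident = numeric(), length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), bitscore = numeric(),
                     stitle = character(), staxids = character(),
                     stringsAsFactors = FALSE)
  }
  if (is.null(df$mismatch)) df$mismatch <- 0L
  if (is.null(df$gapopen)) df$gapopen <- 0L
  if (is.null(df$stitle)) df$stitle <- ""
  if (is.null(df$staxids)) df$staxids <- ""
  df$stitle[is.na(df$stitle)] <- ""
  df$staxids[is.na(df$staxids)] <- ""
  df <- df[, HIT_COLUMNS, drop = FALSE]
  for (cn in HIT_INTEGER) df[[cn]] <- as.integer(df[[cn]])
  for (cn in HIT_NUMERIC) df[[cn]] <- as.numeric(df[[cn]])
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative e-value in hit table")
  df$strand <- ifelse(df$sstart > df$send, "-", "+")
  df$canon_start <- pmin(df$sstart, df$send) - 1L
  df$canon_end <- pmax(df$sstart, df$send)
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Parse a BLAST/DIAMOND tabular hit file
#'
#' @param path path to a tab-separated hit file (no header).
#' @param columns ordered column names; default is the 14-column dialect
#'   (`HIT_COLUMNS`). `stitle` and `staxids` may be omitted.
#' @return a `hit_table`. `staxids` is kept as the raw ';'-separated string;
#'   use [split_staxids()] for integer vectors.
#' @export
parse_tabular_hits <- function(path, columns = HIT_COLUMNS) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- setdiff(HIT_COLUMNS, c("stitle", "staxids", "mismatch", "gapopen"))
  missing <- setdiff(required, columns)
  if (length(missing)) {
    stop("column spec is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  all_lines <- readLines(path)
  keep_ln <- which(nzchar(all_lines))
  lines <- all_lines[keep_ln]
  if (!length(lines)) return(hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # stitle/staxids may legitimately be empty trailing fields
  min_needed <- max(match(required, columns))
  bad <- which(nf < min_needed | nf > length(columns))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                 keep_ln[bad[1]], length(columns), nf[bad[1]]))
  }
  grab <- function(name) {
    idx <- match(name, columns)
    if (is.na(idx)) return(rep("", length(fields)))
    vapply(fields, function(f) if (idx <= length(f)) f[idx] else "",
           character(1))
  }
  df <- data.frame(qseqid = grab("qseqid"), sseqid = grab("sseqid"),
                   stitle = grab("stitle"), staxids = grab("staxids"),
                   stringsAsFactors = FALSE)
  for (cn in c(HIT_NUMERIC, HIT_INTEGER)) {
    raw <- grab(cn)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop(sprintf("line %d: cannot parse field '%s' from '%s'",
                   keep_ln[bad], cn, raw[bad]))
    }
    df[[cn]] <- val
  }
  hit_table(df)
}

#' Write a hit table in the 14-column tabular dialect
#'
#' Inverse of [parse_tabular_hits()]: only the 14 source-dialect columns are
#' written (derived columns are recomputed on re-parse). E-values are
#' formatted in scientific notation with full precision so round-trips are
#' lossless.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  fmt_num <- function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = NA,
                                 trim = TRUE), character(1))
  }
  lines <- if (nrow(hits) == 0L) character(0) else {
    paste(hits$qseqid, hits$sseqid, fmt_num(hits$pident), hits$length,
          hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
          hits$sstart, hits$send, fmt_num(hits$evalue),
          fmt_num(hits$bitscore), hits$stitle, hits$staxids,
          sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Split the staxids column into integer vectors
#'
#' @param hits a `hit_table` (or its `staxids` column).
#' @return a list of integer vectors, one per hit; empty strings give
#'   `integer(0)`.
#' @export
split_staxids <- function(hits) {
  x <- if (is.data.frame(hits)) hits$staxids else hits
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    as.integer(p)
  })
}

# Deterministic total order used by every per-group truncation:
# descending bitscore, then ascending evalue, sseqid, qseqid.
hit_order <- function(hits) {
  order(-hits$bitscore, hits$evalue, hits$sseqid, hits$qseqid)
}

#' Filter hits by e-value and keep the top hits per query
#'
#' Drops hits with `evalue > evalue_max`, then keeps at most
#' `per_query_top_hits` hits per query, ranked by descending bitscore (ties:
#' ascending e-value, subject id, query id).
#'
#' @param hits a `hit_table`.
#' @param params a [search_params()] list.
#' @return the filtered `hit_table`.
#' @export
filter_and_rank <- function(hits, params = search_params()) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- hit_table()
    return(out)
  }
  hits <- hits[hit_order(hits), , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                     FUN = seq_along) <= params$per_query_top_hits
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}
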