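# Forward / reciprocal search engines.
#
# Three routes produce the same hit tables: an external DIAMOND-style binary,
# pre-computed tabular files, or the built-in six-frame translated
# Smith-Waterman aligner. The built-in engine is test/desk-scale: O(m * n)
# per frame, intended for genomes up to a few Mb.

.evescreen_env <- new.env(parent = emptyenv())

#' Search parameters
#'
#' @param evalue_max e-value ceiling (default 1e-5).
#' @param per_query_top_hits hits kept per query after ranking (default 10).
#' @param matrix scoring matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend positive gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`); defaults 11 / 1.
#' @param min_raw_score reporting floor for the built-in aligner (default 40).
#' @return a list of class `search_params`.
#' @export
search_params <- function(evalue_max = 1e-5, per_query_top_hits = 10L,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          min_raw_score = 40) {
  if (evalue_max <= 0) stop("evalue_max must be > 0")
  if (per_query_top_hits < 1) stop("per_query_top_hits must be >= 1")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  structure(list(evalue_max = evalue_max,
                 per_query_top_hits = as.integer(per_query_top_hits),
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, min_raw_score = min_raw_score),
            class = "search_params")
}

# Scoring matrix with '*' (stop) entries forced to the matrix minimum, so
# stop-containing conceptual translations stay alignable but maximally
# penalized. Cached per matrix name.
score_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (!is.null(.evescreen_env[[key]])) return(.evescreen_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  mat <- e[[name]]
  lo <- min(mat)
  mat["*", ] <- lo
  mat[, "*"] <- lo
  .evescreen_env[[key]] <- mat
  mat
}

# Gapped Karlin-Altschul parameters (BLOSUM62, 11/1), used only so the
# built-in engine produces bitscores/e-values on the familiar scale; the
# statistics proper are DIAMOND's job in real runs.
KA_LAMBDA <- 0.267
KA_K <- 0.041

raw_to_bitscore <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

aa_to_index <- function(seq, mat) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], rownames(mat))
  if (anyNA(idx)) {
    idx[is.na(idx)] <- match("X", rownames(mat))
  }
  idx - 1L
}

dna_to_codes <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  codes - 1L
}

# codon index 16*b1 + 4*b2 + b3 (bases A=0 C=1 G=2 T=3) -> 0-based matrix
# column of the translated residue; -1 for stops.
codon_aa_table <- function(mat) {
  key <- "codon_aa"
  if (!is.null(.evescreen_env[[key]])) return(.evescreen_env[[key]])
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- integer(64)
  for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
    codon <- paste0(bases[b1 + 1], bases[b2 + 1], bases[b3 + 1])
    aa <- unname(gc[codon])
    tab[16 * b1 + 4 * b2 + b3 + 1] <-
      if (aa == "*") -1L else match(aa, colnames(mat)) - 1L
  }
  .evescreen_env[[key]] <- tab
  tab
}

#' Translate a DNA string in a given frame
#'
#' Conceptual translation: stops are rendered `*`, codons containing
#' ambiguous bases render `X`. Frames +1..+3 read the forward strand from
#' offsets 0..2; -1..-3 read the reverse complement likewise.
#'
#' @param dna a DNA string.
#' @param frame one of +1, +2, +3, -1, -2, -3.
#' @return the peptide string (possibly empty).
#' @export
translate_frame <- function(dna, frame) {
  stopifnot(frame %in% c(1:3, -1:-3))
  s <- if (frame > 0) dna else revcomp(dna)
  off <- abs(frame) - 1L
  codes <- dna_to_codes(s)
  n_codons <- (length(codes) - off) %/% 3L
  if (n_codons < 1L) return("")
  mat <- score_matrix()
  tab <- codon_aa_table(mat)
  i1 <- off + 3L * (seq_len(n_codons) - 1L)
  b1 <- codes[i1 + 1L]; b2 <- codes[i1 + 2L]; b3 <- codes[i1 + 3L]
  ambig <- b1 > 3L | b2 > 3L | b3 > 3L
  idx <- 16L * b1 + 4L * b2 + b3 + 1L
  idx[ambig] <- 1L  # placeholder, overwritten below
  aa_idx <- tab[idx]
  letters_out <- rep("*", n_codons)
  ok <- aa_idx >= 0L
  letters_out[ok] <- colnames(mat)[aa_idx[ok] + 1L]
  letters_out[ambig] <- "X"
  paste(letters_out, collapse = "")
}

#' Six-frame translated Smith-Waterman search
#'
#' Aligns one protein locally against all six conceptual translations of one
#' DNA sequence and reports, per frame, the best local alignment whose raw
#' score reaches `min_raw_score`, as rows of a hit table with subject
#' coordinates on the DNA (source dialect: 1-based inclusive, minus-strand
#' hits have `sstart > send`). Bitscores use fixed Karlin-Altschul constants
#' for BLOSUM62 11/1; `evalue = m * n * 2^-bitscore`.
#'
#' @param protein a single-row protein [seq_records] (or list with `id`,
#'   `seq`).
#' @param dna a single-row DNA [seq_records] (or list with `id`, `seq`).
#' @param params a [search_params()] list.
#' @return a `hit_table` (possibly empty), ranked by bitscore (deterministic tie order).
#' @export
sixframe_search <- function(protein, dna, params = search_params()) {
  pseq <- protein$seq[1]; pid <- protein$id[1]
  dseq <- dna$seq[1]; did <- dna$id[1]
  if (is.na(pseq) || nchar(pseq) < 5L) stop("protein must be >= 5 aa")
  if (is.na(dseq) || nchar(dseq) < 15L) stop("dna must be >= 15 nt")
  mat <- score_matrix(params$matrix)
  pidx <- aa_to_index(pseq, mat)
  n <- nchar(dseq)
  m <- nchar(pseq)
  rows <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(dseq, frame)
    if (nchar(pep) < 1L) next
    res <- cpp_sw_align(pidx, aa_to_index(pep, mat), mat,
                        params$gap_open, params$gap_extend)
    if (res$score < params$min_raw_score) next
    off <- abs(frame) - 1L
    if (frame > 0) {
      canon_start <- off + 3L * (res$b_start - 1L)
      canon_end <- off + 3L * res$b_end
      sstart <- canon_start + 1L
      send <- canon_end
    } else {
      canon_start <- n - off - 3L * res$b_end
      canon_end <- n - off - 3L * (res$b_start - 1L)
      sstart <- canon_end      # minus strand: sstart > send in the dialect
      send <- canon_start + 1L
    }
    bit <- raw_to_bitscore(res$score)
    rows[[length(rows) + 1L]] <- data.frame(
      qseqid = pid, sseqid = did,
      pident = round(100 * res$n_ident / res$n_cols, 1),
      length = res$n_cols, mismatch = res$n_mismatch,
      gapopen = res$n_gapopen, qstart = res$a_start, qend = res$a_end,
      sstart = sstart, send = send,
      evalue = as.numeric(m) * n * 2^(-bit),
      bitscore = round(bit, 1), stitle = "", staxids = "",
      raw = res$score, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(hit_table())
  df <- do.call(rbind, rows)
  out <- hit_table(df)
  out$raw <- df$raw  # kept for tests/diagnostics; not part of the dialect
  out <- out[hit_order(out), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Built-in forward search of chunked genome against a protein set
#'
#' Runs [sixframe_search()] for every (protein, chunk) pair; subject ids are
#' chunk ids, so the result feeds [cap_hits_per_chunk()] and [remap_hits()].
#' Emits a size-guard warning for genomes above `guard_bp` without an
#' external engine.
#'
#' @param proteins protein [seq_records].
#' @param chunks a `chunk_set` from [chunk_genome()].
#' @param params a [search_params()] list.
#' @param guard_bp warn when total chunk length exceeds this (default 5e6).
#' @return a `hit_table` of chunk-local hits (unfiltered).
#' @export
builtin_forward_search <- function(proteins, chunks,
                                   params = search_params(),
                                   guard_bp = 5e6) {
  total <- sum(chunks$length)
  if (total > guard_bp) {
    warning(sprintf(paste0(
      "builtin aligner is O(m*n) per frame and the genome totals %.1f Mb ",
      "(> %.1f Mb); consider an external search engine"),
      total / 1e6, guard_bp / 1e6))
  }
  out <- list()
  for (p in seq_len(nrow(proteins))) {
    for (k in seq_len(nrow(chunks))) {
      h <- sixframe_search(proteins[p, ],
                           list(id = chunks$chunk_id[k],
                                seq = chunks$seq[k]),
                           params)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(hit_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hit_table", "data.frame")
  res
}

#' Run an external DIAMOND-style search
#'
#' Invokes `binary` with `args`, expecting the 14-column tabular dialect on
#' the output path, then parses and filters the result with
#' [filter_and_rank()]. The full argument vector is recorded in the returned
#' table's `"invocation"` attribute and optionally appended to a log file.
#'
#' @param query path to the query FASTA (genome chunks for `mode =
#'   "forward"`, candidate peptides for `"reciprocal"`).
#' @param db path to the subject database.
#' @param params a [search_params()] list.
#' @param mode `"forward"` (translated query) or `"reciprocal"` (protein
#'   query).
#' @param binary executable name or path (default "diamond").
#' @param log_file optional path; the invocation line is appended there.
#' @return a filtered `hit_table`.
#' @export
run_external_search <- function(query, db, params = search_params(),
                                mode = c("forward", "reciprocal"),
                                binary = "diamond", log_file = NULL) {
  mode <- match.arg(mode)
  resolved <- Sys.which(binary)
  if (!nzchar(resolved)) {
    stop("external search binary '", binary, "' not found on PATH; ",
         "supply pre-computed hit tables (engine = 'precomputed') or use ",
         "the built-in aligner (engine = 'builtin')")
  }
  out <- tempfile(fileext = ".tsv")
  subcmd <- if (mode == "forward") "blastx" else "blastp"
  args <- c(subcmd, "--query", query, "--db", db, "--out", out,
            "--outfmt", "6", "qseqid", "sseqid", "pident", "length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore", "stitle", "staxids",
            "--evalue", format(params$evalue_max),
            "--max-target-seqs", as.character(params$per_query_top_hits))
  if (!is.null(log_file)) {
    cat(paste(c(resolved, args), collapse = " "), "\n", file = log_file,
        append = TRUE)
  }
  status <- suppressWarnings(
    system2(resolved, args, stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("external search exited with status ", code, ": ",
         paste(status, collapse = "\n"))
  }
  hits <- parse_tabular_hits(out)
  hits <- filter_and_rank(hits, params)
  attr(hits, "invocation") <- c(resolved, args)
  hits
}
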