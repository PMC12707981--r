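# Candidate-locus construction: interval merging of forward hits, sequence
# extraction with flanks, and getorf-style ORF discovery.
#
# A candidate locus is a list with elements: locus_id, contig, canon_start,
# canon_end (0-based half-open), strand ('+', '-', 'both'), forward_hits
# (hit_table), seq (or NULL before extraction), orfs (data.frame or NULL),
# reconstruction (list or NULL), rvdb_hits, nr_hits, category, fired_rule.

#' Merge parameters
#'
#' @param merge_distance maximum gap (bp) between hit intervals joined into
#'   one locus (default 1000, the pipeline's defragmentation range).
#' @param flank bp of flanking sequence added on extraction (default 0).
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(merge_distance = 1000L, flank = 0L) {
  merge_distance <- as.integer(merge_distance)
  flank <- as.integer(flank)
  if (is.na(merge_distance) || merge_distance < 0L) {
    stop("merge_distance must be >= 0")
  }
  if (is.na(flank) || flank < 0L) stop("flank must be >= 0")
  structure(list(merge_distance = merge_distance, flank = flank),
            class = "merge_params")
}

new_locus <- function(contig, start, end, strand, forward_hits) {
  structure(list(locus_id = sprintf("%s:%d-%d", contig, start, end),
                 contig = contig, canon_start = as.integer(start),
                 canon_end = as.integer(end), strand = strand,
                 forward_hits = forward_hits, seq = NULL, orfs = NULL,
                 reconstruction = NULL, rvdb_hits = hit_table(),
                 nr_hits = hit_table(), category = NA_character_,
                 fired_rule = NA_integer_),
            class = "candidate_locus")
}

#' Merge forward hits into candidate loci
#'
#' Per contig, hit intervals are sorted by canonical start and joined
#' left-to-right: a hit joins the open locus iff the gap between its start
#' and the running maximum end is at most `merge_distance` (overlaps have a
#' negative gap and always join). Merging ignores strand; a locus whose
#' members disagree is reported with strand `"both"`.
#'
#' @param hits a `hit_table` with contig-level canonical coordinates.
#' @param params a [merge_params()] list.
#' @return a list of `candidate_locus` objects, sorted by (contig, start).
#' @export
merge_hits_to_loci <- function(hits, params = merge_params()) {
  if (nrow(hits) == 0L) return(list())
  if (any(hits$canon_start >= hits$canon_end)) {
    stop("hit with canon_start >= canon_end")
  }
  loci <- list()
  for (contig in sort(unique(hits$sseqid))) {
    sub <- hits[hits$sseqid == contig, , drop = FALSE]
    sub <- sub[order(sub$canon_start, sub$canon_end), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L
    max_end <- sub$canon_end[1]
    grp[1] <- g
    for (k in seq_len(nrow(sub))[-1]) {
      if (sub$canon_start[k] - max_end > params$merge_distance) {
        g <- g + 1L
        max_end <- sub$canon_end[k]
      } else {
        max_end <- max(max_end, sub$canon_end[k])
      }
      grp[k] <- g
    }
    for (gg in seq_len(g)) {
      members <- sub[grp == gg, , drop = FALSE]
      rownames(members) <- NULL
      class(members) <- c("hit_table", "data.frame")
      strands <- unique(members$strand)
      strand <- if (length(strands) == 1L) strands else "both"
      loci[[length(loci) + 1L]] <-
        new_locus(contig, min(members$canon_start), max(members$canon_end),
                  strand, members)
    }
  }
  ord <- order(vapply(loci, `[[`, character(1), "contig"),
               vapply(loci, `[[`, integer(1), "canon_start"))
  loci[ord]
}

#' Extract the (flanked) sequence of a locus from the genome
#'
#' The extracted sequence is always the plus strand of
#' `contig[max(0, start - flank), min(contig_length, end + flank))`; the
#' locus coordinates and id are updated to the clamped flanked interval.
#'
#' @param genome DNA [seq_records].
#' @param locus a `candidate_locus`.
#' @param params a [merge_params()] list (for `flank`).
#' @return the locus with `seq` populated and coordinates flank-adjusted.
#' @export
extract_locus_sequence <- function(genome, locus, params = merge_params()) {
  k <- match(locus$contig, genome$id)
  if (is.na(k)) stop("contig not in genome: ", locus$contig)
  L <- nchar(genome$seq[k])
  start <- max(0L, locus$canon_start - params$flank)
  end <- min(L, locus$canon_end + params$flank)
  locus$canon_start <- as.integer(start)
  locus$canon_end <- as.integer(end)
  locus$locus_id <- sprintf("%s:%d-%d", locus$contig, start, end)
  locus$seq <- substring(genome$seq[k], start + 1L, end)
  locus
}

#' Find open reading frames in all six frames
#'
#' `stop_to_stop` mode (the EMBOSS getorf default) reports every maximal
#' in-frame segment between stop codons (or the sequence ends) whose
#' translation is at least `min_orf_aa` residues; `atg_to_stop` reports the
#' sub-segment from the first ATG of each such segment. Minus-frame
#' coordinates are reported on the forward strand, 0-based half-open.
#'
#' @param dna a DNA string.
#' @param min_orf_aa minimum peptide length (default 50).
#' @param mode `"stop_to_stop"` or `"atg_to_stop"`.
#' @return data.frame with columns `frame` (+1..+3, -1..-3), `nt_start`,
#'   `nt_end`, `peptide`, sorted by (nt_start, frame).
#' @export
find_orfs <- function(dna, min_orf_aa = 50L,
                      mode = c("stop_to_stop", "atg_to_stop")) {
  mode <- match.arg(mode)
  if (min_orf_aa < 1L) stop("min_orf_aa must be >= 1")
  L <- nchar(dna)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(dna, frame)
    if (!nchar(pep)) next
    aa <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- c(0L, which(aa == "*"), length(aa) + 1L)
    off <- abs(frame) - 1L
    for (s in seq_len(length(stops) - 1L)) {
      a0 <- stops[s] + 1L          # first aa of segment (1-based)
      a1 <- stops[s + 1L] - 1L     # last aa of segment
      if (a1 < a0) next
      if (mode == "atg_to_stop") {
        codon_is_atg <- aa[a0:a1] == "M"
        first_m <- which(codon_is_atg)
        if (!length(first_m)) next
        a0 <- a0 + first_m[1] - 1L
      }
      n_aa <- a1 - a0 + 1L
      if (n_aa < min_orf_aa) next
      # frame-local nt coordinates (on the translated strand)
      f0 <- off + 3L * (a0 - 1L)
      f1 <- off + 3L * a1
      if (frame > 0) {
        nt_start <- f0; nt_end <- f1
      } else {
        nt_start <- L - f1; nt_end <- L - f0
      }
      out[[length(out) + 1L]] <- data.frame(
        frame = frame, nt_start = nt_start, nt_end = nt_end,
        peptide = paste(aa[a0:a1], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$nt_start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}
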