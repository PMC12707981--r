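# Frameshift-aware protein-to-DNA reconstruction and degradation counting.
#
# The aligner is a local codon-level dynamic program (a GeneWise
# simplification without intron states): CODON steps consume one residue and
# three nucleotides and score with the substitution matrix (or a strongly
# negative but finite stop score, so in-frame stops remain alignable and
# countable); SHIFT steps consume one residue and 1, 2, 4 or 5 nucleotides at
# a flat frameshift penalty; DNA_GAP / PROT_GAP are affine codon/residue
# gaps. Traceback is deterministic (CODON > SHIFT > DNA_GAP > PROT_GAP at
# equal score).

#' Reconstruction parameters
#'
#' @param matrix scoring matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (defaults 12 / 2).
#' @param frameshift_penalty flat cost per SHIFT step (default 20); must
#'   exceed `gap_open` — frameshifts are rarer than indels.
#' @param stop_match_score score of aligning any residue to a stop codon
#'   (default -15, strongly negative but finite).
#' @param coverage_floor protein coverage needed for `intact` (default 0.8).
#' @param max_cells size guard on the DP table (default 2e7 cells).
#' @return a list of class `reconstruct_params`.
#' @export
reconstruct_params <- function(matrix = "BLOSUM62", gap_open = 12,
                               gap_extend = 2, frameshift_penalty = 20,
                               stop_match_score = -15, coverage_floor = 0.8,
                               max_cells = 2e7) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (frameshift_penalty <= gap_open) {
    stop("frameshift_penalty must exceed gap_open")
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 stop_match_score = stop_match_score,
                 coverage_floor = coverage_floor, max_cells = max_cells),
            class = "reconstruct_params")
}

#' Frameshift-aware local alignment of a protein against locus DNA
#'
#' Aligns against the given strand only; use [reconstruct_locus()] to try
#' both strands and keep the better. The returned path jointly covers a
#' contiguous nucleotide interval and a contiguous residue interval.
#'
#' @param protein a single-row protein [seq_records] (or list with `id`,
#'   `seq`).
#' @param locus_dna the locus nucleotide string (plus strand of the locus).
#' @param params a [reconstruct_params()] list.
#' @param locus_id label carried into the result.
#' @param force bypass the size guard.
#' @return an object of class `fs_alignment`: `protein_id`, `locus_id`,
#'   `raw_score`, `prot_start`/`prot_end` (1-based inclusive),
#'   `nt_start`/`nt_end` (0-based half-open, locus-local), `path` (data.frame
#'   `step`, `aa_pos`, `nt_pos`, `nt_len`, `codon`, `aa`),
#'   `reconstructed_peptide` (stops rendered `*`, frameshift residues `X`).
#' @export
frameshift_align <- function(protein, locus_dna,
                             params = reconstruct_params(),
                             locus_id = "locus", force = FALSE) {
  pseq <- protein$seq[1]
  pid <- protein$id[1]
  if (is.na(pseq) || nchar(pseq) < 1L) stop("protein must be non-empty")
  if (nchar(locus_dna) < 3L) stop("locus DNA must be >= 3 nt")
  m <- nchar(pseq)
  n <- nchar(locus_dna)
  if (!force && as.double(m) * n > params$max_cells) {
    stop(sprintf(paste0("DP table of %d x %d cells exceeds the size guard ",
                        "(%g); band the locus or pass force = TRUE"),
                 m, n, params$max_cells))
  }
  mat <- score_matrix(params$matrix)
  res <- cpp_fs_align(aa_to_index(pseq, mat), dna_to_codes(locus_dna), mat,
                      codon_aa_table(mat), match("X", colnames(mat)) - 1L,
                      params$gap_open, params$gap_extend,
                      params$frameshift_penalty, params$stop_match_score)
  path <- data.frame(step = res$step, aa_pos = res$aa_pos,
                     nt_pos = res$nt_pos, nt_len = res$nt_len,
                     stringsAsFactors = FALSE)
  path$codon <- ifelse(path$nt_len > 0,
                       substring(locus_dna, path$nt_pos + 1L,
                                 path$nt_pos + path$nt_len),
                       "")
  path$aa <- vapply(seq_len(nrow(path)), function(k) {
    switch(path$step[k],
           CODON = translate_frame(path$codon[k], 1L),
           SHIFT = "X",
           DNA_GAP = translate_frame(path$codon[k], 1L),
           PROT_GAP = "")
  }, character(1))
  recon <- paste(path$aa, collapse = "")
  structure(list(protein_id = pid, locus_id = locus_id,
                 raw_score = res$score, prot_start = res$prot_start,
                 prot_end = res$prot_end, nt_start = res$nt_start,
                 nt_end = res$nt_end, path = path,
                 reconstructed_peptide = recon, protein_seq = pseq,
                 strand = "+", params = params),
            class = "fs_alignment")
}

#' Quantify degradation from a reconstruction alignment
#'
#' Counts are recomputed from the alignment path: stops are `*` residues in
#' the reconstructed peptide (CODON or DNA_GAP codons translating to a
#' stop), insertions are DNA_GAP steps (extra codons in the locus), deletions
#' are PROT_GAP steps (protein residues unmatched), frameshifts are SHIFT
#' steps. Percent identity is computed over CODON steps only;
#' `protein_coverage` counts residues consumed by CODON and SHIFT steps.
#'
#' @param alignment an `fs_alignment`.
#' @return a list of class `reconstruction_report`: `n_stops`,
#'   `n_insertions`, `n_deletions`, `n_frameshifts`, `pident`,
#'   `protein_coverage`, `intact`, plus `raw_score` and ids.
#' @export
quantify_changes <- function(alignment) {
  path <- alignment$path
  if (nrow(path)) {
    consumed_nt <- sum(path$nt_len)
    if (consumed_nt != alignment$nt_end - alignment$nt_start) {
      stop("malformed path: nucleotide steps do not tile the interval")
    }
  }
  prot <- strsplit(alignment$protein_seq, "", fixed = TRUE)[[1]]
  is_codon <- path$step == "CODON"
  n_codon <- sum(is_codon)
  aa_ref <- rep(NA_character_, nrow(path))
  sel <- path$aa_pos > 0L
  aa_ref[sel] <- prot[path$aa_pos[sel]]
  n_match <- sum(is_codon & path$aa == aa_ref, na.rm = TRUE)
  n_shift <- sum(path$step == "SHIFT")
  plen <- length(prot)
  report <- list(
    protein_id = alignment$protein_id, locus_id = alignment$locus_id,
    n_stops = sum(path$aa == "*"),
    n_insertions = sum(path$step == "DNA_GAP"),
    n_deletions = sum(path$step == "PROT_GAP"),
    n_frameshifts = n_shift,
    pident = if (n_codon > 0) 100 * n_match / n_codon else NA_real_,
    protein_coverage = (n_codon + n_shift) / plen,
    raw_score = alignment$raw_score,
    strand = alignment$strand)
  report$intact <- report$n_stops == 0L && report$n_frameshifts == 0L &&
    report$protein_coverage >= alignment$params$coverage_floor
  class(report) <- "reconstruction_report"
  report
}

#' Pick the reference protein for reconstruction
#'
#' The closest related protein is the subject of the highest-bitscore hit
#' across the forward and reciprocal tables (ties: lower e-value, then
#' lexicographic id), restricted to proteins whose sequence is available in
#' `proteins` — at desk scale that is the forward query set, since reciprocal
#' database subjects carry no sequences.
#'
#' @param locus a `candidate_locus` with `forward_hits` (and optionally
#'   reciprocal tables) attached.
#' @param proteins protein [seq_records] providing candidate references.
#' @return a single-row [seq_records], or NULL if no hit's protein is
#'   available.
#' @export
choose_reference_protein <- function(locus, proteins) {
  cand <- rbind(
    if (nrow(locus$forward_hits)) {
      data.frame(id = locus$forward_hits$qseqid,
                 bitscore = locus$forward_hits$bitscore,
                 evalue = locus$forward_hits$evalue,
                 stringsAsFactors = FALSE)
    },
    if (nrow(locus$rvdb_hits)) {
      data.frame(id = locus$rvdb_hits$sseqid,
                 bitscore = locus$rvdb_hits$bitscore,
                 evalue = locus$rvdb_hits$evalue, stringsAsFactors = FALSE)
    },
    if (nrow(locus$nr_hits)) {
      data.frame(id = locus$nr_hits$sseqid,
                 bitscore = locus$nr_hits$bitscore,
                 evalue = locus$nr_hits$evalue, stringsAsFactors = FALSE)
    })
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[cand$id %in% proteins$id, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$bitscore, cand$evalue, cand$id), , drop = FALSE]
  proteins[match(cand$id[1], proteins$id), , drop = FALSE]
}

#' Reconstruct a locus against its reference protein
#'
#' Aligns the protein against the locus sequence and its reverse complement
#' and keeps the higher-scoring strand (ties: plus).
#'
#' @param locus a `candidate_locus` with `seq` populated.
#' @param protein a single-row protein [seq_records].
#' @param params a [reconstruct_params()] list.
#' @return the locus with `reconstruction` set to the
#'   `reconstruction_report` (which carries the winning strand).
#' @export
reconstruct_locus <- function(locus, protein,
                              params = reconstruct_params()) {
  if (is.null(locus$seq)) stop("locus sequence not extracted")
  fwd <- frameshift_align(protein, locus$seq, params, locus$locus_id)
  rev <- frameshift_align(protein, revcomp(locus$seq), params,
                          locus$locus_id)
  aln <- if (rev$raw_score > fwd$raw_score) {
    rev$strand <- "-"
    rev
  } else {
    fwd
  }
  locus$reconstruction <- quantify_changes(aln)
  locus$reconstruction_alignment <- aln
  locus
}
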