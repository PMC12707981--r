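# Independent oracles. Each is coded from first principles against the same
# contracts as the implementation, deliberately NOT sharing code paths with
# the package internals.

# BLOSUM62 with stop entries forced to the matrix minimum (mirrors the
# package's stop-scoring convention but built here independently).
oracle_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  mat["*", ] <- min(mat)
  mat[, "*"] <- min(mat)
  mat
}

# Best local protein-protein alignment score via Biostrings.
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = oracle_matrix(), gapOpening = gap_open,
    gapExtension = gap_extend)
  Biostrings::score(pa)
}

# Conceptual six-frame translation via Biostrings (fuzzy codons -> X).
oracle_translate6 <- function(dna) {
  d <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(d)
  peps <- character(0)
  for (s in list(d, rc)) {
    for (off in 0:2) {
      L <- length(s) - off
      L <- L - (L %% 3)
      if (L < 3) next
      peps <- c(peps, as.character(Biostrings::translate(
        Biostrings::subseq(s, start = off + 1, width = L),
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
    }
  }
  peps
}

# Six-frame translated search score oracle: best SW score over all frames.
oracle_sixframe_score <- function(protein, dna, gap_open = 11,
                                  gap_extend = 1) {
  max(vapply(oracle_translate6(dna), oracle_sw_score, numeric(1),
             a = protein, gap_open = gap_open, gap_extend = gap_extend))
}

# filter/sort/slice oracle for per-group hit capping.
oracle_top_hits <- function(df, group_col, k, evalue_max = Inf) {
  df <- df[df$evalue <= evalue_max, , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df[[group_col]]), function(g) {
    g <- g[order(-g$bitscore, g$evalue, g$sseqid, g$qseqid), , drop = FALSE]
    utils::head(g, k)
  }))
  rownames(out) <- NULL
  out
}

# Brute-force transitive-closure interval merger. Intervals are 0-based
# half-open; two intervals connect when the gap between them is at most d.
oracle_merge <- function(starts, ends, d) {
  n <- length(starts)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  gap <- function(i, j) {
    max(starts[i], starts[j]) - min(ends[i], ends[j])
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && gap(i, j) <= d) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    data.frame(start = min(starts[comp == cc]), end = max(ends[comp == cc]))
  }))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force six-frame ORF scan using Biostrings translations only.
oracle_orfs <- function(dna, min_aa, mode = "stop_to_stop") {
  L <- nchar(dna)
  res <- list()
  d <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(d)
  for (sgn in c(1L, -1L)) {
    s <- if (sgn > 0) d else rc
    for (off in 0:2) {
      w <- length(s) - off
      w <- w - (w %% 3)
      if (w < 3) next
      pep <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start = off + 1, width = w),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      aa <- strsplit(pep, "")[[1]]
      bounds <- c(0L, which(aa == "*"), length(aa) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        a0 <- bounds[b] + 1L
        a1 <- bounds[b + 1L] - 1L
        if (a1 < a0) next
        if (mode == "atg_to_stop") {
          mpos <- which(aa[a0:a1] == "M")
          if (!length(mpos)) next
          a0 <- a0 + mpos[1] - 1L
        }
        if (a1 - a0 + 1L < min_aa) next
        f0 <- off + 3L * (a0 - 1L)
        f1 <- off + 3L * a1
        res[[length(res) + 1L]] <- data.frame(
          frame = sgn * (off + 1L),
          nt_start = if (sgn > 0) f0 else L - f1,
          nt_end = if (sgn > 0) f1 else L - f0,
          peptide = paste(aa[a0:a1], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$nt_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independently coded six-rule classifier, written straight from the printed
# decision tree.
oracle_classify <- function(p) {
  has <- function(xs, pat, fixed = TRUE) {
    length(xs) > 0 && any(grepl(pat, xs, fixed = fixed))
  }
  retro_fam <- has(p$rvdb_families, "retro") || has(p$rvdb_families, "caulimo")
  retro_title <- has(
    p$all_titles,
    "\\bgag\\b|\\bpol\\b|\\benv\\b|reverse|pro[-]?pol|protease|\\bpro\\b|\\brt[-]?in\\b",
    fixed = FALSE)
  if (retro_fam && retro_title) return("likely-retro")
  host_kw <- has(p$all_titles, "ubiquitin") || has(p$all_titles, "zinc") ||
    has(p$all_titles, "nynrin") || has(p$all_titles, "kinase")
  if (p$n_rvdb == 0 || (p$n_nr > 0 && p$n_rvdb < 0.30 * p$n_nr) || host_kw) {
    return("likely-host-protein")
  }
  if (has(p$rvdb_kingdoms, "bamford")) return("bamford-related")
  if (!is.na(p$frac_rvdb_euk) && p$frac_rvdb_euk > 0.80 &&
      grepl("\\bpol\\b|transpos|\\bgag\\b|group specific antigen",
            p$best_rvdb_title)) {
    return("likely-transposon")
  }
  excluded <- has(p$rvdb_families, "baculo") || has(p$rvdb_families, "poly") ||
    has(p$rvdb_families, "fabace") || has(p$rvdb_families, "allohe")
  eve1 <- !is.na(p$frac_rvdb_viral) && p$frac_rvdb_viral > 0.60 && !excluded
  eve2 <- !is.na(p$frac_nr_viral) && p$frac_nr_viral > 0.50
  if (eve1 || eve2) return("likely-eve")
  "uncertain"
}

# Exhaustive-path oracle for the frameshift-aware aligner, for tiny
# instances. Recursion over (residues consumed, nt consumed, last step kind)
# scoring alignments that END at (i, j) with a codon/shift step; gap-run
# affinity is tracked through the last-step kind.
oracle_fs_best <- function(protein, dna, gap_open = 12, gap_extend = 2,
                           fs_penalty = 20, stop_score = -15) {
  mat <- oracle_matrix()
  paa <- strsplit(protein, "")[[1]]
  m <- length(paa)
  n <- nchar(dna)
  gc <- Biostrings::GENETIC_CODE
  codon_sc <- function(j0, k, aa) {  # nt j0+1 .. j0+k consumed
    if (k != 3) return(-fs_penalty)
    codon <- substr(dna, j0 + 1, j0 + 3)
    tr <- unname(gc[codon])
    if (is.na(tr)) return(mat[aa, "X"])
    if (tr == "*") return(stop_score)
    mat[aa, tr]
  }
  memo <- new.env(hash = TRUE)
  # best score of a legal path ending at state (i, j, last)
  best_end <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- -Inf
    if (last %in% c("codon", "shift")) {
      ks <- if (last == "codon") 3L else c(1L, 2L, 4L, 5L)
      for (k in ks) {
        if (i < 1 || j < k) next
        s <- codon_sc(j - k, k, paa[i])
        prev <- 0  # fresh local start
        for (pl in c("codon", "shift", "dgap", "pgap")) {
          prev <- max(prev, best_end(i - 1L, j - k, pl))
        }
        res <- max(res, prev + s)
      }
    } else if (last == "dgap") {
      if (j >= 3) {
        for (pl in c("codon", "shift", "dgap", "pgap")) {
          p <- best_end(i, j - 3L, pl)
          cost <- if (pl == "dgap") gap_extend else gap_open + gap_extend
          res <- max(res, p - cost)
        }
      }
    } else {  # pgap
      if (i >= 1) {
        for (pl in c("codon", "shift", "dgap", "pgap")) {
          p <- best_end(i - 1L, j, pl)
          cost <- if (pl == "pgap") gap_extend else gap_open + gap_extend
          res <- max(res, p - cost)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  best <- 0
  for (i in 0:m) for (j in 0:n) {
    for (last in c("codon", "shift")) {  # local paths end on a match step
      best <- max(best, best_end(i, j, last))
    }
  }
  best
}

# Codon-level Smith-Waterman oracle in the no-frameshift limit: protein vs
# the +1 frame translation, with codon gaps equivalent to residue gaps.
oracle_codon_sw <- function(protein, dna, gap_open = 12, gap_extend = 2) {
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, nchar(dna) - nchar(dna) %% 3)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  oracle_sw_score(protein, pep, gap_open, gap_extend)
}
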