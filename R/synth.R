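# Synthetic world: toy viral proteins, host genomes with planted degraded
# viral inserts and exact ground truth, a mock taxdump, and reciprocal hit
# tables engineered to force each classification category.
#
# Everything is deterministic under a seed. Degradation events (stops,
# frameshifts, whole-codon indels) are planted at interior codons, at least
# EVENT_MARGIN codons from either end of the insert, for two reasons fixed
# before any experiment was run: (i) identifiability — a local aligner can
# always trim a terminal event away more cheaply than paying its penalty, so
# events within a few codons of an end have no recoverable truth; and
# (ii) detectability — a terminal segment shorter than ~30 codons scores
# below the forward search's E <= 1e-5 reporting threshold at desk-scale
# search-space sizes, so full-interval recovery is only a fair ask when the
# outermost segments are long enough to be significant. Substitutions are
# missense-only (never create a stop) and keep a clean EDGE_MARGIN so local
# alignments anchor at the exact insert boundaries.

EVENT_MARGIN <- 30L  # codons kept event-free at each end of an insert
EDGE_MARGIN <- 5L    # codons kept substitution-free at each end

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# amino acid -> synonymous codons, from the standard genetic code
aa_codons <- function() {
  if (!is.null(.evescreen_env$aa_codons)) return(.evescreen_env$aa_codons)
  gc <- Biostrings::GENETIC_CODE
  tab <- split(names(gc), unname(gc))
  .evescreen_env$aa_codons <- tab
  tab
}

#' Generate random toy viral proteins
#'
#' Uniform residue composition over the 20 standard amino acids; ids are
#' `vp1, vp2, ...`.
#'
#' @param n number of proteins.
#' @param length_range inclusive range of lengths in aa (default 80-120).
#' @param seed RNG seed.
#' @return protein [seq_records].
#' @export
generate_proteins <- function(n, length_range = c(80L, 120L), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  vals <- seq.int(length_range[1], length_range[2])
  lens <- vals[sample.int(length(vals), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
  seq_records(id = paste0("vp", seq_len(n)), seq = seqs,
              moltype = "protein")
}

#' Generate a random background genome
#'
#' i.i.d. bases with configurable GC content; contig ids `contig1, ...`.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param gc GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return DNA [seq_records].
#' @export
random_genome <- function(n_contigs = 1L, contig_length = 100000L,
                          gc = 0.5, seed = 1L) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(n_contigs), function(k) {
    paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
                 prob = p), collapse = "")
  }, character(1))
  seq_records(id = paste0("contig", seq_len(n_contigs)), seq = seqs,
              moltype = "dna")
}

# Back-translate a peptide with uniform synonymous codon choice (uses the
# current RNG state).
back_translate <- function(peptide) {
  tab <- aa_codons()
  codons <- vapply(strsplit(peptide, "", fixed = TRUE)[[1]], function(aa) {
    opts <- tab[[aa]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Specification of one planted, degraded viral insert
#'
#' @param protein_id id of the source protein.
#' @param contig target contig id.
#' @param position 0-based insertion point in the background contig.
#' @param strand `"+"` or `"-"` (insert reverse-complemented when `"-"`).
#' @param n_stops planted in-frame stop codons.
#' @param n_frameshifts planted 1-2 nt insertions/deletions within a codon.
#' @param n_insertions planted whole-codon insertions.
#' @param n_deletions planted whole-codon deletions.
#' @param substitution_rate per-codon probability of a (missense-only)
#'   nucleotide substitution.
#' @return a list of class `plant_spec`.
#' @export
plant_spec <- function(protein_id, contig, position, strand = "+",
                       n_stops = 0L, n_frameshifts = 0L, n_insertions = 0L,
                       n_deletions = 0L, substitution_rate = 0) {
  stopifnot(strand %in% c("+", "-"), position >= 0,
            n_stops >= 0, n_frameshifts >= 0, n_insertions >= 0,
            n_deletions >= 0, substitution_rate >= 0,
            substitution_rate <= 1)
  structure(list(protein_id = protein_id, contig = contig,
                 position = as.integer(position), strand = strand,
                 n_stops = as.integer(n_stops),
                 n_frameshifts = as.integer(n_frameshifts),
                 n_insertions = as.integer(n_insertions),
                 n_deletions = as.integer(n_deletions),
                 substitution_rate = substitution_rate),
            class = "plant_spec")
}

# Back-translate and degrade one protein per its spec (uses current RNG
# state). Returns list(dna, events data.frame).
degrade_insert <- function(peptide, spec) {
  L <- nchar(peptide)
  dna <- back_translate(peptide)
  codons <- substring(dna, 3L * (seq_len(L) - 1L) + 1L, 3L * seq_len(L))
  n_events <- spec$n_stops + spec$n_frameshifts + spec$n_insertions +
    spec$n_deletions
  lo <- EVENT_MARGIN + 1L
  hi <- L - EVENT_MARGIN
  if (n_events > 0 && hi - lo + 1L < 2L * n_events) {
    stop("protein too short for the requested number of events")
  }
  pos <- integer(0)
  if (n_events > 0) {
    repeat {
      pos <- sort(sample(lo:hi, n_events))
      if (n_events == 1L || min(diff(pos)) >= 2L) break
    }
  }
  kinds <- c(rep("stop", spec$n_stops),
             rep("frameshift", spec$n_frameshifts),
             rep("insertion", spec$n_insertions),
             rep("deletion", spec$n_deletions))
  if (length(kinds) > 1L) kinds <- sample(kinds)
  events <- data.frame(codon = pos, kind = kinds,
                       stringsAsFactors = FALSE)

  # missense-only substitutions outside the clean edges and event codons
  sub_ok <- setdiff((EDGE_MARGIN + 1L):(L - EDGE_MARGIN), pos)
  for (cpos in sub_ok) {
    if (stats::runif(1) >= spec$substitution_rate) next
    repeat {
      cd <- strsplit(codons[cpos], "", fixed = TRUE)[[1]]
      k <- sample.int(3L, 1L)
      cd[k] <- sample(setdiff(c("A", "C", "G", "T"), cd[k]), 1L)
      cand <- paste(cd, collapse = "")
      if (!cand %in% c("TAA", "TAG", "TGA")) {
        codons[cpos] <- cand
        break
      }
    }
  }

  # apply structural events in descending codon order so positions hold
  if (nrow(events)) {
    for (k in order(-events$codon)) {
      cpos <- events$codon[k]
      kind <- events$kind[k]
      if (kind == "stop") {
        codons[cpos] <- sample(c("TAA", "TAG", "TGA"), 1L)
      } else if (kind == "frameshift") {
        op <- sample(c("del1", "del2", "ins1", "ins2"), 1L)
        cd <- codons[cpos]
        codons[cpos] <- switch(op,
          del1 = substring(cd, 1L, 2L),
          del2 = substring(cd, 1L, 1L),
          ins1 = paste0(cd, sample(c("A", "C", "G", "T"), 1L)),
          ins2 = paste0(cd, paste(sample(c("A", "C", "G", "T"), 2L,
                                         replace = TRUE), collapse = "")))
      } else if (kind == "deletion") {
        codons <- codons[-cpos]
      } else {  # insertion of a whole random (non-stop) codon
        repeat {
          ins <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                       collapse = "")
          if (!ins %in% c("TAA", "TAG", "TGA")) break
        }
        codons <- append(codons, ins, after = cpos)
      }
    }
  }
  list(dna = paste(codons, collapse = ""), events = events)
}

#' Plant degraded viral inserts into a background genome
#'
#' Each spec's protein is back-translated (uniform synonymous codons),
#' degraded exactly per the spec, reverse-complemented for minus-strand
#' plants, and inserted at its position; truth intervals are reported in
#' final (post-insertion) coordinates.
#'
#' @param genome background DNA [seq_records].
#' @param proteins protein [seq_records] containing every spec's protein.
#' @param specs list of [plant_spec()] objects; positions on one contig must
#'   be strictly increasing.
#' @param seed RNG seed.
#' @return list with `genome` (modified [seq_records]) and `truth`
#'   (data.frame: protein_id, contig, start, end, strand, event counts,
#'   insert_seq), of class `truth_set`.
#' @export
plant_eves <- function(genome, proteins, specs, seed = 1L) {
  set.seed(seed)
  by_contig <- split(specs, vapply(specs, `[[`, character(1), "contig"))
  truth <- list()
  for (contig in names(by_contig)) {
    k <- match(contig, genome$id)
    if (is.na(k)) stop("spec targets unknown contig: ", contig)
    cs <- by_contig[[contig]]
    posv <- vapply(cs, `[[`, integer(1), "position")
    if (is.unsorted(posv, strictly = TRUE)) {
      stop("plant positions on ", contig, " must be strictly increasing")
    }
    bg <- genome$seq[k]
    if (max(posv) > nchar(bg)) stop("plant position beyond contig end")
    segments <- character(0)
    prev <- 0L
    shift <- 0L
    for (s in cs) {
      p <- match(s$protein_id, proteins$id)
      if (is.na(p)) stop("unknown protein in spec: ", s$protein_id)
      deg <- degrade_insert(proteins$seq[p], s)
      insert <- if (s$strand == "-") revcomp(deg$dna) else deg$dna
      segments <- c(segments, substring(bg, prev + 1L, s$position), insert)
      start <- s$position + shift
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = s$protein_id, contig = contig, start = start,
        end = start + nchar(insert), strand = s$strand,
        n_stops = s$n_stops, n_frameshifts = s$n_frameshifts,
        n_insertions = s$n_insertions, n_deletions = s$n_deletions,
        insert_seq = insert, stringsAsFactors = FALSE)
      shift <- shift + nchar(insert)
      prev <- s$position
    }
    segments <- c(segments, substring(bg, prev + 1L, nchar(bg)))
    genome$seq[k] <- paste(segments, collapse = "")
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(genome = genome, truth = truth, seed = seed),
            class = "truth_set")
}

# --- mock taxonomy ---------------------------------------------------------

MOCK_TAXA <- data.frame(
  taxid = c(1, 10239, 2759,
            2732005, 2732396, 2732397, 2732527, 2732529,
            11632, 186534, 178830, 11266, 11158, 39724, 10780, 10442,
            151341,
            90001, 90002, 90003, 90004, 90005, 90006, 90007, 90008, 90009,
            33208, 33090, 9606, 10090, 3803, 90010),
  parent = c(1, 1, 1,
             10239, 10239, 10239, 10239, 10239,
             2732397, 2732397, 2732396, 2732396, 2732396, 2732527, 2732527,
             2732529, 2732527,
             11632, 186534, 178830, 11266, 39724, 10780, 10442, 151341,
             2732005,
             2759, 2759, 33208, 33208, 33090, 3803),
  rank = c("no rank", "superkingdom", "superkingdom",
           rep("kingdom", 5),
           rep("family", 9),
           rep("species", 9),
           "kingdom", "kingdom", "species", "species", "family",
           "species"),
  name = c("root", "Viruses", "Eukaryota",
           "Bamfordvirae", "Orthornavirae", "Pararnavirae", "Shotokuvirae",
           "Heunggongvirae",
           "Retroviridae", "Caulimoviridae", "Bornaviridae", "Filoviridae",
           "Paramyxoviridae", "Circoviridae", "Parvoviridae",
           "Baculoviridae", "Polyomaviridae",
           "Mock retrovirus", "Mock caulimovirus", "Mock bornavirus",
           "Mock filovirus", "Mock circovirus", "Mock parvovirus",
           "Mock baculovirus", "Mock polyomavirus", "Mock bamfordvirus",
           "Metazoa", "Viridiplantae", "Homo sapiens", "Mus musculus",
           "Fabaceae", "Mock legume"),
  stringsAsFactors = FALSE)

#' Write a mock NCBI taxdump
#'
#' Emits `nodes.dmp` and `names.dmp` for a ~30-node synthetic taxonomy
#' spanning Viruses (with a Bamfordvirae kingdom and the common benchmark
#' families) and Eukaryota, in the real dmp dialect.
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
mock_taxdump <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- MOCK_TAXA
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", t$taxid, t$parent, t$rank),
             file.path(dir, "nodes.dmp"))
  # include a synonym row to exercise the name-class filter
  name_lines <- c(
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", t$taxid, t$name),
    "10239\t|\tVira\t|\t\t|\tsynonym\t|")
  writeLines(name_lines, file.path(dir, "names.dmp"))
  invisible(dir)
}

# --- mock reciprocal evidence ---------------------------------------------

SCENARIOS <- c("retro", "host", "bamford", "transposon", "eve", "uncertain")

scenario_rows <- function(locus_id, scenario, counter) {
  row <- function(i, n, stitle, staxid, bitscore) {
    data.frame(qseqid = locus_id, sseqid = sprintf("db%05d", counter + i),
               pident = 40, length = 100, mismatch = 60, gapopen = 0,
               qstart = 1, qend = 100, sstart = 1, send = 100,
               evalue = 1e-20, bitscore = bitscore, stitle = stitle,
               staxids = as.character(staxid), stringsAsFactors = FALSE)
  }
  mk <- function(n, titles, taxids) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      row(i, n, titles[(i - 1) %% length(titles) + 1],
          taxids[(i - 1) %% length(taxids) + 1], 200 - 5 * i)
    }))
  }
  generic <- "hypothetical conserved peptide"
  switch(scenario,
    retro = list(
      rvdb = mk(5, c("gag polyprotein", "reverse transcriptase"), 90001),
      nr = mk(5, "gag polyprotein", 90001)),
    host = list(
      rvdb = mk(1, generic, 90005),
      nr = mk(10, generic, 9606)),
    bamford = list(
      rvdb = mk(5, "major capsid peptide", 90009),
      nr = mk(5, generic, 9606)),
    transposon = list(
      rvdb = mk(5, "transposase", 9606),
      nr = mk(5, generic, 9606)),
    eve = list(
      rvdb = mk(5, "capsid peptide", 90005),
      nr = mk(5, generic, c(90005, 90005, 9606, 9606, 9606))),
    uncertain = list(
      rvdb = mk(5, generic, c(90005, 90005, 9606, 9606, 9606)),
      nr = mk(5, generic, c(90005, 90005, 9606, 9606, 9606))),
    stop("unknown scenario: ", scenario))
}

#' Mock reciprocal hit tables forcing a category per locus
#'
#' For each locus id and scenario, emits RVDB and nr hit rows whose titles
#' and taxids (consistent with [mock_taxdump()]) drive the decision tree to
#' the scenario's category.
#'
#' @param locus_ids character vector of locus ids (used as `qseqid`).
#' @param scenarios per locus, one of "retro", "host", "bamford",
#'   "transposon", "eve", "uncertain".
#' @param rvdb_path,nr_path output TSV paths.
#' @return invisibly, a list with the two hit tables.
#' @export
mock_reciprocal_tables <- function(locus_ids, scenarios, rvdb_path,
                                   nr_path) {
  stopifnot(length(locus_ids) == length(scenarios),
            all(scenarios %in% SCENARIOS))
  rvdb <- list()
  nr <- list()
  for (k in seq_along(locus_ids)) {
    rows <- scenario_rows(locus_ids[k], scenarios[k], 100L * k)
    rvdb[[k]] <- rows$rvdb
    nr[[k]] <- rows$nr
  }
  rvdb <- hit_table(do.call(rbind, rvdb))
  nr <- hit_table(do.call(rbind, nr))
  write_tabular_hits(rvdb, rvdb_path)
  write_tabular_hits(nr, nr_path)
  invisible(list(rvdb = rvdb, nr = nr))
}

#' Expected category for each synthetic scenario
#'
#' @param scenario scenario name(s).
#' @return the category label(s) the mock evidence is engineered to force.
#' @export
scenario_category <- function(scenario) {
  map <- c(retro = "likely-retro", host = "likely-host-protein",
           bamford = "bamford-related", transposon = "likely-transposon",
           eve = "likely-eve", uncertain = "uncertain")
  unname(map[scenario])
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `genome.fna`, `proteins.faa`, `truth.tsv`, `truth.bed` and
#' `taxdump/` under `dir`. Plants are spaced evenly along each contig with
#' scenarios assigned round-robin; each plant carries 0-2 stops, 0-2
#' frameshifts and 0-1 whole-codon indels.
#'
#' @param dir output directory.
#' @param n_proteins number of toy proteins (default 20).
#' @param contig_length background contig length (default 400000).
#' @param n_plants number of planted EVEs (default 20).
#' @param substitution_rate per-codon missense rate (default 0.05).
#' @param seed RNG seed.
#' @return invisibly, the `truth_set` with an added `scenario` truth column.
#' @export
simulate_dataset <- function(dir, n_proteins = 20L, contig_length = 400000L,
                             n_plants = 20L, substitution_rate = 0.05,
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- generate_proteins(n_proteins, seed = seed)
  genome <- random_genome(1L, contig_length, seed = seed + 1L)
  set.seed(seed + 2L)
  positions <- sort(as.integer(round(
    seq(contig_length * 0.02, contig_length * 0.98,
        length.out = n_plants) +
      stats::runif(n_plants, -contig_length * 0.005,
                   contig_length * 0.005))))
  scenarios <- rep(SCENARIOS, length.out = n_plants)
  strands <- rep(c("+", "-"), length.out = n_plants)
  specs <- lapply(seq_len(n_plants), function(k) {
    plant_spec(proteins$id[(k - 1L) %% n_proteins + 1L], "contig1",
               positions[k], strand = strands[k],
               n_stops = sample(0:2, 1L),
               n_frameshifts = sample(0:2, 1L),
               n_insertions = sample(0:1, 1L),
               n_deletions = sample(0:1, 1L),
               substitution_rate = substitution_rate)
  })
  ts <- plant_eves(genome, proteins, specs, seed = seed + 3L)
  ts$truth$scenario <- scenarios[order(positions)]
  write_fasta(ts$genome, file.path(dir, "genome.fna"))
  write_fasta(proteins, file.path(dir, "proteins.faa"))
  utils::write.table(
    ts$truth[, setdiff(names(ts$truth), "insert_seq")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ts$truth$contig,
                     ts$truth$start, ts$truth$end, ts$truth$protein_id,
                     ts$truth$strand),
             file.path(dir, "truth.bed"))
  mock_taxdump(file.path(dir, "taxdump"))
  invisible(ts)
}
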