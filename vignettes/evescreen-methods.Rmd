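---
title: "Methods: how evescreen finds and classifies endogenous viral elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how evescreen finds and classifies endogenous viral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescreen)
```

## The problem

Endogenous viral elements (EVEs) are fragments of viral genomes that
integrated into a host germline and have been inherited ever since. They are
genomic fossils: most evolve neutrally, accumulating substitutions, in-frame
stop codons, insertions, deletions and frameshifts, until only 20–40% amino
acid identity to their closest known viral relative remains. Finding them in
a host assembly therefore means running a *translated* similarity search with
permissive thresholds — and then deciding, for every candidate interval,
whether it is really a viral integration rather than a host gene that some
virus once captured (or a transposable element that happens to share
retroviral machinery).

`evescreen` implements the computational core of that workflow as a plain R
package: genome chunking, forward search coordination, hit filtering,
interval merging into candidate loci, ORF discovery, frameshift-aware
protein reconstruction with degradation counting, and a six-category
rule-based classifier driven by reciprocal-search evidence and NCBI taxonomy
lineages. A synthetic-data generator plants degraded viral inserts with
exact ground truth so that every stage is testable offline.

## Pipeline model

The driver (`run_pipeline()`) executes, in order:

1. **chunk** — each contig is split into non-overlapping fixed-size chunks
   (default 50,000 bp). Chunking equalizes hit reporting across large
   contigs: without it, high-copy families (endogenous retroviruses above
   all) monopolize the per-target reporting budget and mask rare EVEs.
   Chunks do not overlap; a homology block split by a chunk boundary is
   rejoined downstream by interval merging, which bounds the cost of the
   split.
2. **search** — each chunk is searched against the viral protein query set.
   Three engines emit identical hit tables: an external DIAMOND-style
   binary, pre-computed tabular files, or the built-in six-frame
   Smith–Waterman aligner (below).
3. **filter** — hits above the e-value ceiling (default 1e-5) are dropped;
   at most 10 hits per query and 1000 per chunk are kept, ranked by
   bitscore with a deterministic tie order (e-value, subject id, query id).
4. **merge** — remapped hits are joined into candidate loci when the gap
   between them is at most 1000 bp (the defragmentation distance). Merging
   ignores strand: degraded EVEs accumulate inversions, and the
   defragmentation behavior this mirrors is defined purely by distance.
   Loci whose member hits disagree on strand are reported as strand `both`.
5. **extract / orfs** — locus sequences are cut from the genome (optionally
   with flanks, default 0 since no canonical flank size exists) and scanned
   for ORFs in all six frames. The default ORF semantics are
   *stop-to-stop* (the EMBOSS getorf default: maximal in-frame segments
   between stops); `atg_to_stop` is available. The minimum ORF length
   (default 50 aa) is a package convention — the upstream tools leave it to
   the user.
6. **reciprocal** — per-locus evidence tables against a curated viral
   database (RVDB-like) and a broad protein database (nr-like) are attached
   from pre-computed files (the multi-hundred-GB reference databases are
   out of desk-scale scope).
7. **reconstruct** — each locus is aligned against its reference protein
   (the highest-bitscore hit whose sequence is available, ties broken by
   e-value then id) with the frameshift-aware aligner, on both strands,
   keeping the better.
8. **classify** — the six-rule decision tree (below) labels each locus.

Every stage persists its inputs/outputs as plain files under the output
directory, so any prefix of stages can be run (`stop_after`) and resumed
(`resume = TRUE`) with byte-identical results.

## The built-in six-frame search engine

The built-in engine exists so the whole pipeline runs and is testable
without network access or external binaries. It is an exact local
(Smith–Waterman/Gotoh) aligner of the query protein against all six
conceptual translations of each chunk, with BLOSUM62, affine gaps
(open 11, extend 1), and stop codons retained as a sentinel letter scoring
the matrix minimum (−4). Truncating frames at stops would hide exactly the
degradation this pipeline exists to measure.

Bitscores use fixed published Karlin–Altschul constants for gapped BLOSUM62
11/1 (λ = 0.267, K = 0.041) and `E = m·n·2^(−bit)`. These statistics are
documented as approximate: they exist so the same e-value filtering code
paths run in tests, not to replace a production search engine's statistics.
The engine is explicitly desk-scale — O(m·n) per frame — and the pipeline
warns above a 5 Mb genome guard. One best local alignment is reported per
(protein, chunk, frame); multi-hit-per-frame reporting is not implemented
because boundary and frameshift splits already surface as separate frame or
chunk hits and are rejoined by merging.

## Frameshift-aware reconstruction

The reconstruction stage is a GeneWise-style simplification: a local dynamic
program over (protein residue, nucleotide) with four step types:

* `CODON` — one residue against three nucleotides, scored by BLOSUM62, or by
  a strongly negative but finite stop score (−15) when the codon is a stop.
  Stops must be *alignable* to be *countable*.
* `SHIFT` — one residue against 1, 2, 4 or 5 nucleotides at a flat penalty
  (20): the odd-length codon reading of a ±1/±2 frameshift. Each SHIFT
  counts as one frameshift. The penalty deliberately exceeds the gap-open
  penalty — frameshifts are rarer than indels.
* `DNA_GAP` — an extra codon in the locus (affine, open 12 extend 2);
  counted as an insertion.
* `PROT_GAP` — an unmatched protein residue (same affine costs); counted as
  a deletion.

Traceback is deterministic: at equal score the move priority is
CODON > SHIFT > DNA_GAP > PROT_GAP, and a fresh local start is preferred
over extending a zero-score prefix. The report recomputes all counts from
the path; percent identity is taken over CODON steps only, while protein
coverage counts residues consumed by CODON and SHIFT steps (a frameshifted
residue is located, though not scored, by the alignment). A locus is
`intact` when it has no stops, no frameshifts and coverage at least 0.8 —
the coverage floor is a package convention, since "intactness" has no
canonical numeric definition.

Introns are *not* modeled: the full GeneWise state machine's splice states
are out of scope, and long `DNA_GAP` runs simply appear as unaligned locus
segments in the output. The DP is written in C++ (Rcpp) with a size guard
(default 2×10⁷ cells) rather than heuristic acceleration.

A note on tiny examples: with the default penalties, a 5-residue protein
cannot "afford" an interior event — trimming two flanking residues is
cheaper than a 20-point frameshift penalty, which is the *correct* local
alignment. The micro-examples in the test suite therefore use softened
penalties where the intended path is verified against an exhaustive path
enumeration; default-penalty behavior is validated on realistic protein
lengths.

## The six-category classifier

For each locus, reciprocal hits are summarized into an evidence profile: hit
counts per database, fractions of viral/eukaryotic hits (a hit is viral if
*any* of its taxids has superkingdom Viruses — the permissive reading of
multi-taxid subjects), the set of family and kingdom names in the RVDB hits'
lineages, the best RVDB hit title, and the pooled lowercased titles.
Fractions over an empty table are explicitly undefined (NA), never zero.
Rules fire strictly in order; the first match wins:

1. **likely-retro** — an RVDB family containing `retro` or `caulimo` AND a
   retroviral protein name (`gag`, `pol`, `env`, `reverse`, `pro-pol`,
   `protease`, `pro`, `rt-in`) among the titles.
2. **likely-host-protein** — no RVDB hits, or RVDB hits fewer than 30% of
   the nr hit count, or a host-gene keyword (`ubiquitin`, `zinc`, `nynrin`,
   `kinase`) in any title.
3. **bamford-related** — any RVDB kingdom containing `bamford`. Large DNA
   viruses of this kingdom capture host genes so often that their hits
   deserve their own bin rather than a forced call.
4. **likely-transposon** — more than 80% of RVDB hits eukaryotic AND a
   transposable-element keyword in the best RVDB title.
5. **likely-eve** — more than 60% of RVDB hits viral with none of the
   families matching `baculo`, `poly`, `fabace`, `allohe`; OR more than 50%
   of nr hits viral.
6. **uncertain** — otherwise.

All thresholds are strict inequalities, pinned by tests. Two deliberate
interpretation choices are worth knowing about. First, short keywords
(`pol`, `env`, `gag`, `pro`, `rt-in`) are matched with word boundaries by
default: a bare substring `pol` fires on every "polymerase" and `pro` on
every "protein", which cannot be the intent of a keyword list; the literal
substring behavior is available via
`eve_ruleset(substring_keywords = TRUE)`. Second, rule 2's denominator is
the nr hit count alone (the literal reading of "hits to NR"), and when
there are no nr hits that clause simply cannot fire. The family exclusion
in rule 5 is a substring match as printed, so `poly` also vetoes
e.g. Polyomaviridae — intentionally reproduced.

## The synthetic world

`simulate_dataset()` generates: uniform-composition toy viral proteins
(ids `vp1..vpN`); an i.i.d.-uniform background genome (GC configurable;
uniform composition minimizes accidental homology with the planted
inserts); planted inserts made by back-translating each protein with
uniform synonymous codon choice and then degrading it *exactly* per its
spec — stop events overwrite a codon with TAA/TGA/TAG, frameshift events
insert or delete 1–2 nt within a codon, indel events insert or delete whole
codons, and substitutions mutate single bases at a per-codon rate
(missense-only: a substitution that would create a stop is resampled, so
planted stop counts stay exact); a ~30-node mock taxdump spanning Viruses
(with a Bamfordvirae kingdom and the common benchmark families) and
Eukaryota; and reciprocal hit tables engineered per locus to force each of
the six categories.

Two generator constraints were fixed before any recovery experiment was
run, and both are identifiability conditions rather than tuning:

* **Events are planted ≥ 30 codons from either insert end.** A local
  aligner can always trim a terminal event more cheaply than paying its
  penalty, so events within a few codons of an end have no recoverable
  truth; and a terminal segment shorter than ~30 codons scores below the
  e-value reporting threshold at desk-scale search spaces, so demanding
  full-interval recovery of such an insert would be demanding the
  statistically impossible.
* **Substitutions keep a 5-codon clean margin at the insert ends**, so
  local alignments anchor at the exact planted boundaries and truth
  intervals are sharply defined.

What a green test does and does not establish: the generator produces
uniform-composition sequences with independent events — no codon-usage
bias, no repeats, no nested/overlapping integrations, no orthologous copies
across genomes, and no intron structure. Passing the planted-recovery tests
establishes the *mechanics* (coordinates, merging, counting,
classification) exactly; it does not establish sensitivity on real genomes
against real databases, which depends on search engine sensitivity and
database composition outside this package's scope.

## Numerical and design choices

* Internal coordinates are 0-based half-open with explicit strand
  everywhere; the tabular dialect (1-based inclusive, orientation-encoded
  strand) is converted only at the parse boundary.
* Chunk ids use the grammar `{contig}:{offset}`, split on the *last* colon
  so contig names containing colons survive.
* All per-group truncations (per-query, per-chunk) use one total order:
  bitscore desc, e-value asc, subject id, query id — reproducible across
  runs and platforms.
* Configuration files are JSON: the environment provides a JSON reader
  (jsonlite) and no YAML parser; the config surface is unchanged.
* The scoring matrix is Biostrings' BLOSUM62 with `*` rows/columns forced
  to the matrix minimum; no matrix data is bundled.
* Degenerate inputs: empty hit tables flow through every stage (a
  header-only summary and empty BED are valid outputs); loci with zero
  ORFs or no available reference protein skip reconstruction but are still
  classified; unresolvable taxids count in denominators but satisfy no
  taxonomic predicate.

## Known limitations

* The built-in aligner reports one alignment per frame per chunk and has
  approximate e-values; it is a test harness, not a DIAMOND replacement.
* Reciprocal searching against real nr/RVDB is out of scope; the classifier
  consumes pre-computed tables.
* No intron modeling, no repeat masking, no splice-aware ORF stitching, no
  probabilistic EVE scoring.
* Terminal degradation events (within ~4 codons of an insert end) are
  fundamentally unrecoverable by local alignment and are excluded from the
  generator's stated world.
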