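Package: evescreen
Title: Discovery and Classification of Endogenous Viral Elements in Host Genomes
Version: 0.1.0
Authors@R:
    person("Paleo", "Screener", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for endogenous viral element (EVE) discovery
    in host genome assemblies. Splits genomes into fixed-size chunks for even
    translated homology searching, remaps chunk-local hits to contig
    coordinates, merges nearby hits into candidate loci, extracts locus
    sequences and open reading frames, reconstructs degraded viral proteins
    with a frameshift-aware protein-to-DNA aligner that quantifies stop
    codons, insertions, deletions and frameshifts, and classifies each locus
    into one of six categories from reciprocal-search evidence against viral
    and general protein databases using NCBI taxonomy lineages. Includes a
    built-in six-frame Smith-Waterman search engine for test-scale runs, a
    synthetic-data generator that plants degraded viral inserts with ground
    truth, and an end-to-end pipeline driver with per-stage outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
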