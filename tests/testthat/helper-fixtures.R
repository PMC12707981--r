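# Shared fixture builders. Everything is generated in code at test time.

random_hit_table <- function(n, n_queries = 5, n_subjects = 5,
                             subject_len = 1000) {
  qs <- paste0("q", sample.int(n_queries, n, replace = TRUE))
  ss <- paste0("s", sample.int(n_subjects, n, replace = TRUE))
  a <- sample.int(subject_len - 1L, n, replace = TRUE)
  b <- pmin(subject_len, a + sample.int(300L, n, replace = TRUE))
  minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
  hit_table(data.frame(
    qseqid = qs, sseqid = ss,
    pident = round(stats::runif(n, 20, 100), 1),
    length = b - a + 1L, mismatch = sample.int(50L, n, replace = TRUE),
    gapopen = sample(0:3, n, replace = TRUE),
    qstart = 1L, qend = 50L,
    sstart = ifelse(minus, b, a), send = ifelse(minus, a, b),
    evalue = 10^stats::runif(n, -40, -1),
    bitscore = round(stats::runif(n, 30, 300), 1),
    stitle = sample(c("gag polyprotein", "hypothetical", ""), n,
                    replace = TRUE),
    staxids = sample(c("9606", "11632;10239", ""), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

tiny_taxdump <- function(dir = withr::local_tempdir()) {
  mock_taxdump(dir)
  load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
}

# minimal evidence profile constructor for classifier tests
make_profile <- function(n_rvdb = 5L, n_nr = 5L, frac_rvdb_viral = NA,
                         frac_rvdb_euk = NA, frac_nr_viral = NA,
                         rvdb_families = character(0),
                         rvdb_kingdoms = character(0),
                         best_rvdb_title = "", all_titles = character(0)) {
  structure(list(locus_id = "L", n_rvdb = as.integer(n_rvdb),
                 n_nr = as.integer(n_nr),
                 frac_rvdb_viral = frac_rvdb_viral,
                 frac_rvdb_euk = frac_rvdb_euk,
                 frac_nr_viral = frac_nr_viral,
                 rvdb_families = rvdb_families,
                 rvdb_kingdoms = rvdb_kingdoms,
                 best_rvdb_title = best_rvdb_title,
                 all_titles = all_titles),
            class = "evidence_profile")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
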