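# Synthetic-world generator: determinism, planted truth, scenario forcing.

test_that("generate_proteins is seed-deterministic and length-bounded", {
  a <- generate_proteins(3, c(50, 60), seed = 7)
  b <- generate_proteins(3, c(50, 60), seed = 7)
  expect_identical(a, b)
  expect_true(all(nchar(a$seq) >= 50 & nchar(a$seq) <= 60))
  expect_equal(a$id, c("vp1", "vp2", "vp3"))
})

test_that("residue composition is roughly uniform", {
  p <- generate_proteins(20, c(500, 600), seed = 13)
  chars <- unlist(strsplit(p$seq, ""))
  n <- length(chars)
  expect_gte(n, 10000)
  freq <- table(chars) / n
  # each residue within +/- 3 sd of 1/20 under a binomial model
  sd3 <- 3 * sqrt((1 / 20) * (19 / 20) / n)
  expect_true(all(abs(freq - 1 / 20) <= sd3))
})

test_that("zero-event plants back-translate exactly and align cleanly", {
  prots <- generate_proteins(1, c(60, 60), seed = 17)
  g <- random_genome(1, 2000, seed = 18)
  ts <- plant_eves(g, prots, list(plant_spec("vp1", "contig1", 900L)),
                   seed = 19)
  tr <- ts$truth
  expect_equal(substring(ts$genome$seq, tr$start + 1, tr$end),
               tr$insert_seq)
  expect_equal(translate_frame(tr$insert_seq, 1), prots$seq[1])
  r <- quantify_changes(frameshift_align(prots[1, ], tr$insert_seq))
  expect_equal(r$n_stops + r$n_insertions + r$n_deletions +
                 r$n_frameshifts, 0L)
  expect_equal(r$pident, 100)
})

test_that("planted stop counts appear in the original-frame translation", {
  prots <- generate_proteins(5, c(90, 110), seed = 23)
  g <- random_genome(1, 5000, seed = 24)
  specs <- list(plant_spec("vp1", "contig1", 1000L, n_stops = 2L),
                plant_spec("vp2", "contig1", 3000L, strand = "-",
                           n_stops = 1L))
  ts <- plant_eves(g, prots, specs, seed = 25)
  for (i in 1:2) {
    tr <- ts$truth[i, ]
    ins <- if (tr$strand == "-") revcomp(tr$insert_seq) else tr$insert_seq
    pep <- translate_frame(ins, 1)
    expect_equal(lengths(regmatches(pep, gregexpr("*", pep,
                                                  fixed = TRUE))),
                 tr$n_stops)
  }
})

test_that("planted frameshifts change insert length by the planted amount", {
  prots <- generate_proteins(1, c(100, 100), seed = 29)
  g <- random_genome(1, 2000, seed = 30)
  ts <- plant_eves(g, prots,
                   list(plant_spec("vp1", "contig1", 500L,
                                   n_frameshifts = 1L)),
                   seed = 31)
  delta <- nchar(ts$truth$insert_seq) - 300L
  expect_true(delta %in% c(-2L, -1L, 1L, 2L))
})

test_that("plant_eves is byte-deterministic and truth intervals are exact", {
  prots <- generate_proteins(10, c(80, 100), seed = 37)
  g <- random_genome(2, 20000, seed = 38)
  specs <- lapply(1:10, function(k) {
    plant_spec(paste0("vp", k), paste0("contig", (k - 1) %% 2 + 1),
               as.integer(1500 * ((k - 1) %/% 2 + 1)),
               strand = c("+", "-")[k %% 2 + 1],
               n_stops = k %% 3, n_frameshifts = k %% 2,
               substitution_rate = 0.05)
  })
  ts1 <- plant_eves(g, prots, specs, seed = 39)
  ts2 <- plant_eves(g, prots, specs, seed = 39)
  expect_identical(ts1, ts2)
  for (i in seq_len(nrow(ts1$truth))) {
    tr <- ts1$truth[i, ]
    expect_equal(substring(ts1$genome$seq[ts1$genome$id == tr$contig],
                           tr$start + 1, tr$end), tr$insert_seq)
  }
})

test_that("overlapping or unsorted plant positions are rejected", {
  prots <- generate_proteins(2, c(80, 80), seed = 41)
  g <- random_genome(1, 5000, seed = 42)
  specs <- list(plant_spec("vp1", "contig1", 2000L),
                plant_spec("vp2", "contig1", 1000L))
  expect_error(plant_eves(g, prots, specs, seed = 43),
               "strictly increasing")
})

test_that("mock taxdump loads and carries the advertised lineages", {
  d <- withr::local_tempdir()
  mock_taxdump(d)
  db <- load_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
  expect_equal(tax_rank_name(db, 90009, "kingdom"), "bamfordvirae")
  expect_equal(tax_rank_name(db, 90001, "family"), "retroviridae")
  expect_true(tax_any_superkingdom(db, 90005L, "Viruses"))
  expect_true(tax_any_superkingdom(db, 10090L, "Eukaryota"))
})

test_that("every scenario's mock evidence forces its category", {
  d <- withr::local_tempdir()
  db <- tiny_taxdump(file.path(d, "tax"))
  scn <- c("retro", "host", "bamford", "transposon", "eve", "uncertain")
  ids <- paste0("L", seq_along(scn))
  tabs <- mock_reciprocal_tables(ids, scn, file.path(d, "r.tsv"),
                                 file.path(d, "n.tsv"))
  rvdb <- parse_tabular_hits(file.path(d, "r.tsv"))
  nr <- parse_tabular_hits(file.path(d, "n.tsv"))
  for (k in seq_along(ids)) {
    locus <- structure(list(
      locus_id = ids[k],
      rvdb_hits = rvdb[rvdb$qseqid == ids[k], , drop = FALSE],
      nr_hits = nr[nr$qseqid == ids[k], , drop = FALSE],
      forward_hits = hit_table()), class = "candidate_locus")
    class(locus$rvdb_hits) <- class(locus$nr_hits) <-
      c("hit_table", "data.frame")
    p <- build_evidence(locus, db)
    expect_equal(classify_locus(p)$category, scenario_category(scn[k]))
    # dual route: the independent oracle agrees on the same profile
    expect_equal(oracle_classify(p), scenario_category(scn[k]))
  }
})

test_that("simulate_dataset writes a complete, reloadable world", {
  d <- withr::local_tempdir()
  ts <- simulate_dataset(d, n_proteins = 4, contig_length = 20000,
                         n_plants = 4, seed = 5)
  expect_true(all(file.exists(file.path(
    d, c("genome.fna", "proteins.faa", "truth.tsv", "truth.bed",
         "taxdump/nodes.dmp", "taxdump/names.dmp")))))
  g <- read_fasta(file.path(d, "genome.fna"), "dna")
  expect_identical(g$seq, ts$genome$seq)
  tr <- utils::read.delim(file.path(d, "truth.tsv"))
  expect_equal(nrow(tr), 4L)
  expect_true(all(tr$end > tr$start))
})
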