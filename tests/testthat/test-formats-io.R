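# FASTA, tabular-hit and taxdump I/O.

test_that("read_fasta parses records, wraps, descriptions and gzip", {
  f <- withr::local_tempfile()
  writeLines(c(">a desc", "ACGT"), f)
  r <- read_fasta(f, "dna")
  expect_equal(r$id, "a")
  expect_equal(r$description, "a desc")
  expect_equal(r$seq, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "TTTT"), f)
  r <- read_fasta(f, "dna")
  expect_equal(nrow(r), 2L)
  expect_equal(r$seq[1], "ACGT")

  # lowercase input is uppercased
  writeLines(c(">a", "acgt"), f)
  expect_equal(read_fasta(f, "dna")$seq, "ACGT")

  # gzip detected from content, not extension
  g <- withr::local_tempfile(fileext = ".dat")
  con <- gzfile(g, "w")
  writeLines(c(">z", "GATTACA"), con)
  close(con)
  expect_equal(read_fasta(g, "dna")$seq, "GATTACA")
})

test_that("read_fasta error contract: empty file, illegal characters", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_error(read_fasta(f, "dna"), "no records")
  writeLines(c(">a", "ACGJ"), f)
  expect_error(read_fasta(f, "dna"), "'J' in record 'a' at position 4")
  # IUPAC ambiguity codes are fine
  writeLines(c(">a", "ACGTNRYSWKM"), f)
  expect_silent(read_fasta(f, "dna"))
})

test_that("FASTA round-trip is lossless over generated records", {
  set.seed(101)
  recs <- generate_proteins(100, c(10, 200), seed = 101)
  f <- withr::local_tempfile()
  write_fasta(recs, f)
  back <- read_fasta(f, "protein")
  expect_identical(back$id, recs$id)
  expect_identical(back$seq, recs$seq)
})

test_that("parse_tabular_hits derives strand and canonical coordinates", {
  f <- withr::local_tempfile()
  writeLines(paste("q1", "s1", "45.0", "100", "50", "2", "1", "100",
                   "500", "201", "1e-20", "120.5", "gag polyprotein",
                   "11632", sep = "\t"), f)
  h <- parse_tabular_hits(f)
  expect_equal(h$strand, "-")
  expect_equal(h$evalue, 1e-20)
  expect_equal(h$canon_start, 200L)
  expect_equal(h$canon_end, 500L)
  expect_equal(h$stitle, "gag polyprotein")
  expect_equal(split_staxids(h)[[1]], 11632L)

  writeLines(character(0), f)
  expect_equal(nrow(parse_tabular_hits(f)), 0L)
})

test_that("parse_tabular_hits error contract", {
  f <- withr::local_tempfile()
  writeLines(c("q1\ts1\t45.0", ""), f)
  expect_error(parse_tabular_hits(f), "line 1")
  writeLines(paste("q1", "s1", "xx", "100", "50", "2", "1", "100", "500",
                   "201", "1e-20", "120.5", sep = "\t"), f)
  expect_error(parse_tabular_hits(f), "pident")
})

test_that("tabular round-trip is lossless for randomized hits", {
  set.seed(7)
  h <- random_hit_table(1000)
  f <- withr::local_tempfile()
  write_tabular_hits(h, f)
  back <- parse_tabular_hits(f)
  expect_equal(as.data.frame(back), as.data.frame(h))
})

test_that("load_taxdump resolves lineages and filters name classes", {
  db <- tiny_taxdump()
  lin <- tax_lineage(db, 90001)  # species under Retroviridae
  expect_equal(lin$taxid[nrow(lin)], "1")
  expect_equal(tax_rank_name(db, 90001, "family"), "retroviridae")
  expect_equal(tax_rank_name(db, 90001, "superkingdom", lower = FALSE),
               "Viruses")
  expect_true(tax_any_superkingdom(db, c(9606L), "Eukaryota"))
  expect_false(tax_any_superkingdom(db, c(9606L), "Viruses"))
  # synonym rows in names.dmp are ignored: the scientific name survives
  expect_equal(tax_rank_name(db, 10239, "superkingdom", lower = FALSE),
               "Viruses")
  # unknown taxid: empty lineage, no predicate satisfied
  expect_equal(nrow(tax_lineage(db, 424242)), 0L)
  expect_false(tax_any_superkingdom(db, 424242L, "Viruses"))
})

test_that("load_taxdump rejects orphans", {
  d <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|", "5\t|\t4\t|\tspecies\t|"),
             file.path(d, "nodes.dmp"))
  writeLines("1\t|\troot\t|\t\t|\tscientific name\t|",
             file.path(d, "names.dmp"))
  expect_error(load_taxdump(file.path(d, "nodes.dmp"),
                            file.path(d, "names.dmp")),
               "absent parent")
})

test_that("random 500-node taxonomy: every lineage reaches the root", {
  set.seed(11)
  n <- 500L
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                         integer(1)))
  d <- withr::local_tempdir()
  writeLines(sprintf("%d\t|\t%d\t|\tspecies\t|", 1:n, parent),
             file.path(d, "nodes.dmp"))
  writeLines(sprintf("%d\t|\tnode%d\t|\t\t|\tscientific name\t|", 1:n, 1:n),
             file.path(d, "names.dmp"))
  db <- load_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
  for (t in sample.int(n, 50)) {
    lin <- tax_lineage(db, t)
    expect_lte(nrow(lin), n)
    expect_equal(lin$taxid[nrow(lin)], "1")
  }
})

test_that("write_bed follows the 0-based half-open convention", {
  hits <- hit_table(data.frame(
    qseqid = "q", sseqid = "c1", pident = 90, length = 50, mismatch = 5,
    gapopen = 0, qstart = 1, qend = 50, sstart = 101, send = 250,
    evalue = 1e-30, bitscore = 99.5, stitle = "", staxids = "",
    stringsAsFactors = FALSE))
  loci <- merge_hits_to_loci(hits)
  f <- withr::local_tempfile()
  write_bed(loci, f)
  expect_equal(readLines(f), "c1\t100\t250\tc1:100-250\t99.5\t+")
})

test_that("zero loci give an empty BED and a header-only summary", {
  fb <- withr::local_tempfile()
  fs <- withr::local_tempfile()
  write_bed(list(), fb)
  write_summary(list(), fs)
  expect_equal(length(readLines(fb)), 0L)
  expect_equal(length(readLines(fs)), 1L)
  expect_match(readLines(fs), "^locus_id\tcontig\t")
})
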