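# Evidence aggregation and the six-rule decision tree.

test_that("spec-style profiles classify as printed", {
  expect_equal(classify_locus(make_profile(
    rvdb_families = "retroviridae",
    all_titles = "gag-pol polyprotein"))$category, "likely-retro")

  expect_equal(classify_locus(make_profile(
    n_rvdb = 2, n_nr = 10))$category, "likely-host-protein")

  expect_equal(classify_locus(make_profile(
    n_rvdb = 5, n_nr = 5,
    rvdb_kingdoms = "bamfordvirae"))$category, "bamford-related")

  expect_equal(classify_locus(make_profile(
    frac_rvdb_euk = 0.9,
    best_rvdb_title = "transposase"))$category, "likely-transposon")

  expect_equal(classify_locus(make_profile(
    frac_rvdb_viral = 0.7, rvdb_families = "circoviridae",
    frac_nr_viral = 0.2))$category, "likely-eve")

  # empty profile: rule 2's n_rvdb == 0 clause fires first
  res <- classify_locus(make_profile(n_rvdb = 0, n_nr = 0))
  expect_equal(res$category, "likely-host-protein")
  expect_equal(res$rule, 2L)
})

test_that("rule order is strict: earlier rules preempt later ones", {
  # bamford evidence with zero RVDB hits is host, not bamford-related
  expect_equal(classify_locus(make_profile(
    n_rvdb = 0, n_nr = 5,
    rvdb_kingdoms = "bamfordvirae"))$category, "likely-host-protein")
  # retro beats bamford when both would fire
  expect_equal(classify_locus(make_profile(
    rvdb_families = "retroviridae", rvdb_kingdoms = "bamfordvirae",
    all_titles = "reverse transcriptase"))$category, "likely-retro")
})

test_that("boundary fractions do not fire strict-inequality rules", {
  # n_rvdb / n_nr exactly 0.30 is NOT '< 30%'
  expect_false(classify_locus(make_profile(
    n_rvdb = 3, n_nr = 10))$category == "likely-host-protein")
  # frac_rvdb_euk exactly 0.80 does not fire likely-transposon
  expect_equal(classify_locus(make_profile(
    frac_rvdb_euk = 0.80,
    best_rvdb_title = "transposase"))$category, "uncertain")
  # frac_rvdb_viral exactly 0.60 does not fire likely-eve
  expect_equal(classify_locus(make_profile(
    frac_rvdb_viral = 0.60))$category, "uncertain")
  # frac_nr_viral exactly 0.50 does not fire likely-eve
  expect_equal(classify_locus(make_profile(
    frac_nr_viral = 0.50))$category, "uncertain")
})

test_that("short retro keywords use word boundaries by default", {
  # 'polymerase' must not satisfy the title clause via bare 'pol'
  expect_equal(classify_locus(make_profile(
    rvdb_families = "retroviridae",
    all_titles = "dna polymerase"))$category, "uncertain")
  expect_equal(classify_locus(make_profile(
    rvdb_families = "retroviridae",
    all_titles = "pol protein"))$category, "likely-retro")
  # substring mode restores the printed literal reading
  expect_equal(classify_locus(make_profile(
    rvdb_families = "retroviridae", all_titles = "dna polymerase"),
    eve_ruleset(substring_keywords = TRUE))$category, "likely-retro")
})

test_that("excluded families veto the RVDB clause but not the nr clause", {
  expect_equal(classify_locus(make_profile(
    frac_rvdb_viral = 0.9,
    rvdb_families = "baculoviridae"))$category, "uncertain")
  expect_equal(classify_locus(make_profile(
    frac_rvdb_viral = 0.9, rvdb_families = "baculoviridae",
    frac_nr_viral = 0.6))$category, "likely-eve")
})

test_that("build_evidence tallies a mixed 12-hit fixture by hand counts", {
  db <- tiny_taxdump()
  mk <- function(qs, taxids, titles) {
    hit_table(data.frame(
      qseqid = "L", sseqid = paste0("s", seq_along(taxids)), pident = 50,
      length = 100, mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
      sstart = 1, send = 100, evalue = 1e-10,
      bitscore = 100 - seq_along(taxids), stitle = titles,
      staxids = taxids, stringsAsFactors = FALSE))
  }
  locus <- structure(list(
    locus_id = "L",
    # 6 RVDB: 3 viral (retro, circo, bamford), 2 euk, 1 unresolvable
    rvdb_hits = mk("L", c("90001", "90005", "90009", "9606", "10090",
                          "555555"),
                   c("gag polyprotein", "capsid", "mcp", "transposase",
                     "hypothetical", "unknown")),
    # 6 nr: 2 viral, 3 euk, 1 multi-taxid (viral wins via 'any')
    nr_hits = mk("L", c("90003", "90004", "9606", "9606", "10090",
                        "9606;90005"),
                 c("n1", "n2", "n3", "n4", "n5", "n6")),
    forward_hits = hit_table()), class = "candidate_locus")
  p <- build_evidence(locus, db)
  expect_equal(p$n_rvdb, 6L)
  expect_equal(p$n_nr, 6L)
  expect_equal(p$frac_rvdb_viral, 3 / 6)
  expect_equal(p$frac_rvdb_euk, 2 / 6)
  expect_equal(p$frac_nr_viral, 3 / 6)
  expect_setequal(p$rvdb_families, c("retroviridae", "circoviridae"))
  expect_true("bamfordvirae" %in% p$rvdb_kingdoms)
  expect_equal(p$best_rvdb_title, "gag polyprotein")
})

test_that("empty evidence sides have undefined (NA) fractions", {
  db <- tiny_taxdump()
  locus <- structure(list(locus_id = "L", rvdb_hits = hit_table(),
                          nr_hits = hit_table(),
                          forward_hits = hit_table()),
                     class = "candidate_locus")
  p <- build_evidence(locus, db)
  expect_equal(p$n_rvdb, 0L)
  expect_true(is.na(p$frac_rvdb_viral))
  expect_true(is.na(p$frac_rvdb_euk))
  expect_true(is.na(p$frac_nr_viral))
})

test_that("classification is independent of hit input order", {
  db <- tiny_taxdump()
  set.seed(79)
  base <- hit_table(data.frame(
    qseqid = "L", sseqid = paste0("s", 1:6), pident = 50, length = 100,
    mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
    send = 100, evalue = 1e-10, bitscore = c(90, 80, 70, 60, 50, 40),
    stitle = c("capsid", "x", "y", "transposase", "z", "w"),
    staxids = c("90005", "90005", "90005", "9606", "90005", "90006"),
    stringsAsFactors = FALSE))
  res <- lapply(1:5, function(k) {
    perm <- base[sample.int(nrow(base)), , drop = FALSE]
    class(perm) <- c("hit_table", "data.frame")
    locus <- structure(list(locus_id = "L", rvdb_hits = perm,
                            nr_hits = perm, forward_hits = hit_table()),
                       class = "candidate_locus")
    classify_locus(build_evidence(locus, db))$category
  })
  expect_length(unique(unlist(res)), 1L)
})

test_that("every generable profile gets exactly one of the six labels", {
  set.seed(83)
  for (k in 1:500) {
    nr <- sample(0:10, 1)
    nv <- sample(0:10, 1)
    p <- make_profile(
      n_rvdb = nr, n_nr = nv,
      frac_rvdb_viral = if (nr > 0) stats::runif(1) else NA,
      frac_rvdb_euk = if (nr > 0) stats::runif(1) else NA,
      frac_nr_viral = if (nv > 0) stats::runif(1) else NA,
      rvdb_families = sample(c("retroviridae", "polyomaviridae", "x"),
                             sample(0:2, 1)),
      rvdb_kingdoms = sample(c("bamfordvirae", "metazoa"), sample(0:1, 1)),
      best_rvdb_title = sample(c("", "gag", "transposase"), 1),
      all_titles = sample(c("gag", "kinase", "misc"), sample(0:2, 1)))
    res <- classify_locus(p)
    expect_true(res$category %in% c("likely-retro", "likely-host-protein",
                                    "bamford-related", "likely-transposon",
                                    "likely-eve", "uncertain"))
    expect_equal(res$category, oracle_classify(p))
  }
})
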