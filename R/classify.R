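# Reciprocal-evidence aggregation and the six-category decision tree.
#
# Rules are evaluated strictly in order; the first that fires wins:
#   1 likely-retro        retro/caulimo RVDB family AND a retroviral protein
#                         name among the hit titles
#   2 likely-host-protein no RVDB hits, OR RVDB hits < 30% of the NR hit
#                         count, OR a host-gene keyword in any title
#   3 bamford-related     any RVDB hit whose kingdom contains "bamford"
#   4 likely-transposon   > 80% of RVDB hits eukaryotic AND the best RVDB
#                         title names a transposable-element protein
#   5 likely-eve          > 60% of RVDB hits viral with no excluded family,
#                         OR > 50% of NR hits viral
#   6 uncertain           otherwise
#
# Short keywords (pol, env, gag, pro, rt-in) are matched with word
# boundaries — a bare substring "pol" fires on "polymerase" — unless
# `substring_keywords = TRUE` restores literal substring matching.

CATEGORIES <- c("likely-retro", "likely-host-protein", "bamford-related",
                "likely-transposon", "likely-eve", "uncertain")

#' Classification rule set
#'
#' All string predicates operate on lowercased titles / rank names.
#'
#' @param substring_keywords if TRUE, short keywords are matched as bare
#'   substrings instead of word-bounded tokens.
#' @param rvdb_vs_nr_min_ratio rule 2 ratio threshold (default 0.30).
#' @param transposon_euk_frac rule 4 threshold (default 0.80).
#' @param eve_rvdb_viral_frac,eve_nr_viral_frac rule 5 thresholds
#'   (defaults 0.60 / 0.50).
#' @return a list of class `eve_ruleset`.
#' @export
eve_ruleset <- function(substring_keywords = FALSE,
                        rvdb_vs_nr_min_ratio = 0.30,
                        transposon_euk_frac = 0.80,
                        eve_rvdb_viral_frac = 0.60,
                        eve_nr_viral_frac = 0.50) {
  stopifnot(rvdb_vs_nr_min_ratio > 0, rvdb_vs_nr_min_ratio < 1,
            transposon_euk_frac > 0, transposon_euk_frac < 1,
            eve_rvdb_viral_frac > 0, eve_rvdb_viral_frac < 1,
            eve_nr_viral_frac > 0, eve_nr_viral_frac < 1)
  wb <- function(x) if (substring_keywords) x else paste0("\\b", x, "\\b")
  structure(list(
    retro_family_substrings = c("retro", "caulimo"),
    retro_title_regex = paste(
      c(wb("gag"), wb("pol"), wb("env"), "reverse", "pro[-]?pol",
        "protease", wb("pro"), wb("rt[-]?in")),
      collapse = "|"),
    host_title_substrings = c("ubiquitin", "zinc", "nynrin", "kinase"),
    rvdb_vs_nr_min_ratio = rvdb_vs_nr_min_ratio,
    bamford_kingdom_substring = "bamford",
    transposon_euk_frac = transposon_euk_frac,
    transposon_title_regex = paste(
      c(wb("pol"), "transpos", wb("gag"), "group specific antigen"),
      collapse = "|"),
    eve_rvdb_viral_frac = eve_rvdb_viral_frac,
    eve_excluded_family_substrings = c("baculo", "poly", "fabace", "allohe"),
    eve_nr_viral_frac = eve_nr_viral_frac),
    class = "eve_ruleset")
}

#' Build the evidence profile of a locus
#'
#' A hit counts as viral (eukaryotic) if ANY of its taxids has superkingdom
#' Viruses (Eukaryota); family and kingdom names are collected from the same
#' lineages, lowercased. Hits with no resolvable taxid stay in the
#' denominators but satisfy no taxonomic predicate. Fractions over an empty
#' table are NA (undefined), never 0.
#'
#' @param locus a `candidate_locus` with `rvdb_hits` / `nr_hits` attached
#'   (post [filter_and_rank()]).
#' @param taxdb a `taxonomy_db`.
#' @return a list of class `evidence_profile`.
#' @export
build_evidence <- function(locus, taxdb) {
  profile_side <- function(hits) {
    n <- nrow(hits)
    if (n == 0L) {
      return(list(n = 0L, frac_viral = NA_real_, frac_euk = NA_real_,
                  families = character(0), kingdoms = character(0),
                  best_title = ""))
    }
    taxids <- split_staxids(hits)
    viral <- vapply(taxids, tax_any_superkingdom, logical(1), db = taxdb,
                    superkingdom = "Viruses")
    euk <- vapply(taxids, tax_any_superkingdom, logical(1), db = taxdb,
                  superkingdom = "Eukaryota")
    fams <- unique(unlist(lapply(taxids, function(tt) {
      vapply(tt, function(t) tax_rank_name(taxdb, t, "family"),
             character(1))
    })))
    kings <- unique(unlist(lapply(taxids, function(tt) {
      vapply(tt, function(t) tax_rank_name(taxdb, t, "kingdom"),
             character(1))
    })))
    best <- hits[hit_order(hits)[1], , drop = FALSE]
    list(n = n, frac_viral = mean(viral), frac_euk = mean(euk),
         families = sort(fams[!is.na(fams)]),
         kingdoms = sort(kings[!is.na(kings)]),
         best_title = tolower(best$stitle))
  }
  rvdb <- profile_side(locus$rvdb_hits)
  nr <- profile_side(locus$nr_hits)
  titles <- tolower(c(locus$rvdb_hits$stitle, locus$nr_hits$stitle))
  structure(list(
    locus_id = locus$locus_id,
    n_rvdb = rvdb$n, n_nr = nr$n,
    frac_rvdb_viral = rvdb$frac_viral, frac_rvdb_euk = rvdb$frac_euk,
    frac_nr_viral = nr$frac_viral,
    rvdb_families = rvdb$families, rvdb_kingdoms = rvdb$kingdoms,
    best_rvdb_title = rvdb$best_title,
    all_titles = sort(unique(titles[nzchar(titles)]))),
    class = "evidence_profile")
}

any_contains <- function(strings, substrings) {
  if (!length(strings)) return(FALSE)
  any(vapply(substrings, function(s) any(grepl(s, strings, fixed = TRUE)),
             logical(1)))
}

#' Classify a locus from its evidence profile
#'
#' @param profile an `evidence_profile` (see [build_evidence()]).
#' @param rules an [eve_ruleset()].
#' @return a list with `category` (one of the six labels) and `rule` (the
#'   1-based index of the rule that fired).
#' @export
classify_locus <- function(profile, rules = eve_ruleset()) {
  p <- profile
  # 1 likely-retro
  if (any_contains(p$rvdb_families, rules$retro_family_substrings) &&
      length(p$all_titles) &&
      any(grepl(rules$retro_title_regex, p$all_titles))) {
    return(list(category = "likely-retro", rule = 1L))
  }
  # 2 likely-host-protein
  if (p$n_rvdb == 0L ||
      (p$n_nr > 0L && p$n_rvdb < rules$rvdb_vs_nr_min_ratio * p$n_nr) ||
      any_contains(p$all_titles, rules$host_title_substrings)) {
    return(list(category = "likely-host-protein", rule = 2L))
  }
  # 3 bamford-related
  if (any_contains(p$rvdb_kingdoms, rules$bamford_kingdom_substring)) {
    return(list(category = "bamford-related", rule = 3L))
  }
  # 4 likely-transposon
  if (!is.na(p$frac_rvdb_euk) &&
      p$frac_rvdb_euk > rules$transposon_euk_frac &&
      nzchar(p$best_rvdb_title) &&
      grepl(rules$transposon_title_regex, p$best_rvdb_title)) {
    return(list(category = "likely-transposon", rule = 4L))
  }
  # 5 likely-eve
  rvdb_clause <- !is.na(p$frac_rvdb_viral) &&
    p$frac_rvdb_viral > rules$eve_rvdb_viral_frac &&
    !any_contains(p$rvdb_families, rules$eve_excluded_family_substrings)
  nr_clause <- !is.na(p$frac_nr_viral) &&
    p$frac_nr_viral > rules$eve_nr_viral_frac
  if (rvdb_clause || nr_clause) {
    return(list(category = "likely-eve", rule = 5L))
  }
  list(category = "uncertain", rule = 6L)
}

#' Classify a list of loci
#'
#' Attaches `category` and `fired_rule` to each locus.
#'
#' @param loci list of `candidate_locus` objects with reciprocal hits
#'   attached.
#' @param taxdb a `taxonomy_db`.
#' @param rules an [eve_ruleset()].
#' @return the updated list of loci.
#' @export
classify_loci <- function(loci, taxdb, rules = eve_ruleset()) {
  lapply(loci, function(locus) {
    res <- classify_locus(build_evidence(locus, taxdb), rules)
    locus$category <- res$category
    locus$fired_rule <- res$rule
    locus
  })
}
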