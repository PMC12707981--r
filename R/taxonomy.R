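# NCBI taxdump loading and lineage queries.
#
# The taxonomy database is a list with named vectors keyed by taxid (as
# character): parent, rank, name. Taxid 1 is the root and is its own parent,
# as in the real nodes.dmp.

#' Load an NCBI-style taxdump
#'
#' Reads `nodes.dmp` (taxid | parent | rank | ...) and `names.dmp`
#' (taxid | name | unique name | name class |), keeping only
#' "scientific name" rows from the latter. Every taxid must resolve to the
#' root (taxid 1); orphans and cycles are errors.
#'
#' @param nodes_path path to nodes.dmp.
#' @param names_path path to names.dmp.
#' @return an object of class `taxonomy_db` with elements `parent`, `rank`,
#'   `name` (named character vectors keyed by taxid).
#' @export
load_taxdump <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  nodes <- parse_dmp(nodes_path)
  taxid <- vapply(nodes, `[`, character(1), 1L)
  parent <- vapply(nodes, `[`, character(1), 2L)
  rank <- vapply(nodes, `[`, character(1), 3L)
  if (anyDuplicated(taxid)) {
    stop("duplicate taxids in nodes.dmp: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  }
  names(parent) <- taxid
  names(rank) <- taxid

  orphans <- setdiff(parent, taxid)
  if (length(orphans)) {
    stop("nodes.dmp references absent parent taxid(s): ",
         paste(sort(orphans), collapse = ", "))
  }

  names_rows <- parse_dmp(names_path)
  cls <- vapply(names_rows, function(f) if (length(f) >= 4) f[4] else "",
                character(1))
  sci <- names_rows[cls == "scientific name"]
  nm <- vapply(sci, `[`, character(1), 2L)
  names(nm) <- vapply(sci, `[`, character(1), 1L)

  db <- structure(list(parent = parent, rank = rank, name = nm),
                  class = "taxonomy_db")

  # Every node must reach the root without cycling; depth is bounded by the
  # node count, so a longer walk implies a cycle.
  limit <- length(taxid) + 1L
  for (t in taxid) {
    cur <- t
    steps <- 0L
    while (cur != "1") {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > limit) stop("cycle in taxonomy at taxid ", t)
    }
  }
  db
}

#' Lineage of a taxid, root last
#'
#' @param db a `taxonomy_db`.
#' @param taxid integer or character taxid.
#' @return data.frame with columns `taxid`, `rank`, `name`, from the query
#'   taxid up to the root; zero rows for an unknown taxid.
#' @export
tax_lineage <- function(db, taxid) {
  cur <- as.character(taxid)
  if (!cur %in% names(db$parent)) {
    return(data.frame(taxid = character(), rank = character(),
                      name = character(), stringsAsFactors = FALSE))
  }
  chain <- character(0)
  repeat {
    chain <- c(chain, cur)
    if (cur == "1") break
    cur <- db$parent[[cur]]
  }
  data.frame(taxid = chain,
             rank = unname(db$rank[chain]),
             name = unname(ifelse(is.na(db$name[chain]), "",
                                  db$name[chain])),
             stringsAsFactors = FALSE)
}

#' Name of a given rank in a taxid's lineage
#'
#' @param db a `taxonomy_db`.
#' @param taxid integer or character taxid.
#' @param rank rank label, e.g. "superkingdom", "kingdom", "family".
#' @return the scientific name at that rank (lowercased if `lower = TRUE`),
#'   or `NA_character_` if the rank is absent or the taxid unknown.
#' @param lower lowercase the returned name.
#' @export
tax_rank_name <- function(db, taxid, rank, lower = TRUE) {
  lin <- tax_lineage(db, taxid)
  hit <- lin$name[lin$rank == rank]
  if (!length(hit) || !nzchar(hit[1])) return(NA_character_)
  if (lower) tolower(hit[1]) else hit[1]
}

#' Does any taxid descend from a given superkingdom?
#'
#' @param db a `taxonomy_db`.
#' @param taxids integer vector (possibly empty).
#' @param superkingdom name to test, e.g. "Viruses" or "Eukaryota".
#' @return TRUE if any resolvable taxid has that superkingdom. Unresolvable
#'   taxids satisfy no predicate.
#' @export
tax_any_superkingdom <- function(db, taxids, superkingdom) {
  target <- tolower(superkingdom)
  for (t in taxids) {
    nm <- tax_rank_name(db, t, "superkingdom")
    if (!is.na(nm) && nm == target) return(TRUE)
  }
  FALSE
}
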