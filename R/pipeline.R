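# End-to-end orchestration: chunk -> forward search -> filter/cap -> remap ->
# merge -> extract -> ORFs -> reciprocal evidence -> reconstruct -> classify
# -> outputs. Every stage persists its artifacts under the output directory
# so a run can be stopped after any stage and resumed.

PIPELINE_STAGES <- c("chunk", "search", "filter", "merge", "extract",
                     "orfs", "reciprocal", "reconstruct", "classify",
                     "write")

CONFIG_DEFAULTS <- list(
  query_fasta = NULL,            # mandatory
  genome_list = NULL,            # mandatory: character vector of FASTA paths
  chunk_size = 50000L,
  per_chunk_top_hits = 1000L,
  evalue_max = 1e-5,
  per_query_top_hits = 10L,
  merge_distance = 1000L,
  flank = 0L,
  min_orf_aa = 50L,
  orf_mode = "stop_to_stop",
  engine = "builtin",            # builtin | precomputed | external
  forward_hits = NULL,           # engine = precomputed: chunk-local hits TSV
  reciprocal_mode = "precomputed",  # precomputed | none
  rvdb_hits = NULL,
  nr_hits = NULL,
  taxdump_dir = NULL,
  external_binary = "diamond",
  external_db = NULL,
  matrix = "BLOSUM62",
  gap_open = 11,
  gap_extend = 1,
  min_raw_score = 40,
  fs_gap_open = 12,
  fs_gap_extend = 2,
  frameshift_penalty = 20,
  stop_match_score = -15,
  coverage_floor = 0.8,
  seed = 1L,
  output_dir = NULL)             # mandatory

#' Validate and resolve a pipeline configuration
#'
#' Accepts a JSON file path or a named list. Unknown keys are rejected (with
#' a closest-match suggestion); missing keys are filled with the defaults in
#' `CONFIG_DEFAULTS`; mandatory keys (`query_fasta`, `genome_list`,
#' `output_dir`) and basic type/range constraints are enforced.
#'
#' @param config path to a JSON config file, or a named list.
#' @return the resolved configuration list, of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    txt <- paste(readLines(config), collapse = "\n")
    config <- if (nzchar(trimws(txt))) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      list()
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    sug <- vapply(unknown, function(u) {
      d <- utils::adist(u, names(CONFIG_DEFAULTS))
      names(CONFIG_DEFAULTS)[which.min(d)]
    }, character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, sug),
               collapse = ", "))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, config)
  mandatory <- c("query_fasta", "genome_list", "output_dir")
  missing <- mandatory[vapply(cfg[mandatory], is.null, logical(1))]
  if (length(missing)) {
    stop("mandatory config key(s) missing: ", paste(missing, collapse = ", "))
  }
  if (cfg$chunk_size < 1) stop("chunk_size must be >= 1")
  if (cfg$merge_distance < 0) stop("merge_distance must be >= 0")
  if (cfg$min_orf_aa < 1) stop("min_orf_aa must be >= 1")
  if (!cfg$engine %in% c("builtin", "precomputed", "external")) {
    stop("engine must be builtin, precomputed or external")
  }
  if (!cfg$orf_mode %in% c("stop_to_stop", "atg_to_stop")) {
    stop("orf_mode must be stop_to_stop or atg_to_stop")
  }
  if (!cfg$reciprocal_mode %in% c("precomputed", "none")) {
    stop("reciprocal_mode must be precomputed or none")
  }
  if (cfg$engine == "precomputed" && is.null(cfg$forward_hits)) {
    stop("engine = precomputed requires forward_hits")
  }
  if (cfg$engine == "external" &&
      !nzchar(Sys.which(cfg$external_binary))) {
    stop("engine = external but binary '", cfg$external_binary,
         "' not found on PATH; use engine = builtin or precomputed")
  }
  if (cfg$reciprocal_mode == "precomputed" &&
      (is.null(cfg$rvdb_hits) || is.null(cfg$nr_hits) ||
       is.null(cfg$taxdump_dir))) {
    stop("reciprocal_mode = precomputed requires rvdb_hits, nr_hits and ",
         "taxdump_dir")
  }
  cfg$chunk_size <- as.integer(cfg$chunk_size)
  cfg$per_chunk_top_hits <- as.integer(cfg$per_chunk_top_hits)
  cfg$per_query_top_hits <- as.integer(cfg$per_query_top_hits)
  cfg$merge_distance <- as.integer(cfg$merge_distance)
  cfg$flank <- as.integer(cfg$flank)
  cfg$min_orf_aa <- as.integer(cfg$min_orf_aa)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Dump a resolved configuration to JSON
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the discovery pipeline end to end
#'
#' Stages run in a fixed order; each persists its outputs under
#' `cfg$output_dir` (chunks.fna, forward_hits.tsv, forward_filtered.tsv,
#' loci.bed, candidate_cdna.fna, candidate_peptides.faa,
#' reconstruction.tsv, classification.tsv, summary.tsv, manifest.json).
#' `stop_after` halts after the named stage; `resume = TRUE` reloads
#' completed stages from the manifest and continues.
#'
#' @param config a config path or list (see [validate_config()]).
#' @param stop_after optional stage name from `PIPELINE_STAGES`.
#' @param resume continue a previous partial run in the same directory.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the final `loci`, `truthy` artifacts paths
#'   and the manifest.
#' @export
run_pipeline <- function(config, stop_after = NULL, resume = FALSE,
                         quiet = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  if (!is.null(stop_after) && !stop_after %in% PIPELINE_STAGES) {
    stop("unknown stage: ", stop_after)
  }
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  state_path <- file.path(out, "state")
  dir.create(state_path, showWarnings = FALSE)

  done <- character(0)
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::fromJSON(manifest_path)
    done <- prev$stages_done
  }
  set.seed(cfg$seed)

  sp <- search_params(evalue_max = cfg$evalue_max,
                      per_query_top_hits = cfg$per_query_top_hits,
                      matrix = cfg$matrix, gap_open = cfg$gap_open,
                      gap_extend = cfg$gap_extend,
                      min_raw_score = cfg$min_raw_score)
  cp <- chunk_params(cfg$chunk_size, cfg$per_chunk_top_hits)
  mp <- merge_params(cfg$merge_distance, cfg$flank)
  rp <- reconstruct_params(matrix = cfg$matrix, gap_open = cfg$fs_gap_open,
                           gap_extend = cfg$fs_gap_extend,
                           frameshift_penalty = cfg$frameshift_penalty,
                           stop_match_score = cfg$stop_match_score,
                           coverage_floor = cfg$coverage_floor)

  counts <- list()
  timings <- list()
  run_stage <- function(stage, fun) {
    if (stage %in% done) {
      stage_log(quiet, stage, "already done (resume)")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    done <<- c(done, stage)
    write_manifest()
  }
  write_manifest <- function() {
    inputs <- c(cfg$query_fasta, cfg$genome_list)
    manifest <- list(
      config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
      stages_done = done,
      counts = counts,
      timings_s = timings,
      input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      package_version = as.character(utils::packageVersion("evescreen")))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  halted <- function(stage) {
    !is.null(stop_after) && stage == stop_after
  }

  # lazily loaded shared artifacts
  genome <- NULL
  proteins <- NULL
  load_genome <- function() {
    if (is.null(genome)) {
      genome <<- do.call(rbind, lapply(cfg$genome_list, read_fasta,
                                       moltype = "dna"))
      class(genome) <- c("seq_records", "data.frame")
    }
    genome
  }
  load_proteins <- function() {
    if (is.null(proteins)) {
      proteins <<- read_fasta(cfg$query_fasta, moltype = "protein")
    }
    proteins
  }
  chunks_of <- function() {
    chunk_genome(load_genome(), cp)
  }

  # --- chunk ---
  run_stage("chunk", function() {
    chunks <- chunks_of()
    write_chunk_fasta(chunks, file.path(out, "chunks.fna"))
    counts$chunks <<- nrow(chunks)
    stage_log(quiet, "chunk", "%d chunks of <= %d bp", nrow(chunks),
              cfg$chunk_size)
  })
  if (halted("chunk")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  # --- forward search (chunk-local hits) ---
  fwd_raw_path <- file.path(out, "forward_hits.tsv")
  run_stage("search", function() {
    hits <- switch(cfg$engine,
      builtin = builtin_forward_search(load_proteins(), chunks_of(), sp),
      precomputed = parse_tabular_hits(cfg$forward_hits),
      external = run_external_search(file.path(out, "chunks.fna"),
                                     cfg$external_db, sp, "forward",
                                     binary = cfg$external_binary,
                                     log_file = file.path(out, "search.log")))
    write_tabular_hits(hits, fwd_raw_path)
    counts$forward_hits_raw <<- nrow(hits)
    stage_log(quiet, "search", "%d raw forward hits (engine=%s)",
              nrow(hits), cfg$engine)
  })
  if (halted("search")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  # --- e-value filter + per-query cap, then per-chunk cap, then remap ---
  fwd_path <- file.path(out, "forward_filtered.tsv")
  run_stage("filter", function() {
    hits <- parse_tabular_hits(fwd_raw_path)
    hits <- filter_and_rank(hits, sp)
    hits <- cap_hits_per_chunk(hits, cp)
    hits <- remap_hits(hits, chunks_of())
    write_tabular_hits(hits, fwd_path)
    counts$forward_hits_filtered <<- nrow(hits)
    stage_log(quiet, "filter", "%d hits after filter/cap/remap", nrow(hits))
  })
  if (halted("filter")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  # --- merge into loci ---
  run_stage("merge", function() {
    loci <- merge_hits_to_loci(parse_tabular_hits(fwd_path), mp)
    write_bed(loci, file.path(out, "loci.bed"))
    counts$loci <<- length(loci)
    stage_log(quiet, "merge", "%d candidate loci", length(loci))
  })
  if (halted("merge")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  rebuild_loci <- function() {
    loci <- merge_hits_to_loci(parse_tabular_hits(fwd_path), mp)
    lapply(loci, extract_locus_sequence, genome = load_genome(),
           params = mp)
  }

  # --- extract sequences ---
  run_stage("extract", function() {
    loci <- rebuild_loci()
    write_fasta(seq_records(
      id = vapply(loci, `[[`, character(1), "locus_id"),
      seq = vapply(loci, `[[`, character(1), "seq"),
      moltype = "dna"),
      file.path(out, "candidate_cdna.fna"))
    stage_log(quiet, "extract", "%d locus sequences", length(loci))
  })
  if (halted("extract")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  loci <- rebuild_loci()

  # --- ORFs ---
  run_stage("orfs", function() {
    ids <- character(0)
    peps <- character(0)
    for (k in seq_along(loci)) {
      orfs <- find_orfs(loci[[k]]$seq, cfg$min_orf_aa, cfg$orf_mode)
      loci[[k]]$orfs <<- orfs
      if (nrow(orfs)) {
        ids <- c(ids, sprintf("%s|orf%d|frame%+d", loci[[k]]$locus_id,
                              seq_len(nrow(orfs)), orfs$frame))
        peps <- c(peps, orfs$peptide)
      }
    }
    if (length(ids)) {
      write_fasta(seq_records(id = ids, seq = peps, moltype = "protein"),
                  file.path(out, "candidate_peptides.faa"))
    } else {
      writeLines(character(0), file.path(out, "candidate_peptides.faa"))
    }
    counts$orfs <<- length(ids)
    stage_log(quiet, "orfs", "%d ORFs >= %d aa", length(ids),
              cfg$min_orf_aa)
  })
  if (halted("orfs")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }
  # re-attach ORFs when the orfs stage was skipped on resume
  if (length(loci) && is.null(loci[[1]]$orfs)) {
    for (k in seq_along(loci)) {
      loci[[k]]$orfs <- find_orfs(loci[[k]]$seq, cfg$min_orf_aa,
                                  cfg$orf_mode)
    }
  }

  # --- reciprocal evidence ---
  run_stage("reciprocal", function() {
    if (cfg$reciprocal_mode == "none") {
      stage_log(quiet, "reciprocal", "skipped (mode=none)")
      return(invisible(NULL))
    }
    counts$rvdb_hits <<- nrow(parse_tabular_hits(cfg$rvdb_hits))
    counts$nr_hits <<- nrow(parse_tabular_hits(cfg$nr_hits))
    stage_log(quiet, "reciprocal", "%d RVDB / %d nr hits",
              counts$rvdb_hits, counts$nr_hits)
  })
  if (cfg$reciprocal_mode == "precomputed") {
    rvdb <- filter_and_rank(parse_tabular_hits(cfg$rvdb_hits), sp)
    nr <- filter_and_rank(parse_tabular_hits(cfg$nr_hits), sp)
    for (k in seq_along(loci)) {
      pick <- function(h) {
        sub <- h[h$qseqid == loci[[k]]$locus_id, , drop = FALSE]
        rownames(sub) <- NULL
        class(sub) <- c("hit_table", "data.frame")
        sub
      }
      loci[[k]]$rvdb_hits <- pick(rvdb)
      loci[[k]]$nr_hits <- pick(nr)
    }
  }
  if (halted("reciprocal")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }

  # --- reconstruction ---
  run_stage("reconstruct", function() {
    prots <- load_proteins()
    rows <- list()
    rec_ids <- character(0)
    rec_seqs <- character(0)
    for (k in seq_along(loci)) {
      ref <- choose_reference_protein(loci[[k]], prots)
      if (is.null(ref)) next
      loci[[k]] <<- reconstruct_locus(loci[[k]], ref, rp)
      rec <- loci[[k]]$reconstruction
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = rec$locus_id, protein_id = rec$protein_id,
        strand = rec$strand, raw_score = rec$raw_score,
        n_stops = rec$n_stops, n_insertions = rec$n_insertions,
        n_deletions = rec$n_deletions, n_frameshifts = rec$n_frameshifts,
        pident = round(rec$pident, 2),
        protein_coverage = round(rec$protein_coverage, 4),
        intact = rec$intact, stringsAsFactors = FALSE)
      rec_ids <- c(rec_ids, sprintf("%s|%s", rec$locus_id, rec$protein_id))
      rec_seqs <- c(rec_seqs,
                    loci[[k]]$reconstruction_alignment$reconstructed_peptide)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus_id = character(0))
    utils::write.table(tab, file.path(out, "reconstruction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(rec_ids)) {
      write_fasta(seq_records(id = rec_ids, seq = rec_seqs,
                              moltype = "protein"),
                  file.path(out, "reconstructed_peptides.faa"))
    }
    counts$reconstructed <<- length(rec_ids)
    stage_log(quiet, "reconstruct", "%d loci reconstructed",
              length(rec_ids))
  })
  if (halted("reconstruct")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }
  if (length(loci) && is.null(loci[[1]]$reconstruction)) {
    prots <- load_proteins()
    for (k in seq_along(loci)) {
      ref <- choose_reference_protein(loci[[k]], prots)
      if (!is.null(ref)) loci[[k]] <- reconstruct_locus(loci[[k]], ref, rp)
    }
  }

  # --- classification ---
  run_stage("classify", function() {
    if (cfg$reciprocal_mode == "none") {
      stage_log(quiet, "classify", "skipped (no reciprocal evidence)")
      return(invisible(NULL))
    }
    taxdb <- load_taxdump(file.path(cfg$taxdump_dir, "nodes.dmp"),
                          file.path(cfg$taxdump_dir, "names.dmp"))
    loci <<- classify_loci(loci, taxdb)
    tab <- do.call(rbind, lapply(loci, function(l) {
      data.frame(locus_id = l$locus_id, category = l$category,
                 fired_rule = l$fired_rule, stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, file.path(out, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$classified <<- length(loci)
    stage_log(quiet, "classify", "%d loci classified", length(loci))
  })
  if (halted("classify")) { write_manifest(); return(invisible(list(manifest = manifest_path))) }
  if (cfg$reciprocal_mode == "precomputed" && length(loci) &&
      is.na(loci[[1]]$category)) {
    taxdb <- load_taxdump(file.path(cfg$taxdump_dir, "nodes.dmp"),
                          file.path(cfg$taxdump_dir, "names.dmp"))
    loci <- classify_loci(loci, taxdb)
  }

  # --- final outputs ---
  run_stage("write", function() {
    write_bed(loci, file.path(out, "loci.bed"))
    write_summary(loci, file.path(out, "summary.tsv"))
    stage_log(quiet, "write", "summary.tsv / loci.bed written")
  })
  write_manifest()
  invisible(list(loci = loci, output_dir = out, manifest = manifest_path))
}
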