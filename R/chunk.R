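# Genome chunking and chunk-local -> contig coordinate remapping.
#
# Chunk ids use the grammar "{contig}:{offset}", split on the LAST ':' so
# contig names containing ':' survive the round-trip.

#' Chunking parameters
#'
#' @param chunk_size chunk length in bp (default 50000).
#' @param per_chunk_top_hits maximum hits retained per chunk (default 1000).
#' @return a list of class `chunk_params`.
#' @export
chunk_params <- function(chunk_size = 50000L, per_chunk_top_hits = 1000L) {
  chunk_size <- as.integer(chunk_size)
  per_chunk_top_hits <- as.integer(per_chunk_top_hits)
  if (is.na(chunk_size) || chunk_size < 1L) stop("chunk_size must be >= 1")
  if (is.na(per_chunk_top_hits) || per_chunk_top_hits < 1L) {
    stop("per_chunk_top_hits must be >= 1")
  }
  structure(list(chunk_size = chunk_size,
                 per_chunk_top_hits = per_chunk_top_hits),
            class = "chunk_params")
}

chunk_id <- function(contig, offset) sprintf("%s:%d", contig, offset)

#' Parse a chunk id back to (contig, offset)
#'
#' @param id character vector of chunk ids.
#' @return data.frame with columns `contig`, `offset`.
#' @export
parse_chunk_id <- function(id) {
  m <- regexpr(":[0-9]+$", id)
  if (any(m < 0)) stop("malformed chunk id: ", id[which(m < 0)[1]])
  data.frame(contig = substr(id, 1L, m - 1L),
             offset = as.integer(substring(id, m + 1L)),
             stringsAsFactors = FALSE)
}

#' Split genome contigs into fixed-size chunks
#'
#' Consecutive chunks tile each contig without gaps or overlap; the final
#' chunk of a contig may be shorter than `chunk_size`.
#'
#' @param records DNA [seq_records].
#' @param params a [chunk_params()] list.
#' @return data.frame of class `chunk_set` with columns `chunk_id`, `contig`,
#'   `offset`, `length`, `seq`, ordered by (input record order, offset).
#' @export
chunk_genome <- function(records, params = chunk_params()) {
  stopifnot(inherits(records, "data.frame"))
  if (any(records$moltype != "dna")) stop("chunk_genome expects DNA records")
  size <- params$chunk_size
  pieces <- lapply(seq_len(nrow(records)), function(k) {
    contig <- records$id[k]
    L <- nchar(records$seq[k])
    starts <- seq.int(0L, L - 1L, by = size)
    ends <- pmin(starts + size, L)
    data.frame(chunk_id = chunk_id(contig, starts),
               contig = contig,
               offset = as.integer(starts),
               length = as.integer(ends - starts),
               seq = substring(records$seq[k], starts + 1L, ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("chunk_set", "data.frame")
  out
}

#' Write chunks as a FASTA file for an external search tool
#'
#' @param chunks a `chunk_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chunk_fasta <- function(chunks, path) {
  write_fasta(seq_records(id = chunks$chunk_id, seq = chunks$seq,
                          moltype = "dna"),
              path)
}

#' Remap chunk-local hits to contig coordinates
#'
#' For every hit whose `sseqid` is a chunk id, rewrites `sseqid` to the
#' contig name and shifts the canonical interval by the chunk offset:
#' `canon_start = offset + min(sstart, send) - 1`,
#' `canon_end = offset + max(sstart, send)`. Strand and all other fields are
#' unchanged. Source-dialect `sstart`/`send` are also shifted so the table
#' can be re-written in the tabular dialect without losing the mapping.
#'
#' @param hits a `hit_table` with chunk-local subject coordinates.
#' @param chunks a `chunk_set` containing every `sseqid` in `hits`.
#' @return the remapped `hit_table`.
#' @export
remap_hits <- function(hits, chunks) {
  if (nrow(hits) == 0L) return(hits)
  idx <- match(hits$sseqid, chunks$chunk_id)
  if (anyNA(idx)) {
    stop("hits reference unknown chunk id(s): ",
         paste(unique(hits$sseqid[is.na(idx)]), collapse = ", "))
  }
  lo <- pmin(hits$sstart, hits$send)
  hi <- pmax(hits$sstart, hits$send)
  bad <- which(lo < 1L | hi > chunks$length[idx])
  if (length(bad)) {
    stop(sprintf("hit coordinates [%d,%d] outside chunk %s (length %d)",
                 lo[bad[1]], hi[bad[1]], hits$sseqid[bad[1]],
                 chunks$length[idx[bad[1]]]))
  }
  off <- chunks$offset[idx]
  hits$sseqid <- chunks$contig[idx]
  hits$sstart <- as.integer(hits$sstart + off)
  hits$send <- as.integer(hits$send + off)
  hits$canon_start <- as.integer(off + lo - 1L)
  hits$canon_end <- as.integer(off + hi)
  hits
}

#' Convert contig-coordinate hits back to chunk-local coordinates
#'
#' Inverse of [remap_hits()] for hits known to come from a given chunk.
#'
#' @param hits a remapped `hit_table` (contig coordinates).
#' @param chunks a `chunk_set`; each hit must lie within one of its chunks on
#'   the matching contig.
#' @return the chunk-local `hit_table`.
#' @export
unremap_hits <- function(hits, chunks) {
  if (nrow(hits) == 0L) return(hits)
  idx <- vapply(seq_len(nrow(hits)), function(k) {
    j <- which(chunks$contig == hits$sseqid[k] &
                 chunks$offset <= hits$canon_start[k] &
                 hits$canon_end[k] <= chunks$offset + chunks$length)
    if (!length(j)) {
      stop("no chunk contains hit on ", hits$sseqid[k], " at [",
           hits$canon_start[k], ",", hits$canon_end[k], ")")
    }
    j[1]
  }, integer(1))
  off <- chunks$offset[idx]
  hits$sseqid <- chunks$chunk_id[idx]
  hits$sstart <- as.integer(hits$sstart - off)
  hits$send <- as.integer(hits$send - off)
  hits$canon_start <- as.integer(hits$canon_start - off)
  hits$canon_end <- as.integer(hits$canon_end - off)
  hits
}

#' Cap the number of hits retained per chunk
#'
#' Within each subject (chunk), hits are ranked by descending bitscore (ties:
#' ascending e-value, subject id, query id) and truncated to
#' `per_chunk_top_hits`.
#'
#' @param hits a `hit_table` whose `sseqid` values are chunk ids.
#' @param params a [chunk_params()] list.
#' @return the capped `hit_table`.
#' @export
cap_hits_per_chunk <- function(hits, params = chunk_params()) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hit_order(hits), , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$sseqid,
                     FUN = seq_along) <= params$per_chunk_top_hits
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}
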