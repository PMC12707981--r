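# FASTA I/O and the sequence-record container.
#
# Sequence records are a plain data.frame with columns id, description, seq,
# moltype, so downstream code can subset/iterate with base idioms. Parsing is
# delegated to Biostrings (gzip, CRLF and line-wrapping handled there);
# evescreen adds alphabet validation and the moltype tag.

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U",
                "O", "J", "*", "-")

#' Build a set of sequence records
#'
#' @param id character vector of record ids (first header token).
#' @param seq character vector of sequences (uppercased on construction).
#' @param moltype `"dna"` or `"protein"`.
#' @param description full header lines; defaults to `id`.
#' @return A data.frame of class `seq_records` with columns
#'   `id`, `description`, `seq`, `moltype`.
#' @export
seq_records <- function(id, seq, moltype = c("dna", "protein"),
                        description = id) {
  moltype <- match.arg(moltype)
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id))) stop("sequence record with empty id")
  if (any(!nzchar(seq))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "))
  }
  seq <- toupper(seq)
  validate_alphabet(id, seq, moltype)
  out <- data.frame(id = as.character(id),
                    description = as.character(description),
                    seq = seq,
                    moltype = moltype,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

validate_alphabet <- function(id, seq, moltype) {
  allowed <- if (moltype == "dna") IUPAC_DNA else AA_LETTERS
  for (k in seq_along(seq)) {
    chars <- strsplit(seq[[k]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   moltype, chars[bad[1]], id[[k]], bad[1]))
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file (plain or gzipped)
#'
#' Gzip is detected from the magic bytes, not the file extension. Sequences
#' are uppercased; wrapped lines and CRLF endings are handled.
#'
#' @param path path to a FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @return A [seq_records] data.frame in file order.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  seq_records(id = ids, seq = as.character(set), moltype = moltype,
              description = headers)
}

#' Write sequence records to FASTA
#'
#' Headers are the stored `description` (which begins with the id); lines are
#' wrapped at 70 columns.
#'
#' @param records a [seq_records] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$description
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq a single DNA string (IUPAC codes allowed).
#' @return the reverse complement, as a string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
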