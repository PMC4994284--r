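IUPAC_DNA_CHARS <- "ACGTUNRYSWKMBDHV"

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header; case
#' is preserved as read. Duplicate ids, empty sequences and non-IUPAC
#' characters are rejected.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file '%s' does not exist", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate sequence id(s) in '%s': %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence(s) in '%s': %s",
                 path, paste(ids[!nzchar(seqs)], collapse = ", ")),
         call. = FALSE)
  }
  pattern <- sprintf("[^%s%s]", IUPAC_DNA_CHARS, tolower(IUPAC_DNA_CHARS))
  bad <- grepl(pattern, seqs)
  if (any(bad)) {
    stop(sprintf("non-IUPAC nucleotide character(s) in '%s' in sequence(s): %s",
                 path, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' Sequences are written uppercased and wrapped at `line_width` columns.
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param line_width characters per sequence line.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path, line_width = 60L) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids cannot be written", call. = FALSE)
  }
  set <- Biostrings::BStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x character vector of IUPAC nucleotide sequences.
#' @return Character vector of uppercase reverse complements.
#' @export
reverse_complement <- function(x) {
  rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x)))
  out <- as.character(rc)
  names(out) <- names(x)
  out
}
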