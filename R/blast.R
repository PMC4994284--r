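#' Parse BLAST tabular (outfmt 6) alignments
#'
#' Reads 12-column BLAST tabular output (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Query and
#' subject coordinates, 1-based inclusive in the format, are normalized to
#' zero-based half-open ascending intervals; a subject start greater than the
#' subject end encodes reverse orientation. The bit score becomes the
#' alignment score. Comment lines starting with `#` and blank lines are
#' ignored.
#'
#' @param path path to a BLAST tabular file.
#' @return Alignment records as returned by [alignment_records()].
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("alignment file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(alignment_records())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 12L)) {
    i <- which(nfield != 12L)[1L]
    stop(sprintf(
      "'%s' line %d: expected 12 tab-separated columns, found %d",
      path, lineno[i], nfield[i]
    ), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("'%s' line %d: non-numeric %s '%s'",
                   path, lineno[i], what, m[i, col]), call. = FALSE)
    }
    v
  }
  qstart <- num(7L, "query start")
  qend <- num(8L, "query end")
  sstart <- num(9L, "subject start")
  send <- num(10L, "subject end")
  score <- num(12L, "bit score")
  bad <- qstart < 1 | qend < qstart | sstart < 1 | send < 1
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("'%s' line %d: invalid alignment coordinates",
                 path, lineno[i]), call. = FALSE)
  }
  reverse <- sstart > send
  alignment_records(
    fragment_id = m[, 1L],
    fragment_start = qstart - 1L,
    fragment_end = qend,
    ref_id = m[, 2L],
    ref_start = ifelse(reverse, send, sstart) - 1L,
    ref_end = ifelse(reverse, sstart, send),
    orientation = ifelse(reverse, "reverse", "direct"),
    score = score
  )
}

#' Write alignment records as BLAST tabular (outfmt 6)
#'
#' Inverse of [parse_blast_tabular()]: coordinates are converted back to
#' 1-based inclusive, and reverse orientation is encoded by swapping the
#' subject coordinates. Alignments are written as gap- and mismatch-free
#' (percent identity 100, e-value 0), which matches the exact alignments the
#' simulator emits.
#'
#' @param alignments alignment records.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_blast_tabular <- function(alignments, path) {
  aln <- as.data.frame(alignments, stringsAsFactors = FALSE)
  if (nrow(aln)) {
    validate_alignments(aln)
  }
  reverse <- aln$orientation == "reverse"
  lines <- sprintf(
    "%s\t%s\t%.1f\t%d\t0\t0\t%d\t%d\t%d\t%d\t0.0\t%s",
    aln$fragment_id, aln$ref_id, rep(100, nrow(aln)),
    aln$fragment_end - aln$fragment_start,
    aln$fragment_start + 1L, aln$fragment_end,
    ifelse(reverse, aln$ref_end, aln$ref_start + 1L),
    ifelse(reverse, aln$ref_start + 1L, aln$ref_end),
    format(aln$score, trim = TRUE, scientific = FALSE)
  )
  writeLines(lines, path)
  invisible(path)
}
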