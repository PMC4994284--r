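#' Read annotated features from BED or GFF3
#'
#' Coordinates are normalized to the internal zero-based half-open
#' convention (BED already uses it; GFF3 columns 4-5 are 1-based inclusive).
#' Every non-coordinate column is preserved verbatim so that a
#' read-then-write cycle reproduces the file.
#'
#' BED features come back with columns `seq_id`, `start`, `end`, `name`,
#' `score`, `strand` and `extra` (columns 7+ joined by tabs, `NA` when
#' absent); a hidden `.nfields` column remembers how many columns each input
#' line had. GFF3 features come back with `seq_id`, `start`, `end`, `strand`
#' plus the verbatim `source`, `type`, `score`, `phase` and `attributes`
#' columns; leading `#` directive lines are kept in the `"header"` attribute.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`.
#' @return A data frame of features with a `"format"` attribute.
#' @export
read_features <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("annotation file '%s' does not exist", path), call. = FALSE)
  }
  switch(format, bed = read_bed(path), gff3 = read_gff3(path))
}

#' Write annotated features to BED or GFF3
#'
#' Inverse of [read_features()]: internal zero-based half-open coordinates
#' are converted back to the target format's convention and the preserved
#' non-coordinate columns are written verbatim.
#'
#' @param features feature data frame from [read_features()] (possibly after
#'   [transfer_annotations()]).
#' @param path output file.
#' @param format `"bed"` or `"gff3"`; defaults to the features' own format.
#' @return The path, invisibly.
#' @export
write_features <- function(features, path,
                           format = attr(features, "format")) {
  if (is.null(format)) {
    stop("'format' is required when the features carry no format attribute",
         call. = FALSE)
  }
  format <- match.arg(format, c("bed", "gff3"))
  switch(format,
    bed = write_bed(features, path),
    gff3 = write_gff3(features, path)
  )
  invisible(path)
}

read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  nfield <- lengths(fields)
  if (any(nfield < 3L)) {
    i <- which(nfield < 3L)[1L]
    stop(sprintf("'%s' line %d: BED requires at least 3 columns",
                 path, lineno[i]), call. = FALSE)
  }
  col <- function(j, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("'%s' line %d: non-integer BED coordinate", path, lineno[i]),
         call. = FALSE)
  }
  if (any(start < 0L | start >= end)) {
    i <- which(start < 0L | start >= end)[1L]
    stop(sprintf("'%s' line %d: BED interval [%d, %d) is empty or negative",
                 path, lineno[i], start[i], end[i]), call. = FALSE)
  }
  strand <- col(6L)
  strand[is.na(strand)] <- "."
  extra <- vapply(fields, function(f) {
    if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else NA_character_
  }, character(1))
  out <- data.frame(
    seq_id = col(1L), start = start, end = end,
    name = col(4L), score = col(5L), strand = strand, extra = extra,
    .nfields = nfield, stringsAsFactors = FALSE
  )
  attr(out, "format") <- "bed"
  out
}

write_bed <- function(features, path) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(f) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nfields <- if (".nfields" %in% names(f)) f$.nfields else rep(6L, nrow(f))
  lines <- vapply(seq_len(nrow(f)), function(i) {
    cols <- c(f$seq_id[i], f$start[i], f$end[i])
    n <- nfields[i]
    if (n >= 4L) cols <- c(cols, f$name[i])
    if (n >= 5L) cols <- c(cols, f$score[i])
    if (n >= 6L) cols <- c(cols, f$strand[i])
    if (n >= 7L) cols <- c(cols, f$extra[i])
    paste(cols, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_gff3 <- function(path) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) {
    lines <- lines[seq_len(fasta_at[1L] - 1L)]
  }
  is_comment <- startsWith(lines, "#")
  header <- lines[cumprod(is_comment) == 1]
  keep <- nzchar(lines) & !is_comment
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9L)) {
    i <- which(nfield != 9L)[1L]
    stop(sprintf("'%s' line %d: GFF3 requires 9 tab-separated columns, found %d",
                 path, lineno[i], nfield[i]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    i <- which(is.na(start1) | is.na(end1))[1L]
    stop(sprintf("'%s' line %d: non-integer GFF3 coordinate", path, lineno[i]),
         call. = FALSE)
  }
  start <- start1 - 1L
  end <- end1
  if (any(start < 0L | start >= end)) {
    i <- which(start < 0L | start >= end)[1L]
    stop(sprintf("'%s' line %d: GFF3 interval %d..%d is empty or negative",
                 path, lineno[i], start1[i], end1[i]), call. = FALSE)
  }
  out <- data.frame(
    seq_id = m[, 1L], start = start, end = end, strand = m[, 7L],
    source = m[, 2L], type = m[, 3L], score = m[, 6L], phase = m[, 8L],
    attributes = m[, 9L], stringsAsFactors = FALSE
  )
  attr(out, "format") <- "gff3"
  attr(out, "header") <- if (length(header)) header else "##gff-version 3"
  out
}

write_gff3 <- function(features, path) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  header <- attr(features, "header")
  if (is.null(header)) {
    header <- "##gff-version 3"
  }
  body <- if (nrow(f)) {
    sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
            f$seq_id, f$source, f$type, f$start + 1L, f$end,
            f$score, f$strand, f$phase, f$attributes)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
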