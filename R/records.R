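#' Build a table of pairwise alignment records
#'
#' An alignment record describes one local alignment between a fragment and a
#' reference chromosome. All coordinates are zero-based half-open and
#' ascending on both sequences; reverse-strand hits are encoded by
#' `orientation = "reverse"`, never by descending coordinates.
#'
#' @param fragment_id character, fragment identifiers.
#' @param fragment_start,fragment_end integer, aligned region on the fragment.
#' @param ref_id character, reference chromosome identifiers.
#' @param ref_start,ref_end integer, aligned region on the reference.
#' @param orientation `"direct"` or `"reverse"`.
#' @param score non-negative alignment scores (e.g. BLAST bit scores).
#' @return A data frame with one row per alignment.
#' @examples
#' alignment_records("f1", 0L, 60L, "chr1", 100L, 160L, "direct", 120)
#' @export
alignment_records <- function(fragment_id = character(),
                              fragment_start = integer(),
                              fragment_end = integer(),
                              ref_id = character(),
                              ref_start = integer(),
                              ref_end = integer(),
                              orientation = character(),
                              score = numeric()) {
  aln <- data.frame(
    fragment_id = as.character(fragment_id),
    fragment_start = as.integer(fragment_start),
    fragment_end = as.integer(fragment_end),
    ref_id = as.character(ref_id),
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    orientation = as.character(orientation),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  validate_alignments(aln)
  aln
}

validate_alignments <- function(aln) {
  if (!all(aln$orientation %in% c("direct", "reverse"))) {
    stop("alignment orientation must be \"direct\" or \"reverse\"", call. = FALSE)
  }
  bad <- aln$fragment_start < 0L | aln$fragment_start >= aln$fragment_end |
    aln$ref_start < 0L | aln$ref_start >= aln$ref_end
  if (any(bad)) {
    stop(sprintf(
      "alignment coordinates must satisfy 0 <= start < end (offending fragment(s): %s)",
      paste(unique(aln$fragment_id[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  if (any(aln$score < 0)) {
    stop("alignment scores must be non-negative", call. = FALSE)
  }
  invisible(aln)
}

#' Build a fragment map table
#'
#' One row per placed fragment or inserted gap on an assembled chromosome.
#' Gap rows use the pseudo-fragment id `"GAP"`. Coordinates are zero-based
#' half-open; within each chromosome rows must be sorted by `chrom_start` and
#' pairwise disjoint.
#'
#' @param fragment_id character; `"GAP"` marks an inserted gap.
#' @param fragment_length integer, full fragment length (gap length for gaps).
#' @param fragment_start,fragment_end integer, the part of the fragment placed
#'   (always `[0, fragment_length)` for whole-fragment placement).
#' @param orientation `"+"` or `"-"`.
#' @param chrom_id character, assembled chromosome id.
#' @param chrom_start,chrom_end integer, interval on the assembled chromosome.
#' @return A data frame with one row per record.
#' @export
fragment_map_records <- function(fragment_id = character(),
                                 fragment_length = integer(),
                                 fragment_start = integer(),
                                 fragment_end = integer(),
                                 orientation = character(),
                                 chrom_id = character(),
                                 chrom_start = integer(),
                                 chrom_end = integer()) {
  map <- data.frame(
    fragment_id = as.character(fragment_id),
    fragment_length = as.integer(fragment_length),
    fragment_start = as.integer(fragment_start),
    fragment_end = as.integer(fragment_end),
    orientation = as.character(orientation),
    chrom_id = as.character(chrom_id),
    chrom_start = as.integer(chrom_start),
    chrom_end = as.integer(chrom_end),
    stringsAsFactors = FALSE
  )
  validate_fragment_map(map)
  map
}

#' Validate fragment map invariants
#'
#' Checks length consistency of every record and, per chromosome, ascending
#' order and pairwise disjointness.
#'
#' @param map a fragment map data frame.
#' @return The map, invisibly; errors describe the offending records.
#' @export
validate_fragment_map <- function(map) {
  if (nrow(map) == 0L) {
    return(invisible(map))
  }
  if (!all(map$orientation %in% c("+", "-"))) {
    stop("fragment map orientation must be \"+\" or \"-\"", call. = FALSE)
  }
  span_chrom <- map$chrom_end - map$chrom_start
  span_frag <- map$fragment_end - map$fragment_start
  is_gap <- map$fragment_id == "GAP"
  bad <- (span_chrom != span_frag) | (!is_gap & span_frag != map$fragment_length) |
    (is_gap & map$fragment_length != span_chrom)
  if (any(bad)) {
    stop(sprintf(
      "fragment map length mismatch for record(s): %s",
      paste(unique(map$fragment_id[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  for (chrom in unique(map$chrom_id)) {
    m <- map[map$chrom_id == chrom, , drop = FALSE]
    if (nrow(m) < 2L) next
    prev_end <- m$chrom_end[-nrow(m)]
    next_start <- m$chrom_start[-1L]
    viol <- which(next_start < prev_end)
    if (length(viol)) {
      i <- viol[1L]
      stop(sprintf(
        "fragment map records overlap or are unsorted on %s: '%s' [%d, %d) vs '%s' [%d, %d)",
        chrom, m$fragment_id[i], m$chrom_start[i], m$chrom_end[i],
        m$fragment_id[i + 1L], m$chrom_start[i + 1L], m$chrom_end[i + 1L]
      ), call. = FALSE)
    }
  }
  invisible(map)
}

empty_fragment_map <- function() {
  fragment_map_records()
}

flip_strand <- function(strand) {
  ifelse(strand == "+", "-", ifelse(strand == "-", "+", strand))
}
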