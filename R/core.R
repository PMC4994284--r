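#' Derive a fragment's placement interval on the reference
#'
#' Extrapolates a single anchoring alignment to the interval the whole
#' fragment of length L occupies on the reference chromosome. With the
#' alignment covering fragment region \[S̄, Ē) and reference region
#' \[S, E), the placement is
#'
#' - direct orientation: start = S − S̄, end = start + L;
#' - reverse orientation: end = E + S̄, start = end − L.
#'
#' The start may be negative when the fragment overhangs the start of the
#' reference chromosome; layout clamps this downstream.
#'
#' @param anchor_alignment a single alignment record (one-row data frame or
#'   list with the [alignment_records()] fields).
#' @param fragment_length total fragment length in bp; must be at least the
#'   alignment's `fragment_end`.
#' @return Named numeric vector `c(placed_start, placed_end)` with
#'   `placed_end - placed_start == fragment_length`.
#' @examples
#' a <- alignment_records("f1", 20L, 80L, "chr1", 520L, 580L, "direct", 120)
#' fragment_interval(a, 100L) # c(500, 600)
#' @export
fragment_interval <- function(anchor_alignment, fragment_length) {
  a <- as.list(anchor_alignment)
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < a$fragment_end) {
    stop(sprintf(
      "fragment '%s': stated length %d is shorter than the alignment end %d on the fragment",
      a$fragment_id, fragment_length, a$fragment_end
    ), call. = FALSE)
  }
  if (identical(a$orientation, "direct")) {
    start <- a$ref_start - a$fragment_start
    end <- start + fragment_length
  } else if (identical(a$orientation, "reverse")) {
    end <- a$ref_end + a$fragment_start
    start <- end - fragment_length
  } else {
    stop("orientation must be \"direct\" or \"reverse\"", call. = FALSE)
  }
  c(placed_start = as.integer(start), placed_end = as.integer(end))
}

#' Classify a fragment as anchored, unlocalized or unplaced
#'
#' Sorts the fragment's alignments by score (ties broken by reference id,
#' reference start and fragment start, so classification is deterministic)
#' and applies the score-ratio rule: if the best score exceeds the runner-up
#' by more than `ratio_threshold` (strict `>`), the fragment is anchored at
#' the best alignment. Otherwise it is unplaced when the two top alignments
#' hit different reference chromosomes and unlocalized when they hit the
#' same one. A fragment with a single alignment is anchored: there is no
#' competing evidence, so the ratio is treated as infinite.
#'
#' @param fragment_id the fragment's identifier.
#' @param fragment_length total fragment length in bp.
#' @param alignments alignment records for this fragment (non-empty).
#' @param ratio_threshold score-ratio threshold, strictly greater than 1.
#' @return A list with `fragment_id`, `status` (one of `"anchored"`,
#'   `"unlocalized"`, `"unplaced"`) and, when anchored, `anchor`: a list with
#'   the placement interval (`placed_start`, `placed_end`), `ref_id`,
#'   `orientation`, `best_score` and `second_score` (`NA` for a lone
#'   alignment).
#' @examples
#' aln <- alignment_records(
#'   c("f1", "f1"), c(0L, 0L), c(50L, 20L), c("chr1", "chr2"),
#'   c(100L, 900L), c(150L, 920L), c("direct", "direct"), c(100, 40)
#' )
#' classify_fragment("f1", 60L, aln, ratio_threshold = 2)$status
#' @export
classify_fragment <- function(fragment_id, fragment_length, alignments,
                              ratio_threshold) {
  check_ratio_threshold(ratio_threshold)
  aln <- as.data.frame(alignments, stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) {
    stop(sprintf("fragment '%s' has no alignments", fragment_id), call. = FALSE)
  }
  if (!all(aln$fragment_id == fragment_id)) {
    stop(sprintf(
      "alignments for other fragments passed when classifying '%s'", fragment_id
    ), call. = FALSE)
  }
  ord <- order(-aln$score, aln$ref_id, aln$ref_start, aln$fragment_start)
  aln <- aln[ord, , drop = FALSE]
  best <- aln[1L, ]
  second_score <- if (nrow(aln) >= 2L) aln$score[2L] else NA_real_

  anchored <- is.na(second_score) || best$score / second_score > ratio_threshold
  if (anchored) {
    iv <- fragment_interval(best, fragment_length)
    return(list(
      fragment_id = fragment_id,
      status = "anchored",
      anchor = list(
        fragment_id = fragment_id,
        fragment_length = as.integer(fragment_length),
        ref_id = best$ref_id,
        placed_start = iv[["placed_start"]],
        placed_end = iv[["placed_end"]],
        orientation = best$orientation,
        best_score = best$score,
        second_score = second_score
      )
    ))
  }
  status <- if (best$ref_id == aln$ref_id[2L]) "unlocalized" else "unplaced"
  list(fragment_id = fragment_id, status = status, anchor = NULL)
}

check_ratio_threshold <- function(ratio_threshold) {
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1L ||
      is.na(ratio_threshold) || ratio_threshold <= 1) {
    stop("'ratio_threshold' must be a single number greater than one",
         call. = FALSE)
  }
  invisible(ratio_threshold)
}

#' Transfer a fragment region onto an assembled chromosome
#'
#' Lifts a zero-based half-open region \[S̄, Ē) of a fragment mapped at
#' \[S, E) on a chromosome:
#'
#' - direct (`+`) placement: \[S + S̄, S + Ē), strand preserved;
#' - reverse (`-`) placement: \[E − Ē, E − S̄), strand flipped
#'   (`.` stays `.`).
#'
#' Region length is always preserved.
#'
#' @param region a feature (list or one-row data frame) with `seq_id`,
#'   `start`, `end`, `strand`; `seq_id` must equal the placement's
#'   `fragment_id`. Any other fields are carried through untouched.
#' @param placement a fragment map record (see [fragment_map_records()]).
#' @return The feature with `seq_id`, `start`, `end`, `strand` rewritten to
#'   chromosome space.
#' @seealso [invert_transfer()] for the inverse mapping.
#' @export
transfer_region <- function(region, placement) {
  r <- as.list(region)
  p <- as.list(placement)
  if (!identical(as.character(r$seq_id), as.character(p$fragment_id))) {
    stop(sprintf(
      "region on '%s' cannot be transferred with the placement of fragment '%s'",
      r$seq_id, p$fragment_id
    ), call. = FALSE)
  }
  if (r$start < 0L || r$start >= r$end || r$end > p$fragment_length) {
    stop(sprintf(
      "feature%s [%d, %d) lies outside fragment '%s' [0, %d)",
      feature_label(r), r$start, r$end, p$fragment_id, p$fragment_length
    ), call. = FALSE)
  }
  if (p$orientation == "+") {
    start <- p$chrom_start + r$start
    end <- p$chrom_start + r$end
    strand <- r$strand
  } else {
    start <- p$chrom_end - r$end
    end <- p$chrom_end - r$start
    strand <- flip_strand(r$strand)
  }
  r$seq_id <- p$chrom_id
  r$start <- as.integer(start)
  r$end <- as.integer(end)
  r$strand <- strand
  r
}

#' Map a chromosome region back to fragment coordinates
#'
#' Algebraic inverse of [transfer_region()]: for every in-bounds region `x`,
#' `transfer_region(invert_transfer(x, p), p)` equals `x`.
#'
#' @param chrom_region a feature on an assembled chromosome, contained in the
#'   placement interval.
#' @param placement a fragment map record.
#' @return The feature rewritten to fragment coordinates.
#' @export
invert_transfer <- function(chrom_region, placement) {
  r <- as.list(chrom_region)
  p <- as.list(placement)
  if (!identical(as.character(r$seq_id), as.character(p$chrom_id))) {
    stop(sprintf(
      "region on '%s' does not lie on chromosome '%s'", r$seq_id, p$chrom_id
    ), call. = FALSE)
  }
  if (r$start < p$chrom_start || r$end > p$chrom_end || r$start >= r$end) {
    stop(sprintf(
      "feature%s [%d, %d) is not contained in the placement of '%s' [%d, %d)",
      feature_label(r), r$start, r$end, p$fragment_id, p$chrom_start, p$chrom_end
    ), call. = FALSE)
  }
  if (p$orientation == "+") {
    start <- r$start - p$chrom_start
    end <- r$end - p$chrom_start
    strand <- r$strand
  } else {
    start <- p$chrom_end - r$end
    end <- p$chrom_end - r$start
    strand <- flip_strand(r$strand)
  }
  r$seq_id <- p$fragment_id
  r$start <- as.integer(start)
  r$end <- as.integer(end)
  r$strand <- strand
  r
}

feature_label <- function(r) {
  if (!is.null(r$name) && !is.na(r$name)) sprintf(" '%s'", r$name) else ""
}
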