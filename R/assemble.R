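#' Lay out anchored fragments along one chromosome
#'
#' Fragments are sorted by placement interval (ties by fragment id) and
#' placed left to right with a cumulative shift. The shift starts at
#' `max(0, -first placed_start)` so assembled coordinates begin at zero.
#' When a fragment's shifted start would fall before the previous fragment's
#' end — an overlap of N bp — the shift grows by N + `gap_size`, separating
#' the pair by exactly `gap_size` bp of gap. Because the shift is cumulative,
#' spacing between fragments that did not overlap is preserved and no new
#' overlaps can be created downstream. Every stretch between consecutive
#' fragments (and before the first one) is materialized as a `"GAP"` record.
#'
#' @param anchors data frame of anchors on one reference chromosome, with
#'   columns `fragment_id`, `fragment_length`, `ref_id`, `placed_start`,
#'   `placed_end`, `orientation` (`"direct"`/`"reverse"` or `"+"`/`"-"`).
#' @param gap_size gap inserted between formerly overlapping fragments, in
#'   bp, non-negative. Recommended to be at least the sequencing library
#'   insert size.
#' @return A fragment map data frame for this chromosome.
#' @export
layout_chromosome <- function(anchors, gap_size) {
  gap_size <- as.integer(gap_size)
  if (is.na(gap_size) || gap_size < 0L) {
    stop("'gap_size' must be a non-negative integer", call. = FALSE)
  }
  a <- as.data.frame(anchors, stringsAsFactors = FALSE)
  if (nrow(a) == 0L) {
    return(empty_fragment_map())
  }
  dup <- unique(a$fragment_id[duplicated(a$fragment_id)])
  if (length(dup)) {
    stop(sprintf("duplicate fragment id(s) in layout: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  chrom <- unique(a$ref_id)
  if (length(chrom) != 1L) {
    stop("all anchors in a layout must be on the same reference chromosome",
         call. = FALSE)
  }
  a <- a[order(a$placed_start, a$placed_end, a$fragment_id), , drop = FALSE]
  strand <- ifelse(a$orientation %in% c("direct", "+"), "+", "-")

  n <- nrow(a)
  starts <- integer(n)
  delta <- max(0L, -a$placed_start[1L])
  prev_end <- 0L
  gap_rows <- vector("list", n)
  for (i in seq_len(n)) {
    tentative <- a$placed_start[i] + delta
    if (tentative < prev_end) {
      delta <- delta + (prev_end - tentative) + gap_size
      tentative <- a$placed_start[i] + delta
    }
    if (tentative > prev_end) {
      gap_rows[[i]] <- c(prev_end, tentative)
    }
    starts[i] <- tentative
    prev_end <- tentative + a$fragment_length[i]
  }

  frag <- data.frame(
    fragment_id = a$fragment_id,
    fragment_length = as.integer(a$fragment_length),
    fragment_start = 0L,
    fragment_end = as.integer(a$fragment_length),
    orientation = strand,
    chrom_id = chrom,
    chrom_start = starts,
    chrom_end = starts + as.integer(a$fragment_length),
    stringsAsFactors = FALSE
  )
  gaps <- Filter(Negate(is.null), gap_rows)
  if (length(gaps)) {
    g <- do.call(rbind, gaps)
    frag <- rbind(frag, data.frame(
      fragment_id = "GAP",
      fragment_length = g[, 2L] - g[, 1L],
      fragment_start = 0L,
      fragment_end = g[, 2L] - g[, 1L],
      orientation = "+",
      chrom_id = chrom,
      chrom_start = g[, 1L],
      chrom_end = g[, 2L],
      stringsAsFactors = FALSE
    ))
  }
  frag <- frag[order(frag$chrom_start, frag$chrom_end), , drop = FALSE]
  rownames(frag) <- NULL
  validate_fragment_map(frag)
  frag
}

#' Run the fragment-arrangement pipeline: classify, map and lay out
#'
#' Classifies every fragment by the score-ratio rule, derives placement
#' intervals for the anchored ones, and lays them out per reference
#' chromosome with overlap resolution. Fragments without any alignment are
#' reported as unplaced. Reference chromosomes that receive no anchored
#' fragment are absent from the map.
#'
#' @param fragments named character vector of fragment sequences (or a named
#'   integer vector of fragment lengths when sequences are not needed).
#' @param alignments alignment records for the fragments.
#' @param ratio_threshold score-ratio threshold, strictly greater than 1.
#' @param gap_size gap inserted between formerly overlapping fragments (bp).
#' @return A list with `map` (fragment map data frame), `unlocalized_ids`,
#'   `unplaced_ids`, and `classifications` (data frame with `fragment_id`,
#'   `fragment_length`, `status`).
#' @export
build_fragment_map <- function(fragments, alignments, ratio_threshold,
                               gap_size) {
  check_ratio_threshold(ratio_threshold)
  aln <- as.data.frame(alignments, stringsAsFactors = FALSE)
  frag_ids <- names(fragments)
  if (is.null(frag_ids)) {
    stop("'fragments' must be a named vector", call. = FALSE)
  }
  lengths_bp <- if (is.character(fragments)) nchar(fragments) else
    as.integer(fragments)
  names(lengths_bp) <- frag_ids
  unknown <- setdiff(unique(aln$fragment_id), frag_ids)
  if (length(unknown)) {
    stop(sprintf("alignment(s) reference unknown fragment(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  too_long <- aln$fragment_end > lengths_bp[aln$fragment_id]
  if (any(too_long)) {
    stop(sprintf(
      "alignment coordinates exceed fragment length for: %s",
      paste(unique(aln$fragment_id[too_long]), collapse = ", ")
    ), call. = FALSE)
  }

  by_frag <- split(seq_len(nrow(aln)), aln$fragment_id)
  status <- character(length(frag_ids))
  names(status) <- frag_ids
  anchors <- vector("list", length(frag_ids))
  for (i in seq_along(frag_ids)) {
    id <- frag_ids[i]
    rows <- by_frag[[id]]
    if (is.null(rows)) {
      status[i] <- "unplaced"
      next
    }
    cls <- classify_fragment(id, lengths_bp[[id]],
                             aln[rows, , drop = FALSE], ratio_threshold)
    status[i] <- cls$status
    if (cls$status == "anchored") {
      anchors[[i]] <- as.data.frame(cls$anchor, stringsAsFactors = FALSE)
    }
  }
  anchors <- do.call(rbind, Filter(Negate(is.null), anchors))

  map <- empty_fragment_map()
  if (!is.null(anchors) && nrow(anchors)) {
    per_chrom <- lapply(sort(unique(anchors$ref_id)), function(chrom) {
      layout_chromosome(anchors[anchors$ref_id == chrom, , drop = FALSE],
                        gap_size)
    })
    map <- do.call(rbind, per_chrom)
    rownames(map) <- NULL
  }
  list(
    map = map,
    unlocalized_ids = frag_ids[status == "unlocalized"],
    unplaced_ids = frag_ids[status == "unplaced"],
    classifications = data.frame(
      fragment_id = frag_ids,
      fragment_length = as.integer(lengths_bp),
      status = unname(status),
      stringsAsFactors = FALSE
    )
  )
}

#' Emit assembled chromosome sequences from a fragment map
#'
#' Each chromosome is the concatenation of its map records: fragment
#' intervals carry the fragment sequence (reverse-complemented for `"-"`
#' placements) and gap intervals, as well as any uncovered stretch, are
#' filled with `N`. The chromosome length equals the last record's end.
#'
#' @param map fragment map data frame.
#' @param fragments named character vector of fragment sequences.
#' @return Named character vector of assembled chromosome sequences.
#' @export
emit_sequences <- function(map, fragments) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  validate_fragment_map(map)
  chroms <- unique(map$chrom_id)
  out <- vapply(chroms, function(chrom) {
    m <- map[map$chrom_id == chrom, , drop = FALSE]
    pieces <- character(0)
    cursor <- 0L
    for (i in seq_len(nrow(m))) {
      if (m$chrom_start[i] > cursor) {
        pieces <- c(pieces, strrep("N", m$chrom_start[i] - cursor))
      }
      if (m$fragment_id[i] == "GAP") {
        pieces <- c(pieces, strrep("N", m$chrom_end[i] - m$chrom_start[i]))
      } else {
        seq <- unname(fragments[m$fragment_id[i]])
        if (length(seq) != 1L || is.na(seq)) {
          stop(sprintf("fragment '%s' in the map has no sequence",
                       m$fragment_id[i]), call. = FALSE)
        }
        if (nchar(seq) != m$fragment_length[i]) {
          stop(sprintf(
            "fragment '%s': sequence length %d does not match map length %d",
            m$fragment_id[i], nchar(seq), m$fragment_length[i]
          ), call. = FALSE)
        }
        if (m$orientation[i] == "-") {
          seq <- reverse_complement(seq)
        }
        pieces <- c(pieces, seq)
      }
      cursor <- m$chrom_end[i]
    }
    paste(pieces, collapse = "")
  }, character(1))
  names(out) <- chroms
  out
}

#' Summary statistics of a reference-assisted assembly
#'
#' @param classifications data frame with `fragment_id`, `fragment_length`,
#'   `status` (from [build_fragment_map()]).
#' @param map fragment map data frame.
#' @param chromosomes assembled chromosome sequences (optional); when given,
#'   the overall N fraction is counted from the actual sequences, otherwise
#'   from gap records in the map.
#' @return A list with `fragments` (count and bp per status),
#'   `per_chromosome` (fragment count, assembled length and gap bp per
#'   chromosome) and `n_fraction`.
#' @export
compute_stats <- function(classifications, map, chromosomes = NULL) {
  cls <- as.data.frame(classifications, stringsAsFactors = FALSE)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  statuses <- c("anchored", "unlocalized", "unplaced")
  frag <- data.frame(
    status = statuses,
    count = vapply(statuses, function(s) sum(cls$status == s), integer(1)),
    bp = vapply(statuses, function(s)
      sum(cls$fragment_length[cls$status == s]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  chrom_ids <- unique(map$chrom_id)
  per_chrom <- data.frame(
    chrom_id = chrom_ids,
    n_fragments = vapply(chrom_ids, function(c)
      sum(map$chrom_id == c & map$fragment_id != "GAP"), integer(1)),
    length = vapply(chrom_ids, function(c)
      max(0L, map$chrom_end[map$chrom_id == c]), integer(1)),
    gap_bp = vapply(chrom_ids, function(c) {
      g <- map$chrom_id == c & map$fragment_id == "GAP"
      sum(map$chrom_end[g] - map$chrom_start[g])
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  total_len <- sum(per_chrom$length)
  n_bp <- if (!is.null(chromosomes)) {
    sum(nchar(gsub("[^Nn]", "", chromosomes)))
  } else {
    sum(per_chrom$gap_bp)
  }
  list(
    fragments = frag,
    per_chromosome = per_chrom,
    n_fraction = if (total_len > 0L) n_bp / total_len else 0
  )
}

#' Lift annotated features from fragments onto assembled chromosomes
#'
#' Each feature whose `seq_id` names a placed fragment is rewritten to
#' chromosome coordinates with [transfer_region()] (strand-aware for
#' reverse placements). Features on fragments absent from the map — the
#' unlocalized and unplaced ones — are returned in `skipped` with a reason.
#' Input order is preserved within each output.
#'
#' @param features feature data frame (from [read_features()] or with at
#'   least `seq_id`, `start`, `end`, `strand` columns).
#' @param map fragment map data frame.
#' @return A list with `transferred` (features in chromosome coordinates)
#'   and `skipped` (untouched features with a `reason` column).
#' @export
transfer_annotations <- function(features, map) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  validate_fragment_map(map)
  placements <- map[map$fragment_id != "GAP", , drop = FALSE]
  idx <- match(f$seq_id, placements$fragment_id)

  transferred <- f[0, , drop = FALSE]
  skipped <- cbind(f[0, , drop = FALSE], reason = character(0))
  for (i in seq_len(nrow(f))) {
    if (is.na(idx[i])) {
      row <- cbind(f[i, , drop = FALSE],
                   reason = sprintf("fragment '%s' is not in the map",
                                    f$seq_id[i]))
      skipped <- rbind(skipped, row)
      next
    }
    lifted <- transfer_region(f[i, , drop = FALSE],
                              placements[idx[i], , drop = FALSE])
    row <- f[i, , drop = FALSE]
    row$seq_id <- lifted$seq_id
    row$start <- lifted$start
    row$end <- lifted$end
    row$strand <- lifted$strand
    transferred <- rbind(transferred, row)
  }
  rownames(transferred) <- NULL
  rownames(skipped) <- NULL
  attr(transferred, "format") <- attr(features, "format")
  attr(transferred, "header") <- attr(features, "header")
  attr(skipped, "format") <- attr(features, "format")
  attr(skipped, "header") <- attr(features, "header")
  list(transferred = transferred, skipped = skipped)
}
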