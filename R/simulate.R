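#' Configuration for the genome-shredding simulator
#'
#' The simulator emulates the inputs of a reference-assisted assembly run:
#' a chromosome-level reference, a set of draft fragments obtained by
#' shredding it, and exact fragment-versus-reference alignments. It does not
#' model sequencing error, inter-species divergence or rearrangement; the
#' only sources of ambiguity are optional duplicated-placement fragments and
#' alignment-free junk fragments.
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param n_chromosomes number of reference chromosomes.
#' @param chromosome_length length of each reference chromosome (bp).
#' @param fragment_length_range `c(min, max)` fragment length in bp; the last
#'   fragment of a chromosome may be shorter when the remainder is short.
#' @param reverse_fraction probability that a fragment is reverse-complemented
#'   relative to the reference.
#' @param overlap_bp overlap between consecutive fragments on the reference
#'   (bp); must be smaller than the minimum fragment length.
#' @param n_ambiguous number of fragments given two equal-score alignments on
#'   different chromosomes, forcing unplaced calls; requires at least two
#'   chromosomes.
#' @param n_unaligned number of junk fragments with no alignment at all.
#' @return A validated configuration list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 2L,
                              chromosome_length = 100000L,
                              fragment_length_range = c(1000L, 5000L),
                              reverse_fraction = 0.5,
                              overlap_bp = 0L,
                              n_ambiguous = 0L,
                              n_unaligned = 0L) {
  config <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    fragment_length_range = as.integer(fragment_length_range),
    reverse_fraction = as.numeric(reverse_fraction),
    overlap_bp = as.integer(overlap_bp),
    n_ambiguous = as.integer(n_ambiguous),
    n_unaligned = as.integer(n_unaligned)
  )
  r <- config$fragment_length_range
  if (length(r) != 2L || r[1L] < 1L || r[1L] > r[2L]) {
    stop("'fragment_length_range' must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (r[2L] > config$chromosome_length) {
    stop("fragments cannot be longer than a chromosome", call. = FALSE)
  }
  if (config$reverse_fraction < 0 || config$reverse_fraction > 1) {
    stop("'reverse_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (config$overlap_bp < 0L || config$overlap_bp >= r[1L]) {
    stop("'overlap_bp' must be non-negative and smaller than the minimum fragment length",
         call. = FALSE)
  }
  if (config$n_ambiguous > 0L && config$n_chromosomes < 2L) {
    stop("ambiguous fragments require at least two chromosomes", call. = FALSE)
  }
  if (config$n_chromosomes < 1L || config$n_ambiguous < 0L ||
      config$n_unaligned < 0L) {
    stop("chromosome and fragment counts must be non-negative", call. = FALSE)
  }
  class(config) <- "simulation_config"
  config
}

#' Shred a synthetic reference into fragments with exact alignments
#'
#' Generates a random reference genome, tiles each chromosome with fragments
#' of random length (consecutive fragments overlapping by `overlap_bp`),
#' reverse-complements a `reverse_fraction` share of them, and emits for each
#' fragment one exact full-length alignment whose score is twice the
#' alignment length (bit-score-like; classification only uses score ratios,
#' so the scale is irrelevant). Ambiguous fragments additionally get a
#' second, equal-score alignment on a different chromosome; junk fragments
#' get none. The true placement of every shredded fragment is returned as a
#' truth map.
#'
#' Output is deterministic given `config$seed`; the global RNG state is left
#' untouched.
#'
#' @param config a [simulation_config()].
#' @return A list with `reference` and `fragments` (named character
#'   vectors), `alignments` (alignment records) and `truth` (fragment map
#'   records at the true reference positions, which may overlap when
#'   `overlap_bp > 0`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  chrom_ids <- sprintf("chr%d", seq_len(config$n_chromosomes))
  reference <- vapply(chrom_ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), config$chromosome_length,
                 replace = TRUE), collapse = "")
  }, character(1))

  lmin <- config$fragment_length_range[1L]
  lmax <- config$fragment_length_range[2L]
  # sample(n, 1) on a scalar would draw from 1:n, so guard the degenerate range
  rand_len <- function() {
    if (lmin == lmax) lmin else sample(seq.int(lmin, lmax), 1L)
  }
  frag_ids <- character(0)
  frag_seqs <- character(0)
  truth <- list()
  aln <- list()
  counter <- 0L
  for (chrom in chrom_ids) {
    pos <- 0L
    while (pos < config$chromosome_length) {
      len <- rand_len()
      end <- min(pos + len, config$chromosome_length)
      len <- end - pos
      counter <- counter + 1L
      id <- sprintf("frag_%04d", counter)
      seq <- substr(reference[[chrom]], pos + 1L, end)
      reversed <- stats::runif(1L) < config$reverse_fraction
      if (reversed) {
        seq <- reverse_complement(seq)
      }
      frag_ids <- c(frag_ids, id)
      frag_seqs <- c(frag_seqs, seq)
      truth[[length(truth) + 1L]] <- data.frame(
        fragment_id = id, fragment_length = len,
        fragment_start = 0L, fragment_end = len,
        orientation = if (reversed) "-" else "+",
        chrom_id = chrom, chrom_start = pos, chrom_end = end,
        stringsAsFactors = FALSE
      )
      aln[[length(aln) + 1L]] <- data.frame(
        fragment_id = id, fragment_start = 0L, fragment_end = len,
        ref_id = chrom, ref_start = pos, ref_end = end,
        orientation = if (reversed) "reverse" else "direct",
        score = 2 * len, stringsAsFactors = FALSE
      )
      if (end == config$chromosome_length) break
      pos <- end - config$overlap_bp
    }
  }

  # fragments placed equally well on two chromosomes: unresolvable, so the
  # classifier must call them unplaced at any threshold > 1
  for (k in seq_len(config$n_ambiguous)) {
    len <- rand_len()
    src <- sample(seq_along(chrom_ids), 2L)
    start1 <- sample.int(config$chromosome_length - len + 1L, 1L) - 1L
    start2 <- sample.int(config$chromosome_length - len + 1L, 1L) - 1L
    id <- sprintf("ambig_%04d", k)
    frag_ids <- c(frag_ids, id)
    frag_seqs <- c(frag_seqs,
                   substr(reference[[chrom_ids[src[1L]]]], start1 + 1L,
                          start1 + len))
    aln[[length(aln) + 1L]] <- data.frame(
      fragment_id = rep(id, 2L), fragment_start = 0L, fragment_end = len,
      ref_id = chrom_ids[src], ref_start = c(start1, start2),
      ref_end = c(start1, start2) + len,
      orientation = "direct", score = 2 * len, stringsAsFactors = FALSE
    )
  }

  for (k in seq_len(config$n_unaligned)) {
    len <- rand_len()
    id <- sprintf("junk_%04d", k)
    frag_ids <- c(frag_ids, id)
    frag_seqs <- c(frag_seqs,
                   paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = ""))
  }

  names(frag_seqs) <- frag_ids
  alignments <- if (length(aln)) {
    do.call(rbind, aln)
  } else {
    alignment_records()
  }
  rownames(alignments) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else empty_fragment_map()
  rownames(truth) <- NULL
  list(reference = reference, fragments = frag_seqs,
       alignments = alignments, truth = truth)
}

#' Compare an assembly against the simulator's truth map
#'
#' Counts, for the fragments present in the truth map: fragments missing
#' from the result; fragments on the wrong chromosome; fragments whose
#' placement interval differs from truth (any start/end difference, so
#' layout shifts count here); fragments with flipped orientation; and
#' fragments whose (previous, next) fragment neighbours on their chromosome
#' differ from the truth neighbours — the order-level notion of
#' misplacement, robust to gap-insertion shifts.
#'
#' @param result_map fragment map data frame produced by the pipeline.
#' @param truth truth map from [simulate_genome()].
#' @return A list of counts with the offending fragment ids:
#'   `missing`, `wrong_chromosome`, `misplaced`, `misoriented`,
#'   `neighbor_mismatch`, plus `n_truth`.
#' @export
truth_compare <- function(result_map, truth) {
  res <- as.data.frame(result_map, stringsAsFactors = FALSE)
  res <- res[res$fragment_id != "GAP", , drop = FALSE]
  tru <- as.data.frame(truth, stringsAsFactors = FALSE)
  tru <- tru[tru$fragment_id != "GAP", , drop = FALSE]

  idx <- match(tru$fragment_id, res$fragment_id)
  missing <- tru$fragment_id[is.na(idx)]
  both <- !is.na(idx)
  r <- res[idx[both], , drop = FALSE]
  t <- tru[both, , drop = FALSE]
  wrong_chromosome <- t$fragment_id[r$chrom_id != t$chrom_id]
  misplaced <- t$fragment_id[
    r$chrom_id != t$chrom_id |
      r$chrom_start != t$chrom_start | r$chrom_end != t$chrom_end
  ]
  misoriented <- t$fragment_id[r$orientation != t$orientation]

  neighbors <- function(map) {
    out <- list()
    for (chrom in unique(map$chrom_id)) {
      ids <- map$fragment_id[map$chrom_id == chrom][
        order(map$chrom_start[map$chrom_id == chrom])]
      n <- length(ids)
      for (i in seq_len(n)) {
        out[[ids[i]]] <- c(
          prev = if (i > 1L) ids[i - 1L] else NA_character_,
          nxt = if (i < n) ids[i + 1L] else NA_character_
        )
      }
    }
    out
  }
  nb_res <- neighbors(res)
  nb_tru <- neighbors(tru)
  neighbor_mismatch <- t$fragment_id[vapply(t$fragment_id, function(id) {
    !identical(nb_res[[id]], nb_tru[[id]])
  }, logical(1))]

  list(
    n_truth = nrow(tru),
    missing = missing,
    wrong_chromosome = wrong_chromosome,
    misplaced = misplaced,
    misoriented = misoriented,
    neighbor_mismatch = neighbor_mismatch
  )
}
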