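anchor_row <- function(id, start, end, ref_id = "chr1", orientation = "direct") {
  data.frame(fragment_id = id, fragment_length = end - start,
             ref_id = ref_id, placed_start = start, placed_end = end,
             orientation = orientation, stringsAsFactors = FALSE)
}

test_that("overlaps are resolved by an (N + S) cumulative shift", {
  # A and B overlap by N = 10; with S = 20 B shifts by 30 and a 20 bp gap appears
  anchors <- rbind(anchor_row("A", 0L, 100L), anchor_row("B", 90L, 190L))
  map <- layout_chromosome(anchors, gap_size = 20L)
  expect_equal(map$fragment_id, c("A", "GAP", "B"))
  expect_equal(map$chrom_start, c(0L, 100L, 120L))
  expect_equal(map$chrom_end, c(100L, 120L, 220L))

  # downstream fragment C keeps its distance to the shifted frame
  anchors <- rbind(anchors, anchor_row("C", 300L, 400L))
  map <- layout_chromosome(anchors, gap_size = 20L)
  c_row <- map[map$fragment_id == "C", ]
  expect_equal(c(c_row$chrom_start, c_row$chrom_end), c(330L, 430L))

  # disjoint fragments are untouched; the spacing becomes an explicit gap
  anchors <- rbind(anchor_row("A", 0L, 100L), anchor_row("B", 150L, 250L))
  map <- layout_chromosome(anchors, gap_size = 99L)
  expect_equal(map$fragment_id, c("A", "GAP", "B"))
  expect_equal(map$chrom_start, c(0L, 100L, 150L))
  expect_equal(map$chrom_end, c(100L, 150L, 250L))

  # a negative placement start is clamped to zero
  map <- layout_chromosome(anchor_row("A", -10L, 90L), gap_size = 5L)
  expect_equal(c(map$chrom_start, map$chrom_end), c(0L, 100L))

  expect_error(
    layout_chromosome(rbind(anchor_row("A", 0L, 100L), anchor_row("A", 50L, 150L)), 0L),
    "duplicate fragment id"
  )
})

test_that("random overlap scenarios stay disjoint with exact gap-size separation", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    S <- sample(0:50, 1)
    starts <- cumsum(sample(-20:80, n, replace = TRUE))
    starts <- starts - min(starts) # keep some at 0, rest spread out
    lens <- sample(30:120, n, replace = TRUE)
    anchors <- do.call(rbind, lapply(seq_len(n), function(i) {
      anchor_row(sprintf("f%02d", i), starts[i], starts[i] + lens[i])
    }))
    map <- layout_chromosome(anchors, gap_size = S)
    frag <- map[map$fragment_id != "GAP", ]
    # pairwise disjoint and sorted
    expect_true(all(diff(frag$chrom_start) > 0))
    expect_true(all(frag$chrom_start[-1] >= frag$chrom_end[-nrow(frag)]))

    # order preservation and exact separation of formerly overlapping neighbors
    ord <- order(anchors$placed_start, anchors$placed_end, anchors$fragment_id)
    a <- anchors[ord, ]
    expect_identical(frag$fragment_id, a$fragment_id)
    shift <- frag$chrom_start - a$placed_start
    expect_true(all(diff(shift) >= 0)) # shift only accumulates
    for (i in 2:nrow(a)) {
      overlapped <- a$placed_start[i] + shift[i - 1] < frag$chrom_end[i - 1]
      spacing <- frag$chrom_start[i] - frag$chrom_end[i - 1]
      if (overlapped) {
        expect_identical(spacing, S)
      } else {
        # non-overlapping neighbors keep their spacing in the shifted frame
        expect_identical(spacing,
                         a$placed_start[i] + shift[i - 1] - frag$chrom_end[i - 1])
      }
    }
  }
})

test_that("the pipeline partitions fragments and excludes ambiguous ones from the map", {
  fragments <- c(f1 = strrep("ACGT", 25), f2 = strrep("GATC", 25),
                 f3 = strrep("TTAA", 25), tie = strrep("CCGG", 25),
                 local = strrep("AATT", 25), naked = strrep("GGCC", 25))
  aln <- rbind(
    alignment_records("f1", 0L, 100L, "chr1", 0L, 100L, "direct", 200),
    alignment_records("f2", 0L, 100L, "chr1", 100L, 200L, "direct", 200),
    alignment_records("f3", 0L, 100L, "chr1", 200L, 300L, "reverse", 200),
    alignment_records(c("tie", "tie"), c(0L, 0L), c(100L, 100L),
                      c("chr1", "chr2"), c(500L, 500L), c(600L, 600L),
                      c("direct", "direct"), c(150, 150)),
    alignment_records(c("local", "local"), c(0L, 0L), c(100L, 100L),
                      c("chr2", "chr2"), c(0L, 800L), c(100L, 900L),
                      c("direct", "direct"), c(150, 135))
  )
  res <- build_fragment_map(fragments, aln, ratio_threshold = 1.5, gap_size = 10L)

  expect_identical(res$unplaced_ids, c("tie", "naked"))
  expect_identical(res$unlocalized_ids, "local")
  expect_identical(res$classifications$status,
                   c("anchored", "anchored", "anchored", "unplaced",
                     "unlocalized", "unplaced"))
  placed <- res$map$fragment_id[res$map$fragment_id != "GAP"]
  expect_setequal(placed, c("f1", "f2", "f3"))
  # exact tiling of chr1: no gaps at all
  expect_identical(res$map$fragment_id, c("f1", "f2", "f3"))
  expect_equal(res$map$chrom_start, c(0L, 100L, 200L))

  expect_error(
    build_fragment_map(fragments,
                       alignment_records("ghost", 0L, 10L, "chr1", 0L, 10L,
                                         "direct", 20),
                       1.5, 10L),
    "unknown fragment.*ghost"
  )
})

test_that("assembled sequences place fragments verbatim, reverse-complemented on '-'", {
  f1 <- "ACGTACGTAC"
  map <- fragment_map_records("f1", 10L, 0L, 10L, "+", "chr1", 0L, 10L)
  expect_identical(emit_sequences(map, c(f1 = f1)), c(chr1 = f1))

  map <- fragment_map_records(
    fragment_id = c("GAP", "f1"), fragment_length = c(5L, 10L),
    fragment_start = c(0L, 0L), fragment_end = c(5L, 10L),
    orientation = c("+", "-"), chrom_id = "chr1",
    chrom_start = c(0L, 5L), chrom_end = c(5L, 15L)
  )
  expect_identical(emit_sequences(map, c(f1 = f1)),
                   c(chr1 = paste0("NNNNN", "GTACGTACGT")))

  map <- fragment_map_records(
    fragment_id = c("f1", "GAP", "f2"), fragment_length = c(10L, 20L, 4L),
    fragment_start = c(0L, 0L, 0L), fragment_end = c(10L, 20L, 4L),
    orientation = "+", chrom_id = "chr1",
    chrom_start = c(0L, 10L, 30L), chrom_end = c(10L, 30L, 34L)
  )
  got <- emit_sequences(map, c(f1 = f1, f2 = "GATC"))
  expect_identical(unname(got), paste0(f1, strrep("N", 20), "GATC"))
  expect_identical(nchar(unname(got)), 34L)

  expect_error(emit_sequences(map, c(f1 = f1, f2 = "GATCA")),
               "'f2'.*does not match map length")
  expect_error(emit_sequences(map, c(f1 = f1)), "'f2'.*no sequence")
})

test_that("assembly statistics summarize the partition and gap content", {
  cls <- data.frame(
    fragment_id = c("a", "b", "c", "d"),
    fragment_length = c(100L, 50L, 25L, 10L),
    status = c("anchored", "anchored", "anchored", "unplaced"),
    stringsAsFactors = FALSE
  )
  map <- fragment_map_records(
    fragment_id = c("a", "GAP", "b"), fragment_length = c(100L, 20L, 50L),
    fragment_start = c(0L, 0L, 0L), fragment_end = c(100L, 20L, 50L),
    orientation = "+", chrom_id = "chr1",
    chrom_start = c(0L, 100L, 120L), chrom_end = c(100L, 120L, 170L)
  )
  stats <- compute_stats(cls, map)
  expect_equal(stats$fragments$count, c(3L, 0L, 1L))
  expect_equal(stats$fragments$bp, c(175, 0, 10))
  expect_equal(stats$per_chromosome$gap_bp, 20L)
  expect_equal(stats$per_chromosome$n_fragments, 2L)
  expect_equal(stats$per_chromosome$length, 170L)
  expect_equal(stats$n_fraction, 20 / 170)

  # with sequences, N content is counted from the actual bases
  stats2 <- compute_stats(cls, map,
                          c(chr1 = paste0(strrep("A", 100), strrep("N", 20),
                                          strrep("C", 50))))
  expect_equal(stats2$n_fraction, 20 / 170)

  empty <- compute_stats(cls[0, ], fragment_map_records())
  expect_equal(sum(empty$fragments$count), 0L)
  expect_equal(empty$n_fraction, 0)
})

test_that("annotation transfer lifts features through the map and reports skips", {
  map <- fragment_map_records(
    fragment_id = c("f1", "f2"), fragment_length = c(100L, 100L),
    fragment_start = 0L, fragment_end = 100L,
    orientation = c("+", "-"), chrom_id = "chr1",
    chrom_start = c(500L, 700L), chrom_end = c(600L, 800L)
  )
  feats <- data.frame(
    seq_id = c("f1", "f2", "lost"),
    start = c(10L, 10L, 0L), end = c(30L, 30L, 5L),
    strand = c("+", "+", "+"),
    name = c("geneA", "geneB", "geneC"),
    stringsAsFactors = FALSE
  )
  res <- transfer_annotations(feats, map)
  expect_equal(res$transferred$seq_id, c("chr1", "chr1"))
  expect_equal(res$transferred$start, c(510L, 770L))
  expect_equal(res$transferred$end, c(530L, 790L))
  expect_equal(res$transferred$strand, c("+", "-"))
  expect_equal(res$transferred$name, c("geneA", "geneB"))
  expect_equal(res$skipped$name, "geneC")
  expect_match(res$skipped$reason, "not in the map")

  oob <- data.frame(seq_id = "f1", start = 90L, end = 110L, strand = "+",
                    name = "tooFar", stringsAsFactors = FALSE)
  expect_error(transfer_annotations(oob, map), "'tooFar'.*outside fragment")
})

test_that("raising the ratio threshold never promotes a fragment to anchored", {
  set.seed(33)
  statuses <- c(anchored = 2L, unlocalized = 1L, unplaced = 0L)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    aln <- alignment_records(
      fragment_id = rep("f", n),
      fragment_start = rep(0L, n), fragment_end = rep(50L, n),
      ref_id = sample(c("chr1", "chr2"), n, replace = TRUE),
      ref_start = sample(0:1000, n), ref_end = sample(1100:2000, n),
      orientation = "direct",
      score = round(runif(n, 10, 100), 1)
    )
    sweep <- vapply(c(1.05, 1.2, 1.5, 2, 3, 10), function(thr) {
      statuses[[classify_fragment("f", 50L, aln, thr)$status]]
    }, integer(1))
    # anchored (2) can only degrade as the threshold rises, never improve
    expect_true(all(diff(sweep >= 2L) <= 0L))
  }
})
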