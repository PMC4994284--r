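# Brute-force oracle for fragment placement: instead of using the
# closed-form interval equations, walk the fragment base-by-base from the
# aligned region towards fragment base 0, verifying at every step that the
# fragment character matches the reference (complement for reverse hits),
# and read the placement off the final walk position.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

walk_oracle_interval <- function(ref, frag, fragment_start,
                                 ref_start, ref_end, orientation) {
  L <- nchar(frag)
  rchars <- strsplit(ref, "")[[1]]
  fchars <- strsplit(frag, "")[[1]]
  i <- fragment_start
  if (orientation == "direct") {
    pos <- ref_start # reference position of fragment base `fragment_start`
    while (i > 0L) {
      i <- i - 1L
      pos <- pos - 1L
      if (pos >= 0L && fchars[i + 1L] != rchars[pos + 1L]) {
        stop("oracle walk: fragment does not match reference")
      }
    }
    c(pos, pos + L)
  } else {
    pos <- ref_end - 1L # fragment base `fragment_start` pairs with the hit's last ref base
    while (i > 0L) {
      i <- i - 1L
      pos <- pos + 1L
      if (pos < length(rchars) &&
          fchars[i + 1L] != COMPLEMENT[[rchars[pos + 1L]]]) {
        stop("oracle walk: fragment does not match reverse-complemented reference")
      }
    }
    c(pos + 1L - L, pos + 1L)
  }
}

# A random mismatch-free scenario: a reference, a fragment cut from it at a
# known interval (possibly reverse-complemented), and a partial alignment
# covering a random sub-region of the fragment.
random_exact_case <- function(ref_len = 300L) {
  L <- sample(20:80, 1L)
  s <- sample.int(ref_len - L + 1L, 1L) - 1L
  e <- s + L
  ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
               collapse = "")
  reversed <- runif(1) < 0.5
  frag_fwd <- substr(ref, s + 1L, e)
  frag <- if (reversed) chromstitch::reverse_complement(frag_fwd) else frag_fwd
  a <- sample.int(L, 1L) - 1L
  b <- a + sample.int(L - a, 1L)
  if (reversed) {
    rs <- e - b
    re <- e - a
  } else {
    rs <- s + a
    re <- s + b
  }
  list(
    ref = ref, frag = frag, fragment_length = L,
    truth = c(s, e),
    alignment = alignment_records(
      "frag", a, b, "ref", rs, re,
      if (reversed) "reverse" else "direct", 2 * (b - a)
    )
  )
}

# A random fragment placement plus an in-bounds region on the fragment, for
# transfer round-trip checks.
random_placement_case <- function() {
  L <- sample(50:200, 1L)
  chrom_start <- sample(0:1000, 1L)
  placement <- fragment_map_records(
    "frag", L, 0L, L, sample(c("+", "-"), 1L), "chr",
    chrom_start, chrom_start + L
  )
  a <- sample.int(L, 1L) - 1L
  b <- a + sample.int(L - a, 1L)
  region <- list(seq_id = "frag", start = a, end = b,
                 strand = sample(c("+", "-", "."), 1L))
  list(placement = placement, region = region)
}
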