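---
title: "Reference-assisted arrangement of genome fragments"
author: "chromstitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-assisted arrangement of genome fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstitch)
```

## The problem

A draft genome assembly is a bag of contigs or scaffolds ("fragments") with
no chromosome context. When a chromosome-level assembly of a closely
related species exists, the order, orientation and approximate spacing of
the fragments can be inferred from nothing more than their pairwise local
alignments to that reference — no mate pairs, optical maps or Hi-C
required. chromstitch implements this arrangement strategy for alignments
in BLAST tabular format, together with annotation liftover onto the
resulting chromosomes.

The method assumes the two genomes are largely collinear. It cannot detect
rearrangements between the species: a fragment spanning a breakpoint is
simply placed where its strongest alignment puts it. Users working across
larger evolutionary distances should treat the output as a hypothesis
ordered by the reference, not as an independent assembly.

All coordinates inside the package are zero-based half-open (the first base
is position 0, interval ends are exclusive). BLAST tabular and GFF3 are
1-based inclusive on disk; conversion happens only in the readers and
writers.

## The model

### Anchoring by score ratio

For each fragment, alignments are ranked by score (BLAST bit score). Let
$s_1 \ge s_2$ be the two best scores. The fragment is *anchored* at its
best alignment when $s_1 / s_2 > r$ for the user-chosen ratio threshold
$r > 1$ (strict inequality: a ratio exactly at the threshold does not
anchor). Otherwise the fragment is *unplaced* when the two best hits lie on
different reference chromosomes — the evidence is ambiguous at the
chromosome level — and *unlocalized* when they lie on the same chromosome:
the chromosome is known but the position is not. Unlocalized and unplaced
fragments are excluded from the layout and reported in id lists.

Two boundary cases are not settled by the rule above and are the package's
own choices:

* **Single alignment.** The ratio is undefined; we anchor the fragment,
  treating the ratio as infinite. There is no conflicting evidence, and
  discarding such fragments would throw away the least ambiguous
  placements. Callers who distrust lone weak hits can pre-filter the
  alignment table by score.
* **Exact best ties.** A tie gives ratio 1, which can never exceed a
  threshold greater than one, so tied-best fragments are never anchored;
  the unplaced/unlocalized split then uses the chromosomes of the two tied
  hits. Sorting is deterministic (score descending, then reference id,
  reference start, fragment start), so identical inputs always classify
  identically.

Only the two best scores participate; weaker alignments are ignored.
Classification depends only on score *ratios*, so any positive rescaling
of the scores leaves it unchanged — the suite checks this property
explicitly.

### Mapping a fragment to reference coordinates

An anchored fragment of length $L$ whose alignment covers fragment region
$[\bar{S}, \bar{E})$ and reference region $[S, E)$ occupies

* direct orientation: $[\,S - \bar{S},\; (S - \bar{S}) + L\,)$,
* reverse orientation: $[\,(E + \bar{S}) - L,\; E + \bar{S}\,)$,

on the reference: the unaligned fragment ends are extrapolated outwards.
The start may be negative when a fragment overhangs the chromosome start;
the layout step clamps the whole chromosome so output coordinates begin at
zero. `fragment_interval()` implements these equations, and the tests
compare them against a brute-force oracle that walks the fragment
base-by-base along an exactly matching reference.

### Overlap resolution

Extrapolated intervals of neighbouring fragments can overlap.
`layout_chromosome()` sorts the anchored fragments of each chromosome by
placement interval and applies a cumulative shift $\Delta$, initialized to
$\max(0, -\text{first start})$. When a fragment's shifted start falls $N$
bp before the previous fragment's end, $\Delta$ grows by $N + S$, where $S$
is the insertion size parameter; the pair ends up separated by exactly $S$
bp of `N` gap. Because the shift is cumulative, fragments that did not
overlap keep their reference-derived spacing in the shifted frame, and one
overlap can never create another downstream. (The alternative — shifting
only the offending fragment — compresses downstream spacing and can
cascade new overlaps, which is why we did not adopt it.) Every uncovered
stretch, including a possible prefix before the first fragment, becomes an
explicit `GAP` record, so transferred coordinates stay collinear with the
reference frame.

The assembled chromosome ends at its last fragment; it is not padded to
the reference chromosome's length, and reference chromosomes that anchor
no fragment are omitted. Unlocalized fragments are listed but not emitted
as `*_random`-style sequences.

### Annotation transfer

A feature $[\bar{S}_R, \bar{E}_R)$ on a fragment mapped at $[S_F, E_F)$
moves to

* direct: $[\,S_F + \bar{S}_R,\; S_F + \bar{E}_R\,)$, strand preserved,
* reverse: $[\,E_F - \bar{E}_R,\; E_F - \bar{S}_R\,)$, strand flipped
  (`.` stays `.`).

`invert_transfer()` is the exact algebraic inverse, which gives the suite a
round-trip identity to verify on random regions. Features on fragments
absent from the map are returned as skipped with a reason rather than
silently dropped.

## Parameters

* **`ratio_threshold`** (dimensionless, required, must exceed 1). Controls
  the anchoring stringency: higher values demand stronger dominance of the
  best alignment and push borderline fragments into the unlocalized or
  unplaced lists. Raising it can only ever demote fragments, never promote
  them (a monotonicity the tests assert). There is no universally correct
  default — it trades placement rate against misplacement risk — so the
  command line requires it explicitly; 1.2 is a reasonable starting point
  for closely related genomes.
* **`gap_size`** (`S`, bp, required, non-negative). The gap inserted
  between formerly overlapping fragments. Overlaps typically arise from
  repeats or over-extrapolated fragment ends, so a value at or above the
  sequencing library's insert size keeps downstream scaffolding honest
  about the uncertainty.

## The simulator

`simulate_genome()` generates the study conditions the package is tested
under: a uniform-random reference genome, fragments cut from it at random
lengths (default 1–5 kb over 100 kb chromosomes), a configurable fraction
reverse-complemented (default 0.5), and the corresponding *exact*
full-length alignments with score equal to twice the alignment length —
bit-score-like, and irrelevant in scale because classification is
ratio-based. Optional knobs add overlapping fragments, fragments duplicated
across chromosomes (two equal-score hits, forcing unplaced calls at any
threshold) and alignment-free junk fragments. All randomness flows from one
seed and the global RNG state is restored afterwards, so fixtures are
byte-reproducible.

What the simulator deliberately does not model: sequencing error, assembly
chimeras, inter-species sequence divergence, rearrangements, and repeat
structure that produces many near-equal alignments. Passing the
shred-and-reassemble suite therefore demonstrates that the coordinate
algebra, classification, layout and emission are exact — it does not
demonstrate robustness to noisy real-world alignments, where anchoring
quality is governed by the aligner and the threshold choice.

## Numerical and degenerate-input choices

* Coordinates are plain R integers; genomes beyond ~2 Gb per chromosome
  would need the layout arithmetic revisited.
* Fragments with *no* alignments at all are reported as unplaced by the
  pipeline (`build_fragment_map()`), while `classify_fragment()` itself
  treats an empty alignment list as a caller error — the distinction keeps
  the low-level contract strict.
* An empty alignment file produces an empty map and a complete unplaced
  list, exit status 0: absence of evidence is a valid result, not a crash.
* The fragment map is an 8-column TSV (fragment id, length, fragment
  interval, orientation, chromosome, chromosome interval) with `GAP`
  pseudo-fragments; it is validated for ordering, disjointness and length
  consistency on every read and write.
* Writers emit uppercase FASTA wrapped at 60 columns; readers preserve the
  case they find.

## Worked example

```{r example}
config <- simulation_config(seed = 7, n_chromosomes = 2,
                            chromosome_length = 20000,
                            fragment_length_range = c(500, 1500),
                            reverse_fraction = 0.5,
                            n_ambiguous = 2, n_unaligned = 1)
sim <- simulate_genome(config)
res <- build_fragment_map(sim$fragments, sim$alignments,
                          ratio_threshold = 1.2, gap_size = 100)
table(res$classifications$status)
head(res$map, 3)
chromosomes <- emit_sequences(res$map, sim$fragments)
identical(chromosomes[order(names(chromosomes))], sim$reference)
truth_compare(res$map, sim$truth)$misplaced
```

The test suite runs these checks at larger sizes: 1000 randomized
alignments against the base-walk oracle, 1000 transfer round trips, and a
2 × 100 kb shred-and-reassemble study — sizes chosen so the full suite
completes in about a minute on a laptop while still exercising every
branch of the coordinate algebra.

## Known limitations

* One reference genome only; no reconciliation of multiple references and
  no rearrangement calling.
* BLAST tabular is the only alignment dialect; chain/net or PSL input
  would need a new reader (the internal alignment record is
  dialect-agnostic).
* Gap sizes are a single fixed parameter, not estimated from data.
* Interoperability with other tools' map-file formats is not guaranteed;
  the map format here is the package's own.
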