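Package: chromstitch
Title: Reference-Assisted Arrangement of Genome Fragments into Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds draft chromosome sequences from contigs or scaffolds using
    only their pairwise alignments to a related reference genome. Fragments are
    anchored by the ratio of their two best alignment scores, mapped onto
    reference coordinates in zero-based half-open convention, laid out with
    gap-based overlap resolution, and emitted as chromosome FASTA plus a
    fragment map. Annotations in BED or GFF3 can be lifted from fragment
    coordinates onto the assembled chromosomes. A genome-shredding simulator
    produces synthetic references, fragments and exact alignments so the whole
    pipeline is testable without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
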