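Package: orgedit
Title: Organelle C-to-U RNA Editing Analysis from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-site C-to-U RNA editing extents in plant
    organelle (mitochondrial and plastid) transcripts from strand- and
    transcript-specific amplicon deep-sequencing data, either from
    edited/unedited read-count tables or by pileup on strand-specific
    alignments. Classifies sites as increased, decreased or invariant
    between genotypes with a replicate-intersection chi-square test under
    Bonferroni family-wise error control and an effect-size floor;
    evaluates transgenic rescue with a normalized complementation-effect
    statistic; computes intron splicing efficiency from junction-informative
    reads; and summarises cross-mutant dependence with contingency tables.
    Includes a synthetic-data generator emulating the count structure of
    such studies so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
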