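Package: relmart
Title: Dependency-Aware Data Mart, Exchange Format and Sequence Tools for
    Biological Data Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, dependency-aware warehouse for biological data
    built on the principles of record unicity and data atomicity. Scientific
    concepts (organisms, genes, transcripts, proteins, assays, ...) are
    registered in a dependency graph with computed levels; records are stored
    with unicity keys, per-residue atomic sequences, provenance and a
    versioning table; updates are driven by a parent-gated orchestrator that
    holds child sources when a parent fails. Any record set can be exported
    with its complete dependency closure as a BIORJ document (JSON or
    linearized text) and re-imported with unicity merge. Sequence
    applications include CDS translation, classification of A-to-G RNA
    editing consequences (silent, amino-acid-modifying, or
    premature-stop-preventing), mismatch-tolerant oligonucleotide matching,
    and affine-gap Smith-Waterman local alignment. A deterministic synthetic
    ecosystem generator provides multi-provider toy data sources in standard
    formats (FASTA, GFF3, VCF, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
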