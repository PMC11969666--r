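---
title: "relmart: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{relmart: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmart)
```

## The problem

Biological data sources do not stand alone: a gene record is meaningless
without the organism it is defined in, a transcript needs its gene and the
chromosome sequence, an assay result needs the assay, the target protein and,
transitively, everything beneath them. Most integration efforts flatten these
relationships away and leave each scientist to re-derive them. `relmart`
models them explicitly and makes three things fall out of one structure — a
dependency graph over *scientific concepts*:

* a safe **update order** for data sources (parents first, children held when
  a parent fails),
* **cascade deletion** (a record that loses a critical ancestor loses its
  scientific integrity and is removed with it), and
* **closure-complete exchange** (exporting a record always exports everything
  it depends on).

## The dependency model

Concepts are nodes; an edge runs from a parent concept to the child that
depends on it. Edges come in two kinds. **Critical** dependencies are
integrity-bearing: without the parent record the child record is
scientifically meaningless (gene → organism). **Related** dependencies merely
augment a record (publications, external identifiers, evidence codes) and
never gate processing.

The **dependency level** of a concept is defined over critical edges only:

* a concept with no critical parents is a root, level `L1`;
* otherwise its level is `1 + max(level of critical parents)` — equivalently
  one plus the longest critical path up to a root.

Related edges are excluded from both level computation and cycle detection.
This is deliberate: related dependencies may legitimately be cyclic across
ecosystems (publications cite genes, gene records cite publications), while
the critical graph must be a DAG for update ordering and cascade semantics to
be well defined. Levels are computed with a single Kahn pass; because levels
strictly increase along critical edges, sorting any parent-closed subset by
`(level, name)` is itself a valid topological order, which is what
`update_order()` returns. The lexicographic tie-break is a package choice —
independent sources have no inherent order — made so that every downstream
artifact (event logs, exports, dumps) is deterministic and testable.

The level domain is unbounded. The packaged transcription of the assay export
map (`export_map_graph()`) reaches level 9: the cell-based assay concept sits
at level 8, its experimental data at level 9, and the transitive closure of
the two seeds (critical plus annotation edges) spans 30 concepts. Annotation
flags (`publications`, `evidence_ontology`) are expanded to related edges on
the `publication` / `evidence_ontology` concepts at validation, which is how
the figure-style "P"/"E" markers are modelled.

Two transcription choices in the packaged fixtures are worth flagging. In the
genomic chain (`chain_graph()`) the chromosome concept depends critically on
the organism, not on the assembly, which places chromosome-level genomic
sequence at the third dependency layer. And the protein concept keeps
`transcript` and `organism` as critical parents (gene-level information
arrives through the transcript); demoting gene→protein to a related edge, as
some providers' pragmatics would suggest, is possible in a user-supplied
graph without any code change.

## The warehouse: unicity and atomicity

Two principles shape the store. **Unicity**: each real-world entity has
exactly one record per concept, keyed by the concept's declared unicity key.
`upsert_record()` therefore merges rather than duplicates: provenance
accumulates, and non-key annotations from different providers are kept as
per-source rows next to each other instead of overwriting — the critical
identity of a record is separated from its annotations, and no provider wins
by arriving last. This is also what makes two gene providers with overlapping
symbol sets load to exactly the union of their keys. **Atomicity**: sequences
are decomposed to one positional row per nucleotide or amino acid
(`load_sequence()`), which is what makes `region_query()` a direct positional
slice with 1-based closed coordinates (the GFF convention; the store uses it
everywhere).

Cascade deletion follows critical links in reverse, transitively; related
links pointing at deleted records are cleared rather than propagated, because
related edges do not carry integrity. `integrity_check()` re-derives every
structural invariant from scratch (dangling critical links, unicity
collisions, sequence contiguity, versioning-table uniqueness) and is run in
the test suite after every mutating operation on randomized stores.

The store contract is engine-agnostic; this implementation keeps the record
store in memory behind the same operation surface and serializes the complete
logical state with `logical_dump()` — canonical JSON with surrogate ids
remapped to canonical ordinals and timestamps excluded. Two stores loaded
from the same inputs produce byte-identical dumps, which is the package's
operational definition of database-level determinism, and the property the
test suite asserts.

## The orchestrator

Each data source is wrapped in an adapter with three hooks: `check_release()`
(newest version token or nothing), `download(version)`, and
`process(store, payload)`. Version tokens are opaque and compared only for
inequality, since real sources mix dates, release numbers and checksums.

`run_cycle()` visits every source once, in the topological order of the
source graph (the daily-master-script model; continuous scheduling is out of
scope). A source with pending work processes only when every direct parent is
*current* — no known unprocessed release, not failed — and no transitive
ancestor is failed. On success the previous payload is cleaned up and only
then is the version bumped in the versioning table, so a version token in the
table always denotes a fully processed release. On failure the source is
marked failed, its payload kept for diagnosis, and descendants with pending
work are held. Hold is recomputed each cycle rather than stored, which makes
`mark_resolved()` trivial: reset the source and let the next cycle re-derive
eligibility.

One gating question the model had to settle: may a child process its own new
release while an unrelated ancestor is failed? The package says no for
ancestors on the critical path (a failed ancestor holds the whole subtree,
which is the conservative reading of hold-until-resolution) but yes for
parents that simply have no new release — a quiet parent gates nothing.

## BIORJ: closure-complete exchange

`export_biorj()` materializes the dependency closure of a record set as a
document of concept blocks in topological order, with document-local ids
(store surrogate ids never leak), per-record provenance, and a
`source_versions` table that is exactly the deduplicated set of
`(source, version)` pairs occurring in the payload. Related records are
exported one hop beyond the critical closure by default — the annotations *of
the exported records* — with their own critical closures pulled in to keep
the document closure-complete; `related = "transitive"` follows annotation
edges all the way, `"none"` ships the critical skeleton only. Related
references that point outside the document are dropped, critical ones can
never be (the closure guarantees it).

The format is frozen as `format_version` "1.0" and described by a JSON-Schema
file shipped under `inst/extdata/biorj-schema.json`. JSON output has sorted
keys and canonical record order, so identical logical payloads give identical
bytes. Canonical equality (`biorj_equal()`) ignores the generator's instance
id and timestamp and renames local ids — the two fields that legitimately
differ between two exports of the same data. The linearized text form is
line-oriented (header lines plus one tab-delimited, JSON-celled line per
record) and round-trips losslessly through `parse_linear()`.

Import validates first and rejects documents with violations; upserts then
run in block order under unicity merge, so importing a document twice creates
zero records, and importing documents with disjoint payloads commutes. The
store exports whatever it currently holds; embedding upstream-deleted
records for reproducibility snapshots is a property of when you export, not
of the format.

## Sequence applications

`translate_cds()` implements the standard genetic code (NCBI table 1 only;
selenocysteine and alternative codes are out of scope), reports the first
stop strictly before the final codon as premature, and translates ambiguous
codons to `X`.

The A→G editing scanner reflects ADAR biology: adenosines are read as
guanosine after editing, so every adenosine of a mature transcript —
reference or introduced by a variant — is a candidate site.
`enumerate_edit_candidates()` works in sense-strand transcript coordinates;
variants are supplied in plus-strand genomic coordinates and complemented for
minus-strand transcripts. A site that is adenosine in the reference takes
precedence over a variant at the same position, variants whose `ref` allele
contradicts the genome are skipped with a warning, and each candidate is
evaluated with at most the single variant that creates it applied (sites are
independent; phasing is ignored). `classify_edit()` then substitutes A→G and
compares codon translations: `non_coding` outside the CDS,
`no_protein_change` when the translation is unchanged,
`prevents_premature_termination` when a stop strictly upstream of the
terminal codon becomes a coding codon, and `amino_acid_modification`
otherwise. Two boundary cases are folded into the last category by design:
editing the canonical terminal stop (stop-loss) and destroying the start
codon (ATG→GTG) — both alter the protein, neither rescues a premature stop,
and the four-way partition stays exhaustive and disjoint. The classification
is proven equivalent, over the full codon space and both allele origins, to
the definition-level oracle "translate before and after and diff".

`match_oligo()` reports every fully contained alignment window within a
Hamming distance budget (no indels — the oligo use case is exact-length
hybridization), optionally against the reverse complement of the query, with
positions always on the target's own coordinates. Matching is delegated to
`Biostrings::matchPattern()`; the naive sliding-window scan lives in the test
suite as the oracle. Sequence-specific activity weighting of siRNA seeds is
out of scope.

`local_align()` is an affine-gap Smith–Waterman written in full in the
package because its traceback policy is part of the contract: ties break
diagonal > up > left, and within a gap the gap is closed rather than extended
on ties, so the reported alignment is deterministic. A gap of length L costs
`gap_open + L * gap_extend` (the BLAST convention). The score of the empty
alignment is 0; when no residue pair scores positively the result is score 0
with an empty alignment. Substitution matrices are read in NCBI text format;
BLOSUM62 ships with the package. In the tests, `Biostrings`'
`pairwiseAlignment()` serves as an independent dynamic-programming oracle for
the score on random peptide pairs.

## The synthetic ecosystem generator

`generate_ecosystem()` emulates the multi-provider situation the warehouse
exists for, at desk scale: one organism, one 20 kb chromosome, 8 gene loci
(alternating strands, three exons, a frame-preserving skippable middle exon,
2 isoforms per gene), two gene providers whose symbol sets overlap by 50%
(provider B additionally reports its own novel symbols), 40 variants of which
25% are planted premature-stop creators, protein translations, assay and
result tables, and a source-adapter configuration wiring everything to the
orchestrator. These defaults are the package's study conditions; they were
chosen once as a realistic miniature (CDS of 30–50 codons, intron and UTR
sizes in the tens of bases, low allele frequencies for the pathogenic-style
planted variants) and the test suite runs against them.

Determinism is a contract: each output file draws from its own named
pseudo-random stream derived from the master seed, so the same spec produces
byte-identical files and adding a file never perturbs existing ones. The
generator also writes a `ledger.json` with the ground truth it knows by
construction — the union of gene unicity keys and the exact per-isoform list
of planted premature-stop sites. Planted variants convert a TGG codon to TAG
via a transcript-sense G>A (a genomic C>T for minus-strand genes); all other
variants are placed outside every CDS. That placement rule is what makes the
ledger exact: reference CDS are built from non-stop codons, so the *only*
sites the scanner can classify as `prevents_premature_termination` are the
planted ones, and the acceptance suite checks set equality, not overlap.

What the generator does **not** emulate — and what passing tests therefore do
not show — includes: real provider file dialects beyond what the loaders
need, overlapping gene loci and shared exons between genes, multi-chromosome
genomes, indels and multi-nucleotide variants, sequencing noise, and
genome-scale data volumes. The pipeline's correctness arguments are
structural (oracle equivalence, closure properties, determinism), not
benchmarks.

## Numerical and scale choices

Coordinates are 1-based closed intervals everywhere. Degenerate inputs error
early with the valid range in the message (region queries, empty sequences,
CDS length not divisible by 3, non-ACGT oligo queries). The test suite sizes
its property suites to what the oracles can verify exhaustively or
near-exhaustively: 200 random DAGs of up to 12 nodes against a path-
enumeration oracle, 200 scripted 20-source scheduler runs over 3 cycles, 100
randomized stores for cascade deletion, 100 random exports for the BIORJ
fixpoint, the full 64-codon space for edit classification, and 100 random
cases each for oligo matching and local alignment. The whole suite runs in
about two minutes on one CPU.

## Known limitations

* The store is in-memory; persistence is via the deterministic logical dump,
  not a transactional on-disk engine. Concurrency is out of scope.
* The orchestrator models one pass per cycle; there is no calendar, retry
  budget, or parallel execution.
* BIORJ has no cross-version schema migration and no streaming import.
* The edit scanner evaluates sites independently; compound effects of
  multiple variants in one codon are not modelled.
* `local_align()` is plain R and intended for the short sequences the
  package's applications use (oligos, peptides, single proteins), not for
  genome-scale alignment.
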