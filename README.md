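# relmart

A dependency-aware, desk-scale data mart for biological data integration,
with a closure-complete exchange format (BIORJ) and sequence-level
applications.

Biological records depend on each other: a gene only exists within an
organism, a transcript needs its gene and the chromosome sequence, an assay
result needs the assay and — transitively — everything beneath it. `relmart`
makes that dependency structure a first-class object and derives the three
operations that integration pipelines usually improvise from it: a safe
update order across data sources, cascade deletion of records that lose a
critical ancestor, and export/import of any record set *with its complete
dependency closure*.

It is aimed at anyone who maintains a local warehouse of heterogeneous
biological sources (taxonomy, gene catalogs, genome annotation, variants,
assay results) and wants integrity, determinism and exchangeability without a
production ETL stack.

## The model

Scientific concepts form a graph. An edge runs from a parent concept to the
child that depends on it, and is either **critical** (integrity-bearing:
without the parent the child record is scientifically meaningless) or
**related** (augmenting: publications, external identifiers, evidence
codes). The dependency level of a concept is defined over critical edges
only:

```
L(c) = 1                                  if c has no critical parents
L(c) = 1 + max{ L(p) : p critical parent of c }
```

so `L(c)` is one plus the longest critical path from `c` to a root. Levels
drive everything downstream:

* **update order** — sources process parents-first; a child is held while a
  parent has unprocessed work or a transitive ancestor is failed, and a
  source's version is bumped in the versioning table only after successful
  processing;
* **storage** — records obey *unicity* (one record per real-world entity per
  concept, keyed by a unicity key; duplicate submissions merge, with
  per-source annotations kept side by side) and *atomicity* (sequences
  stored one residue per positional row, so any region is a direct slice);
* **exchange** — a BIORJ document carries a record set plus its transitive
  critical closure (and, optionally, related annotations), in topologically
  ordered concept blocks with provenance and per-source versions, as plain
  JSON or a linearized text file;
* **sequence applications** — CDS translation (standard genetic code),
  classification of every adenosine a transcript could carry (reference or
  variant-introduced) by the consequence of an A→G edit
  (`non_coding`, `no_protein_change`, `amino_acid_modification`,
  `prevents_premature_termination`), mismatch-tolerant oligo matching, and
  affine-gap Smith–Waterman local alignment
  (gap of length L costs `gap_open + L * gap_extend`).

## Worked example

```r
library(relmart)

# 1. The packaged dependency map behind exporting a cell-based assay
g <- export_map_graph()
g
#> <concept_graph> with 30 concepts (validated, max level 9)
dependency_level(g, "cell_based_assay")
#> [1] 8
dependency_level(g, "experimental_data")
#> [1] 9
length(dependency_closure(g, c("cell_based_assay", "experimental_data"),
                          include_related = TRUE))
#> [1] 30
```

The cell-based assay concept sits eight dependency layers above the roots,
its experimental data nine; describing the two of them completely requires
30 scientific concepts.

```r
# 2. Generate the synthetic multi-provider ecosystem and load it through
#    the orchestrator (one parent-gated cycle)
dir <- file.path(tempdir(), "eco")
generate_ecosystem(ecosystem_spec(seed = 1), dir)
eco <- load_ecosystem(dir)
glance(eco$store)
#> # A tibble: 1 × 5
#>   n_records n_concepts n_molecules n_sources n_violations
#>       <int>      <int>       <int>     <int>        <int>
#> 1        98          8          17         9            0
```

98 records over 8 concepts, 17 atomically stored molecules (the chromosome
plus 16 proteins), 9 source versions recorded, zero integrity violations —
the two overlapping gene providers merged to the union of their symbols.

```r
# 3. Scan every transcript for A->G editing consequences
models <- transcript_models_from_gff(file.path(dir, "annotation.gff3"),
                                     file.path(dir, "chromosome.fasta"))
vars <- read_variant_table(file.path(dir, "variants.vcf"))
scan <- edit_scan(models, vars)
dplyr::count(scan, category)
#> # A tibble: 4 × 2
#>   category                           n
#>   <fct>                          <int>
#> 1 non_coding                        86
#> 2 no_protein_change                143
#> 3 amino_acid_modification          302
#> 4 prevents_premature_termination    20
```

Of the 551 candidate adenosines, 20 would rescue a premature stop if edited —
exactly the sites the generator planted (G>A variants turning a TGG codon
into TAG), recovered by the scan.

```r
# 4. Export one experimental result with its complete dependency closure
rid <- lookup_record(eco$store, "experimental_result",
                     list(result_id = "RES0001"))
doc <- export_biorj(eco$store, rid)
doc
#> <biorj_document> format 1.0 - 7 concept blocks, 7 records, 7 source versions
```

One requested record pulls in its whole chain — organism, chromosome, gene,
transcript, protein, assay — in topological block order, each block carrying
provenance and source versions; `write_biorj()` / `linearize_biorj()`
serialize it, `import_biorj()` merges it into another warehouse with zero
duplicates.

A thin CLI over the same functions ships at `inst/cli/relmart`
(`generate-ecosystem`, `editscan`, `match`, `query-region`,
`validate-biorj`, `linearize-biorj`).

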