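#' Packaged concept-graph fixtures
#'
#' `export_map_graph()` (alias `fig3_graph()`) returns the curated
#' transcription of the dependency map behind the export of a cell-based
#' assay and its experimental data: 30 scientific concepts over 9 dependency
#' levels, spanning the genomic, proteomic, molecular-entity,
#' disease/anatomy, assay, ontology and scientific-community ecosystems.
#' `chain_graph()` returns the genomic dependency chain
#' organism -> \{genome_assembly, chromosome\} -> genomic_sequence, whose
#' sequence concept sits at the third dependency layer.
#' `ecosystem_graph()` returns the concept graph used by the synthetic toy
#' ecosystem (see [generate_ecosystem()]).
#'
#' The transcriptions are frozen as YAML files under `inst/extdata/`; tests
#' and applications depend on the files, not on any figure.
#'
#' @return A validated `concept_graph`.
#' @examples
#' dependency_level(export_map_graph(), "cell_based_assay")  # 8
#' dependency_level(chain_graph(), "genomic_sequence")       # 3
#' @export
export_map_graph <- function() {
  read_concept_graph(system.file("extdata", "export-map-graph.yaml",
                                 package = "relmart"))
}

#' @rdname export_map_graph
#' @export
fig3_graph <- export_map_graph

#' @rdname export_map_graph
#' @export
chain_graph <- function() {
  read_concept_graph(system.file("extdata", "chain-graph.yaml",
                                 package = "relmart"))
}

#' @rdname export_map_graph
#' @export
ecosystem_graph <- function() {
  read_concept_graph(system.file("extdata", "ecosystem-graph.yaml",
                                 package = "relmart"))
}

#' Parameters of the synthetic toy ecosystem
#'
#' The generator emulates a small multi-provider data ecosystem: one
#' organism, one chromosome, two gene providers with overlapping symbol
#' sets (to exercise unicity merge), spliced transcripts with CDS on both
#' strands, variants including transcript-sense G>A changes that create
#' premature stop codons, protein translations, and assay/result tables.
#'
#' @param seed Integer master seed; the same spec produces byte-identical
#'   files.
#' @param n_genes Gene loci on the chromosome (>= 1).
#' @param n_transcripts_per_gene Isoforms per gene (>= 1): isoform 1 uses
#'   all three exons, isoform 2 skips the (frame-preserving) middle exon,
#'   further isoforms shorten the 3' UTR.
#' @param chromosome_length Chromosome length in nt.
#' @param n_variants Total variants; `premature_stop_variant_fraction` of
#'   them are planted premature-stop creators (TGG -> TAG via a
#'   transcript-sense G>A), the rest fall outside CDS.
#' @param premature_stop_variant_fraction Fraction in `[0, 1]`.
#' @param provider_overlap_fraction Fraction of provider A's symbols also
#'   reported by provider B (B additionally reports its own novel symbols).
#' @return An object of class `ecosystem_spec`.
#' @export
ecosystem_spec <- function(seed = 1L, n_genes = 8L, n_transcripts_per_gene = 2L,
                           chromosome_length = 20000L, n_variants = 40L,
                           premature_stop_variant_fraction = 0.25,
                           provider_overlap_fraction = 0.5) {
  stopifnot(n_genes >= 1L, n_transcripts_per_gene >= 1L,
            chromosome_length >= 1L, n_variants >= 1L,
            premature_stop_variant_fraction >= 0,
            premature_stop_variant_fraction <= 1,
            provider_overlap_fraction >= 0, provider_overlap_fraction <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
                 chromosome_length = as.integer(chromosome_length),
                 n_variants = as.integer(n_variants),
                 premature_stop_variant_fraction = premature_stop_variant_fraction,
                 provider_overlap_fraction = provider_overlap_fraction),
            class = "ecosystem_spec")
}

# One named pseudo-random stream per output file: adding a file never
# perturbs the streams of existing ones.
eco_seed <- function(spec, stream) {
  h <- sum(utf8ToInt(stream) * (seq_len(nchar(stream)) * 131L))
  (spec$seed * 100003L + h) %% 2147483647L
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Generate the synthetic toy ecosystem
#'
#' Writes every input file the other modules need into `out_dir`: taxonomy
#' TSV, two overlapping gene-provider TSVs, chromosome FASTA, GFF3
#' transcript/CDS annotation, VCF variants, protein FASTA, assay and result
#' TSVs, a source-adapter YAML wiring them to the orchestrator, a manifest
#' with per-file MD5 checksums, and a `ledger.json` recording the ground
#' truth the generator knows by construction (the union of gene unicity
#' keys and the exact list of planted premature-stop edit sites) for
#' parameter-recovery-style checks.
#'
#' @param spec An [ecosystem_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
generate_ecosystem <- function(spec = ecosystem_spec(), out_dir) {
  stopifnot(inherits(spec, "ecosystem_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tax_id <- "77133"

  # --- gene structures ------------------------------------------------------
  set.seed(eco_seed(spec, "genes"))
  per_gene_span <- 420L
  if (spec$chromosome_length < spec$n_genes * per_gene_span + 200L) {
    stop("chromosome_length too small for ", spec$n_genes, " gene loci",
         call. = FALSE)
  }
  symbols <- sprintf("GENE%03d", seq_len(spec$n_genes))
  genes <- vector("list", spec$n_genes)
  offset <- 100L
  for (g in seq_len(spec$n_genes)) {
    n_codons <- sample(30:50, 1L)       # incl. terminal stop
    if (n_codons < 7L) stop("CDS shorter than one codon", call. = FALSE)
    body <- sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE)
    codons <- c("ATG", body, "TAA")
    k1 <- sample(3:8, 1L)               # codons in exon 1
    k2 <- sample(5:10, 1L)              # codons in exon 2 (frame-preserving)
    utr5 <- paste(sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"),
                         10L + 2L * max(0L, spec$n_transcripts_per_gene - 2L),
                         replace = TRUE), collapse = "")
    exon1 <- paste0(utr5, paste(codons[1:k1], collapse = ""))
    exon2 <- paste(codons[(k1 + 1L):(k1 + k2)], collapse = "")
    exon3 <- paste0(paste(codons[(k1 + k2 + 1L):length(codons)], collapse = ""),
                    utr3)
    strand <- if (g %% 2L == 0L) "-" else "+"
    intron1 <- paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
                     collapse = "")
    intron2 <- paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
                     collapse = "")
    genes[[g]] <- list(symbol = symbols[[g]], strand = strand,
                       codons = codons, k1 = k1, k2 = k2,
                       exons = c(exon1, exon2, exon3),
                       introns = c(intron1, intron2),
                       utr5 = utr5, utr3 = utr3, start = offset)
    offset <- offset + per_gene_span
  }

  # --- chromosome -----------------------------------------------------------
  set.seed(eco_seed(spec, "chromosome"))
  chrom_v <- sample(c("A", "C", "G", "T"), spec$chromosome_length,
                    replace = TRUE)
  cds_genomic <- logical(spec$chromosome_length)  # positions inside any CDS
  for (g in seq_len(spec$n_genes)) {
    gn <- genes[[g]]
    locus_sense <- paste0(gn$exons[[1L]], gn$introns[[1L]], gn$exons[[2L]],
                          gn$introns[[2L]], gn$exons[[3L]])
    locus <- if (gn$strand == "-") revcomp_chr(locus_sense) else locus_sense
    idx <- gn$start:(gn$start + nchar(locus) - 1L)
    chrom_v[idx] <- strsplit(locus, "", fixed = TRUE)[[1L]]
    genes[[g]]$locus_len <- nchar(locus)
    # exon genomic coordinates, in *sense* (transcription) order
    lens <- nchar(c(gn$exons[[1L]], gn$introns[[1L]], gn$exons[[2L]],
                    gn$introns[[2L]], gn$exons[[3L]]))
    sense_off <- cumsum(c(0L, lens[-5L]))
    exon_rng_sense <- lapply(c(1L, 3L, 5L), function(k) {
      c(sense_off[[k]] + 1L, sense_off[[k]] + lens[[k]])
    })
    if (gn$strand == "+") {
      exon_rng <- lapply(exon_rng_sense, function(r)
        c(gn$start + r[[1L]] - 1L, gn$start + r[[2L]] - 1L))
    } else {
      L <- nchar(locus)
      exon_rng <- lapply(exon_rng_sense, function(r)
        c(gn$start + (L - r[[2L]]), gn$start + (L - r[[1L]])))
    }
    genes[[g]]$exon_rng <- exon_rng  # transcription order
    # CDS genomic mask (for placing non-planted variants outside CDS)
    utr5n <- nchar(gn$utr5); utr3n <- nchar(gn$utr3)
    cds_sense <- c(utr5n + 1L,
                   nchar(locus_sense) - utr3n)  # includes introns in between
    splice_sense <- setdiff(seq(cds_sense[[1L]], cds_sense[[2L]]),
                            c(seq(sense_off[[2L]] + 1L,
                                  sense_off[[2L]] + lens[[2L]]),
                              seq(sense_off[[4L]] + 1L,
                                  sense_off[[4L]] + lens[[4L]])))
    gmap <- if (gn$strand == "+") {
      gn$start + seq_len(nchar(locus_sense)) - 1L
    } else {
      gn$start + nchar(locus_sense) - seq_len(nchar(locus_sense))
    }
    cds_genomic[gmap[splice_sense]] <- TRUE
    genes[[g]]$sense_to_genomic <- gmap
  }

  # --- planted premature-stop variants --------------------------------------
  set.seed(eco_seed(spec, "variants"))
  n_planted <- round(spec$n_variants * spec$premature_stop_variant_fraction)
  planted <- list()
  g_cycle <- rep_len(seq_len(spec$n_genes), n_planted)
  used_codons <- lapply(seq_len(spec$n_genes), function(g) integer())
  for (k in seq_len(n_planted)) {
    g <- g_cycle[[k]]
    gn <- genes[[g]]
    # candidate codons shared by all isoforms: exon 1 (after ATG) and exon 3
    # (before the terminal stop), so skipping exon 2 keeps the site premature
    n_cod <- length(gn$codons)
    cand <- setdiff(c(2:gn$k1, (gn$k1 + gn$k2 + 1L):(n_cod - 1L)),
                    used_codons[[g]])
    if (length(cand) == 0L) next
    ci <- cand[sample.int(length(cand), 1L)]
    used_codons[[g]] <- c(used_codons[[g]], ci)
    genes[[g]]$codons[[ci]] <- "TGG"
    planted[[length(planted) + 1L]] <- list(gene = g, codon = ci)
  }
  # rewrite the chromosome with the TGG codons in place
  for (g in seq_len(spec$n_genes)) {
    gn <- genes[[g]]
    exon1 <- paste0(gn$utr5, paste(gn$codons[1:gn$k1], collapse = ""))
    exon2 <- paste(gn$codons[(gn$k1 + 1L):(gn$k1 + gn$k2)], collapse = "")
    exon3 <- paste0(paste(gn$codons[(gn$k1 + gn$k2 + 1L):length(gn$codons)],
                          collapse = ""), gn$utr3)
    genes[[g]]$exons <- c(exon1, exon2, exon3)
    locus_sense <- paste0(exon1, gn$introns[[1L]], exon2, gn$introns[[2L]],
                          exon3)
    locus <- if (gn$strand == "-") revcomp_chr(locus_sense) else locus_sense
    idx <- gn$start:(gn$start + nchar(locus) - 1L)
    chrom_v[idx] <- strsplit(locus, "", fixed = TRUE)[[1L]]
  }
  # genomic coordinates of the planted G (2nd base of the TGG codon)
  variant_rows <- list()
  ledger_sites <- list()
  for (pl in planted) {
    gn <- genes[[pl$gene]]
    # sense-locus position of the codon's 2nd base
    utr5n <- nchar(gn$utr5)
    cpos_spliced <- (pl$codon - 1L) * 3L + 2L       # within CDS, spliced
    # spliced (exonic) position -> sense-locus position (skip introns)
    cds_off <- utr5n + cpos_spliced
    exon1_cds <- gn$k1 * 3L
    exon2_cds <- gn$k2 * 3L
    in_exon <- if (cpos_spliced <= exon1_cds) 1L else
      if (cpos_spliced <= exon1_cds + exon2_cds) 2L else 3L
    sense_pos <- cds_off +
      (if (in_exon >= 2L) nchar(gn$introns[[1L]]) else 0L) +
      (if (in_exon == 3L) nchar(gn$introns[[2L]]) else 0L)
    gpos <- gn$sense_to_genomic[[sense_pos]]
    ref <- chrom_v[[gpos]]                          # G on +, C on -
    alt <- if (gn$strand == "-") "T" else "A"
    variant_rows[[length(variant_rows) + 1L]] <- tibble::tibble(
      chrom = "chr1", pos = gpos, ref = ref, alt = alt,
      af = round(stats::runif(1L, 0.0001, 0.01), 6), planted = TRUE)
    ledger_sites[[length(ledger_sites) + 1L]] <- list(
      gene = gn$symbol, codon_index = pl$codon, genomic_position = gpos,
      ref = ref, alt = alt)
  }
  # non-planted variants: strictly outside every CDS
  n_other <- spec$n_variants - length(planted)
  non_cds <- which(!cds_genomic)
  other_pos <- sort(sample(non_cds, n_other))
  for (posn in other_pos) {
    ref <- chrom_v[[posn]]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    variant_rows[[length(variant_rows) + 1L]] <- tibble::tibble(
      chrom = "chr1", pos = posn, ref = ref, alt = alt,
      af = round(stats::runif(1L, 0.001, 0.5), 6), planted = FALSE)
  }
  variants <- dplyr::arrange(dplyr::bind_rows(variant_rows), .data$pos,
                             .data$alt)

  # --- write files ----------------------------------------------------------
  writeLines(c("tax_id\tname", paste0(tax_id, "\tToyorganism exemplum")),
             p("taxonomy.tsv"))

  set.seed(eco_seed(spec, "providers"))
  n_shared <- round(spec$n_genes * spec$provider_overlap_fraction)
  shared <- if (n_shared > 0L) sort(sample(symbols, n_shared)) else character()
  novel_b <- sprintf("GENEB%02d", seq_len(max(1L, ceiling(spec$n_genes / 2))))
  gene_tab <- function(syms, provider) {
    c("symbol\ttax_id\tdescription",
      paste0(syms, "\t", tax_id, "\t", provider, " annotation of ", syms))
  }
  writeLines(gene_tab(symbols, "providerA"), p("genes_providerA.tsv"))
  writeLines(gene_tab(c(shared, novel_b), "providerB"), p("genes_providerB.tsv"))

  chrom_seq <- paste(chrom_v, collapse = "")
  writeLines(c(">chr1", substring(chrom_seq,
                                  seq(1L, nchar(chrom_seq), 70L),
                                  pmin(seq(70L, nchar(chrom_seq) + 69L, 70L),
                                       nchar(chrom_seq)))),
             p("chromosome.fasta"))

  gff <- eco_write_gff(genes, spec)
  writeLines(gff, p("annotation.gff3"))

  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                   variants$pos, variants$ref, variants$alt, variants$af))
  writeLines(vcf, p("variants.vcf"))

  models <- transcript_models_from_gff(p("annotation.gff3"),
                                       c(chr1 = chrom_seq))
  prot_lines <- unlist(lapply(models, function(m) {
    tr <- translate_cds(m$spliced_sequence, m$cds_start, m$cds_end)
    c(paste0(">", sub("^tx", "prot", m$transcript_id), " transcript=",
             m$transcript_id), tr$protein)
  }))
  writeLines(prot_lines, p("proteins.fasta"))

  set.seed(eco_seed(spec, "assays"))
  prot_ids <- sub("^tx", "prot", names(models))
  n_assays <- max(2L, spec$n_genes %/% 2L)
  assay_ids <- sprintf("ASSAY%03d", seq_len(n_assays))
  writeLines(c("assay_id\tprotein_id\tformat",
               paste0(assay_ids, "\t",
                      prot_ids[rep_len(seq_along(prot_ids), n_assays)],
                      "\tcell_based")),
             p("assays.tsv"))
  result_ids <- sprintf("RES%04d", seq_len(2L * n_assays))
  writeLines(c("result_id\tassay_id\tvalue\tunit",
               paste0(result_ids, "\t",
                      assay_ids[rep_len(seq_along(assay_ids), length(result_ids))],
                      "\t", round(stats::runif(length(result_ids), 0.01, 99), 3),
                      "\tuM")),
             p("results.tsv"))

  ver <- paste0("v1-seed", spec$seed)
  sources_cfg <- list(
    taxonomy = list(file = "taxonomy.tsv", produces = list("organism"),
                    parents = list(), version = ver),
    gene_a = list(file = "genes_providerA.tsv", produces = list("gene"),
                  parents = list("taxonomy"), version = ver),
    gene_b = list(file = "genes_providerB.tsv", produces = list("gene"),
                  parents = list("taxonomy"), version = ver),
    genome = list(file = "chromosome.fasta", produces = list("chromosome"),
                  parents = list("taxonomy"), version = ver,
                  tax_id = tax_id),
    annotation = list(file = "annotation.gff3", produces = list("transcript"),
                      parents = list("gene_a", "gene_b", "genome"),
                      version = ver),
    variants = list(file = "variants.vcf", produces = list("variant"),
                    parents = list("genome"), version = ver),
    proteins = list(file = "proteins.fasta", produces = list("protein"),
                    parents = list("annotation"), version = ver),
    assays = list(file = "assays.tsv", produces = list("assay"),
                  parents = list("proteins"), version = ver),
    results = list(file = "results.tsv",
                   produces = list("experimental_result"),
                   parents = list("assays"), version = ver))
  yaml::write_yaml(sources_cfg, p("sources.yaml"))

  # ledger: ground truth by construction
  union_symbols <- sort(unique(c(symbols, shared, novel_b)))
  site_rows <- eco_ledger_sites(genes, models, ledger_sites)
  ledger <- list(
    params = unclass(spec),
    gene_symbols_provider_a = as.list(symbols),
    gene_symbols_provider_b = as.list(c(shared, novel_b)),
    gene_key_union = as.list(union_symbols),
    gene_key_union_count = length(union_symbols),
    premature_stop_sites = site_rows)
  writeLines(canonical_json(ledger), p("ledger.json"))

  files <- c("taxonomy.tsv", "genes_providerA.tsv", "genes_providerB.tsv",
             "chromosome.fasta", "annotation.gff3", "variants.vcf",
             "proteins.fasta", "assays.tsv", "results.tsv", "sources.yaml",
             "ledger.json")
  manifest <- tibble::tibble(file = files,
                             md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

# GFF3 lines for all gene loci / isoforms
eco_write_gff <- function(genes, spec) {
  lines <- c("##gff-version 3")
  tx_counter <- 0L
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    rngs <- gn$exon_rng  # transcription order; element = c(start, end) genomic
    gene_start <- min(vapply(rngs, min, numeric(1)))
    gene_end <- max(vapply(rngs, max, numeric(1)))
    gid <- paste0("g", g)
    lines <- c(lines, sprintf(
      "chr1\trelmart\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      gene_start, gene_end, gn$strand, gid, gn$symbol))
    for (iso in seq_len(spec$n_transcripts_per_gene)) {
      tx_counter <- tx_counter + 1L
      tid <- sprintf("tx%03d", tx_counter)
      use <- if (iso == 2L) c(1L, 3L) else c(1L, 2L, 3L)
      utr3_trim <- if (iso > 2L) 2L * (iso - 2L) else 0L
      ex <- rngs[use]
      # trim the 3' UTR end of the last exon for isoforms > 2
      if (utr3_trim > 0L) {
        last <- length(ex)
        if (gn$strand == "+") ex[[last]][[2L]] <- ex[[last]][[2L]] - utr3_trim
        else ex[[last]][[1L]] <- ex[[last]][[1L]] + utr3_trim
      }
      tx_start <- min(vapply(ex, min, numeric(1)))
      tx_end <- max(vapply(ex, max, numeric(1)))
      lines <- c(lines, sprintf(
        "chr1\trelmart\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        tx_start, tx_end, gn$strand, tid, gid))
      for (e in ex) {
        lines <- c(lines, sprintf(
          "chr1\trelmart\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          min(e), max(e), gn$strand, tid))
      }
      # CDS genomic ranges: exon ranges minus the UTRs
      utr5n <- nchar(gn$utr5)
      utr3n <- nchar(gn$utr3) - utr3_trim
      cds_rngs <- eco_cds_ranges(ex, gn$strand, utr5n, utr3n)
      for (cr in cds_rngs) {
        lines <- c(lines, sprintf(
          "chr1\trelmart\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
          cr[[1L]], cr[[2L]], gn$strand, tid))
      }
    }
  }
  lines
}

# clip utr5n nt from the transcript 5' end and utr3n from the 3' end of a
# set of exon ranges given in transcription order
eco_cds_ranges <- function(ex, strand, utr5n, utr3n) {
  lens <- vapply(ex, function(e) max(e) - min(e) + 1L, numeric(1))
  total <- sum(lens)
  cds_t <- c(utr5n + 1L, total - utr3n)  # transcript-coordinate CDS bounds
  out <- list()
  t0 <- 0L
  for (k in seq_along(ex)) {
    t_rng <- c(t0 + 1L, t0 + lens[[k]])
    ov <- c(max(t_rng[[1L]], cds_t[[1L]]), min(t_rng[[2L]], cds_t[[2L]]))
    if (ov[[1L]] <= ov[[2L]]) {
      off <- ov - t_rng[[1L]]  # offsets within the exon, transcript direction
      gr <- if (strand == "+") {
        c(min(ex[[k]]) + off[[1L]], min(ex[[k]]) + off[[2L]])
      } else {
        c(max(ex[[k]]) - off[[2L]], max(ex[[k]]) - off[[1L]])
      }
      out[[length(out) + 1L]] <- gr
    }
    t0 <- t0 + lens[[k]]
  }
  out
}

# expand per-gene planted codons into per-isoform transcript positions
eco_ledger_sites <- function(genes, models, ledger_sites) {
  out <- list()
  for (site in ledger_sites) {
    for (m in models) {
      if (m$gene != site$gene) next
      gpos <- tm_genomic_positions(m)
      tpos <- match(site$genomic_position, gpos)
      if (is.na(tpos)) next  # codon spliced out of this isoform
      out[[length(out) + 1L]] <- list(
        transcript_id = m$transcript_id, transcript_position = tpos,
        genomic_position = site$genomic_position, gene = site$gene,
        ref = site$ref, alt = site$alt)
    }
  }
  out
}

#' Build source adapters from a generated ecosystem directory
#'
#' Reads the `sources.yaml` written by [generate_ecosystem()] and wires each
#' file to the matching loader, producing adapters ready for [scheduler()].
#' Each adapter's release check reports the configured version token; its
#' process hook loads the file into the warehouse.
#'
#' @param dir Directory produced by [generate_ecosystem()].
#' @return Named list of `source_adapter` objects.
#' @export
adapters_from_config <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "sources.yaml"))
  loaders <- list(
    taxonomy = function(store, path, src, ver, entry)
      load_taxonomy_tsv(store, path, src, ver),
    gene_a = function(store, path, src, ver, entry)
      load_gene_tsv(store, path, src, ver),
    gene_b = function(store, path, src, ver, entry)
      load_gene_tsv(store, path, src, ver),
    genome = function(store, path, src, ver, entry)
      load_chromosome_fasta(store, path, src, ver, tax_id = entry$tax_id),
    annotation = function(store, path, src, ver, entry)
      load_transcript_gff(store, path, src, ver),
    variants = function(store, path, src, ver, entry)
      load_variant_vcf(store, path, src, ver),
    proteins = function(store, path, src, ver, entry)
      load_protein_fasta(store, path, src, ver),
    assays = function(store, path, src, ver, entry)
      load_assay_tsv(store, path, src, ver),
    results = function(store, path, src, ver, entry)
      load_result_tsv(store, path, src, ver))
  adapters <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    loader <- loaders[[nm]]
    path <- file.path(dir, entry$file)
    force(entry); force(loader); force(path); force(nm)
    source_adapter(
      name = nm,
      produces = unlist(entry$produces),
      parents = unlist(entry$parents) %||% character(),
      check_release = function() entry$version,
      download = function(version) path,
      process = function(store, payload)
        loader(store, payload, nm, entry$version, entry))
  })
  stats::setNames(adapters, names(cfg))
}

#' Load a full generated ecosystem into a fresh warehouse
#'
#' Convenience wrapper: builds a warehouse over [ecosystem_graph()], wires
#' the adapters and runs one orchestrator cycle, which loads every file
#' parents-first.
#'
#' @param dir Directory produced by [generate_ecosystem()].
#' @return A list: `store` (the loaded `warehouse`), `sched` (the
#'   `scheduler` after one cycle).
#' @export
load_ecosystem <- function(dir) {
  store <- warehouse(ecosystem_graph())
  sched <- scheduler(adapters_from_config(dir))
  run_cycle(sched, store)
  list(store = store, sched = sched)
}

#' Read the generator's ground-truth ledger
#'
#' @param dir Directory produced by [generate_ecosystem()].
#' @return A list: generation parameters, provider symbol lists, the gene
#'   unicity-key union, and the planted premature-stop sites.
#' @export
read_ecosystem_ledger <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "ledger.json"), simplifyVector = FALSE)
}
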