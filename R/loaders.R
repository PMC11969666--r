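#' Loaders: standard-format files into the warehouse
#'
#' Each loader reads one provider file (TSV, FASTA, GFF3, VCF) through the
#' field's standard parser and upserts records of the matching concept, with
#' critical parent links resolved against records already in the store —
#' which is why sources must load parents-first (see [run_cycle()]).
#'
#' @name loaders
NULL

#' @describeIn loaders Taxonomy TSV (`tax_id`, `name`) into `organism`
#'   records.
#' @param store A `warehouse`.
#' @param path File to load.
#' @param source,version Provenance recorded on every touched record.
#' @return Invisibly, a named integer: records created and merged.
#' @export
load_taxonomy_tsv <- function(store, path, source = "taxonomy", version = "0") {
  tab <- utils::read.delim(path, colClasses = "character")
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tab))) {
    res <- upsert_record(store, warehouse_record(
      "organism", list(tax_id = tab$tax_id[[i]]),
      attributes = list(name = tab$name[[i]]),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' @describeIn loaders Gene provider TSV (`symbol`, `tax_id`, `description`)
#'   into `gene` records; organisms must already be loaded.
#' @export
load_gene_tsv <- function(store, path, source, version = "0") {
  tab <- utils::read.delim(path, colClasses = "character")
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tab))) {
    org <- lookup_record(store, "organism", list(tax_id = tab$tax_id[[i]]))
    if (is.null(org)) {
      stop("gene '", tab$symbol[[i]], "': organism tax_id ", tab$tax_id[[i]],
           " not in store", call. = FALSE)
    }
    res <- upsert_record(store, warehouse_record(
      "gene", list(symbol = tab$symbol[[i]]),
      attributes = list(description = tab$description[[i]]),
      parent_links = list(organism = org),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' @describeIn loaders Chromosome FASTA into `chromosome` records with the
#'   sequence stored atomically (one row per nucleotide).
#' @param tax_id Organism the chromosomes belong to.
#' @export
load_chromosome_fasta <- function(store, path, source = "genome",
                                  version = "0", tax_id) {
  seqs <- Biostrings::readDNAStringSet(path)
  org <- lookup_record(store, "organism", list(tax_id = tax_id))
  if (is.null(org)) stop("organism tax_id ", tax_id, " not in store", call. = FALSE)
  counts <- c(created = 0L, merged = 0L)
  for (nm in names(seqs)) {
    name <- strsplit(nm, "\\s+")[[1L]][[1L]]
    res <- upsert_record(store, warehouse_record(
      "chromosome", list(name = name),
      attributes = list(length = length(seqs[[nm]])),
      parent_links = list(organism = org),
      source = source, version = version))
    if (res$status == "created") {
      load_sequence(store, res$record_id, as.character(seqs[[nm]]))
    }
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

# Shared GFF3 reading: returns a tibble of transcripts with list-columns of
# exon and CDS genomic ranges, via rtracklayer.
read_gff_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]]),
    character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[[i]]
    gene_id <- mrna$Parent[[i]]
    gene_name <- genes$Name[match(gene_id, genes$ID)]
    if (is.na(gene_name)) gene_name <- gene_id
    kids <- df[!is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    exons <- kids[kids$type == "exon", c("seqnames", "start", "end", "strand")]
    cds <- kids[kids$type == "CDS", c("seqnames", "start", "end", "strand")]
    strand <- as.character(mrna$strand[[i]])
    # transcription order: ascending starts on +, descending on -
    exons <- exons[order(exons$start, decreasing = (strand == "-")), ]
    tibble::tibble(transcript_id = tid, gene = gene_name,
                   chrom = as.character(mrna$seqnames[[i]]), strand = strand,
                   exons = list(tibble::tibble(
                     chrom = as.character(exons$seqnames),
                     start = exons$start, end = exons$end,
                     strand = strand)),
                   cds = list(tibble::tibble(start = cds$start, end = cds$end)))
  })
  dplyr::bind_rows(out)
}

#' Build spliced transcript models from a GFF3 annotation and a genome
#'
#' Reads gene/mRNA/exon/CDS features (via `rtracklayer`), splices exon
#' sequences in transcription order (reverse-complementing minus-strand
#' transcripts) and maps the CDS onto spliced coordinates.
#'
#' @param gff_path GFF3 file with gene, mRNA, exon and CDS features.
#' @param genome Named character vector of chromosome sequences, or a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return A named list of [transcript_model()] objects.
#' @export
transcript_models_from_gff <- function(gff_path, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, character(1), 1L)
  tx <- read_gff_transcripts(gff_path)
  models <- lapply(seq_len(nrow(tx)), function(i) {
    blocks <- tx$exons[[i]]
    chrseq <- genome[[tx$chrom[[i]]]]
    if (is.null(chrseq)) {
      stop("transcript ", tx$transcript_id[[i]], ": chromosome '",
           tx$chrom[[i]], "' not in genome", call. = FALSE)
    }
    piece <- function(b) {
      s <- substr(chrseq, b$start, b$end)
      if (b$strand == "-") revcomp_chr(s) else s
    }
    spliced <- paste(vapply(seq_len(nrow(blocks)), function(k)
      piece(blocks[k, ]), character(1)), collapse = "")
    gpos <- unlist(lapply(seq_len(nrow(blocks)), function(k) {
      b <- blocks[k, ]
      if (b$strand == "-") seq(b$end, b$start) else seq(b$start, b$end)
    }))
    cds <- tx$cds[[i]]
    cds_genomic <- unlist(lapply(seq_len(nrow(cds)), function(k)
      seq(cds$start[[k]], cds$end[[k]])))
    spliced_cds <- sort(match(cds_genomic, gpos))
    if (any(is.na(spliced_cds)) ||
        !all(diff(spliced_cds) == 1L)) {
      stop("transcript ", tx$transcript_id[[i]],
           ": CDS is not contiguous on the spliced sequence", call. = FALSE)
    }
    transcript_model(tx$transcript_id[[i]], tx$gene[[i]], spliced,
                     min(spliced_cds), max(spliced_cds), blocks)
  })
  stats::setNames(models, tx$transcript_id)
}

#' @describeIn loaders GFF3 annotation into `transcript` records (gene and
#'   chromosome parents resolved in the store).
#' @export
load_transcript_gff <- function(store, path, source = "annotation",
                                version = "0") {
  tx <- read_gff_transcripts(path)
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tx))) {
    gene <- lookup_record(store, "gene", list(symbol = tx$gene[[i]]))
    chrom <- lookup_record(store, "chromosome", list(name = tx$chrom[[i]]))
    if (is.null(gene) || is.null(chrom)) {
      stop("transcript '", tx$transcript_id[[i]],
           "': gene or chromosome parent not in store", call. = FALSE)
    }
    exons <- tx$exons[[i]]
    res <- upsert_record(store, warehouse_record(
      "transcript", list(transcript_id = tx$transcript_id[[i]]),
      attributes = list(strand = tx$strand[[i]],
                        n_exons = nrow(exons),
                        span = paste0(min(exons$start), "-", max(exons$end))),
      parent_links = list(gene = gene, chromosome = chrom),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' Read a VCF-like variant table into a tibble
#'
#' Parses through `vcfR` and returns the minimal per-site table the edit
#' scanner consumes. Multi-allelic ALT entries are split into one row per
#' alternate allele.
#'
#' @param path Path to an (uncompressed) VCF file.
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `af` (NA when absent).
#' @export
read_variant_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  if (length(af) == 0L) af <- rep(NA_real_, nrow(fix))
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[[i]], ",", fixed = TRUE)[[1L]]
    tibble::tibble(chrom = fix$CHROM[[i]], pos = as.integer(fix$POS[[i]]),
                   ref = toupper(fix$REF[[i]]), alt = toupper(alts),
                   af = af[[i]])
  })
  dplyr::bind_rows(rows)
}

#' @describeIn loaders VCF variants into `variant` records (chromosome
#'   parent resolved in the store). Only single-nucleotide `ref`/`alt` pairs
#'   are stored.
#' @export
load_variant_vcf <- function(store, path, source = "variants", version = "0") {
  tab <- read_variant_table(path)
  tab <- tab[nchar(tab$ref) == 1L & nchar(tab$alt) == 1L, , drop = FALSE]
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tab))) {
    chrom <- lookup_record(store, "chromosome", list(name = tab$chrom[[i]]))
    if (is.null(chrom)) {
      stop("variant at ", tab$chrom[[i]], ":", tab$pos[[i]],
           ": chromosome not in store", call. = FALSE)
    }
    attrs <- if (is.na(tab$af[[i]])) list() else list(af = tab$af[[i]])
    res <- upsert_record(store, warehouse_record(
      "variant", list(chrom = tab$chrom[[i]], pos = tab$pos[[i]],
                      ref = tab$ref[[i]], alt = tab$alt[[i]]),
      attributes = attrs,
      parent_links = list(chromosome = chrom),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' @describeIn loaders Protein FASTA into `protein` records with atomic
#'   amino-acid rows; FASTA names must be `<protein_id> transcript=<id>`.
#' @export
load_protein_fasta <- function(store, path, source = "proteins",
                               version = "0") {
  seqs <- Biostrings::readAAStringSet(path)
  counts <- c(created = 0L, merged = 0L)
  for (nm in names(seqs)) {
    parts <- strsplit(nm, "\\s+")[[1L]]
    pid <- parts[[1L]]
    txid <- sub("^transcript=", "", parts[grepl("^transcript=", parts)][1L])
    tx <- lookup_record(store, "transcript", list(transcript_id = txid))
    if (is.null(tx)) {
      stop("protein '", pid, "': transcript ", txid, " not in store",
           call. = FALSE)
    }
    res <- upsert_record(store, warehouse_record(
      "protein", list(protein_id = pid),
      attributes = list(length = length(seqs[[nm]])),
      parent_links = list(transcript = tx),
      source = source, version = version))
    if (res$status == "created") {
      load_sequence(store, res$record_id, as.character(seqs[[nm]]))
    }
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' @describeIn loaders Assay TSV (`assay_id`, `protein_id`, `format`) into
#'   `assay` records.
#' @export
load_assay_tsv <- function(store, path, source = "assays", version = "0") {
  tab <- utils::read.delim(path, colClasses = "character")
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tab))) {
    prot <- lookup_record(store, "protein", list(protein_id = tab$protein_id[[i]]))
    if (is.null(prot)) {
      stop("assay '", tab$assay_id[[i]], "': protein not in store", call. = FALSE)
    }
    res <- upsert_record(store, warehouse_record(
      "assay", list(assay_id = tab$assay_id[[i]]),
      attributes = list(format = tab$format[[i]]),
      parent_links = list(protein = prot),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}

#' @describeIn loaders Result TSV (`result_id`, `assay_id`, `value`, `unit`)
#'   into `experimental_result` records.
#' @export
load_result_tsv <- function(store, path, source = "results", version = "0") {
  tab <- utils::read.delim(path, colClasses = "character")
  counts <- c(created = 0L, merged = 0L)
  for (i in seq_len(nrow(tab))) {
    assay <- lookup_record(store, "assay", list(assay_id = tab$assay_id[[i]]))
    if (is.null(assay)) {
      stop("result '", tab$result_id[[i]], "': assay not in store", call. = FALSE)
    }
    res <- upsert_record(store, warehouse_record(
      "experimental_result", list(result_id = tab$result_id[[i]]),
      attributes = list(value = tab$value[[i]], unit = tab$unit[[i]]),
      parent_links = list(assay = assay),
      source = source, version = version))
    counts[[res$status]] <- counts[[res$status]] + 1L
  }
  invisible(counts)
}
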