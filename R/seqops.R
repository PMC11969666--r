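#' Spliced transcript model
#'
#' Holds the sense-strand spliced mRNA sequence (DNA alphabet), the CDS
#' coordinates on that spliced sequence (1-based, closed), and the ordered
#' genomic blocks (exons in transcription order) that map spliced positions
#' to genomic positions. For minus-strand transcripts the blocks walk the
#' chromosome rightmost-first and genomic positions decrease along the
#' transcript.
#'
#' @param transcript_id Transcript identifier.
#' @param gene Gene identifier the transcript belongs to.
#' @param spliced_sequence Sense-strand mRNA sequence, DNA alphabet (ACGT).
#' @param cds_start,cds_end 1-based inclusive CDS bounds on the spliced
#'   sequence; the CDS length must be a multiple of 3.
#' @param genomic_blocks Tibble/data frame with columns `chrom`, `start`,
#'   `end`, `strand`, in transcription order; block lengths must sum to the
#'   spliced length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, spliced_sequence,
                             cds_start, cds_end, genomic_blocks) {
  spliced_sequence <- toupper(spliced_sequence)
  n <- nchar(spliced_sequence)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end > n || cds_start > cds_end) {
    stop("transcript ", transcript_id, ": CDS [", cds_start, ", ", cds_end,
         "] outside spliced sequence of length ", n, call. = FALSE)
  }
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("transcript ", transcript_id, ": CDS length not divisible by 3",
         call. = FALSE)
  }
  gb <- tibble::as_tibble(genomic_blocks)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(gb)))
  if (sum(gb$end - gb$start + 1L) != n) {
    stop("transcript ", transcript_id,
         ": genomic block lengths do not sum to the spliced length",
         call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, gene = gene,
                 spliced_sequence = spliced_sequence,
                 cds_start = cds_start, cds_end = cds_end,
                 genomic_blocks = gb),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "(gene", x$gene, "):",
      nchar(x$spliced_sequence), "nt spliced, CDS", x$cds_start, "-",
      x$cds_end, ",", nrow(x$genomic_blocks), "block(s),",
      x$genomic_blocks$strand[[1L]], "strand\n")
  invisible(x)
}

# genomic position of every spliced position, in transcript order
tm_genomic_positions <- function(model) {
  unlist(lapply(seq_len(nrow(model$genomic_blocks)), function(i) {
    b <- model$genomic_blocks[i, ]
    if (b$strand == "-") seq(b$end, b$start) else seq(b$start, b$end)
  }))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  paste(rev(unname(COMPLEMENT[strsplit(toupper(x), "", fixed = TRUE)[[1L]]])),
        collapse = "")
}

#' Translate a coding sequence
#'
#' Standard genetic code (NCBI translation table 1), codon by codon. A stop
#' codon strictly before the final codon of the CDS is reported as a
#' premature stop; the terminal stop (if any) is not part of the returned
#' protein string. Codons containing ambiguous or non-ACGT characters
#' translate to `X`.
#'
#' @param sequence Nucleotide string (DNA alphabet) carrying the CDS.
#' @param cds_start,cds_end 1-based inclusive CDS bounds within `sequence`;
#'   length must be a multiple of 3.
#' @return A list: `protein` (amino acids, internal stops as `*`, terminal
#'   stop stripped), `premature_stop` (1-based codon index of the first
#'   internal stop, or `NA`), and `codons` (character vector of the codons).
#' @examples
#' translate_cds("ATGTGGTAA", 1, 9)$protein  # "MW"
#' @export
translate_cds <- function(sequence, cds_start = 1L, cds_end = nchar(sequence)) {
  sequence <- toupper(sequence)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end > nchar(sequence) || cds_start > cds_end) {
    stop("CDS bounds outside sequence", call. = FALSE)
  }
  len <- cds_end - cds_start + 1L
  if (len %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  cds <- substr(sequence, cds_start, cds_end)
  codons <- substring(cds, seq(1L, len, 3L), seq(3L, len, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  n <- length(aa)
  internal_stops <- which(aa == "*" & seq_len(n) < n)
  premature <- if (length(internal_stops) > 0L) internal_stops[[1L]] else NA_integer_
  protein <- paste(if (aa[[n]] == "*") aa[-n] else aa, collapse = "")
  list(protein = protein, premature_stop = premature, codons = codons)
}

# effective spliced sequence with (at most) one variant applied; each edit
# site is evaluated independently, with only the variant creating it in place
tm_effective_sequence <- function(model, position, allele_origin, variants) {
  seqv <- strsplit(model$spliced_sequence, "", fixed = TRUE)[[1L]]
  if (allele_origin == "variant") {
    gpos <- tm_genomic_positions(model)
    strand <- model$genomic_blocks$strand[[1L]]
    hit <- variants[variants$chrom == model$genomic_blocks$chrom[[1L]] &
                      variants$pos == gpos[[position]], , drop = FALSE]
    sense_alt <- if (strand == "-") unname(COMPLEMENT[hit$alt]) else hit$alt
    hit <- hit[sense_alt == "A", , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop("no variant with sense-strand alt A at transcript position ",
           position, call. = FALSE)
    }
    seqv[[position]] <- "A"
  }
  seqv
}

#' Enumerate candidate A-to-G editing sites on a transcript
#'
#' ADAR-style editing deaminates adenosines to inosine, read as guanine by
#' the ribosome; every adenosine of the mature transcript is therefore a
#' candidate site. Candidates are every spliced position whose sense-strand
#' reference base is `A`, plus every position where a variant's alt allele is
#' `A` on the transcript's sense strand (variants on the chromosome's plus
#' strand are complemented for minus-strand transcripts). Positions are
#' sorted; a position that is both reference-A and variant-A is reported once
#' with `allele_origin = "reference"`.
#'
#' Variants whose `ref` allele disagrees with the transcript's reference base
#' at the mapped position are skipped with a warning.
#'
#' @param model A `transcript_model`.
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `af`), 1-based genomic coordinates on the plus strand.
#' @return A tibble: `transcript_position`, `genomic_position`,
#'   `allele_origin` (`"reference"` or `"variant"`).
#' @export
enumerate_edit_candidates <- function(model, variants = NULL) {
  stopifnot(inherits(model, "transcript_model"))
  seqv <- strsplit(model$spliced_sequence, "", fixed = TRUE)[[1L]]
  gpos <- tm_genomic_positions(model)
  ref_pos <- which(seqv == "A")
  out <- tibble::tibble(transcript_position = ref_pos,
                        genomic_position = gpos[ref_pos],
                        allele_origin = rep("reference", length(ref_pos)))
  if (!is.null(variants) && nrow(variants) > 0L) {
    strand <- model$genomic_blocks$strand[[1L]]
    chrom <- model$genomic_blocks$chrom[[1L]]
    v <- variants[variants$chrom == chrom & variants$pos %in% gpos, , drop = FALSE]
    if (nrow(v) > 0L) {
      tpos <- match(v$pos, gpos)
      sense_ref <- if (strand == "-") unname(COMPLEMENT[toupper(v$ref)]) else toupper(v$ref)
      sense_alt <- if (strand == "-") unname(COMPLEMENT[toupper(v$alt)]) else toupper(v$alt)
      mismatch <- sense_ref != seqv[tpos]
      if (any(mismatch)) {
        warning(sum(mismatch), " variant(s) skipped: ref allele does not ",
                "match the transcript reference base", call. = FALSE)
      }
      keep <- !mismatch & sense_alt == "A"
      var_tbl <- tibble::tibble(transcript_position = tpos[keep],
                                genomic_position = v$pos[keep],
                                allele_origin = rep("variant", sum(keep)))
      out <- dplyr::bind_rows(out, var_tbl)
    }
  }
  out |>
    dplyr::arrange(.data$transcript_position,
                   .data$allele_origin) |>  # "reference" < "variant"
    dplyr::distinct(.data$transcript_position, .keep_all = TRUE)
}

EDIT_CATEGORIES <- c("non_coding", "no_protein_change",
                     "amino_acid_modification", "prevents_premature_termination")

#' Classify the consequence of editing one adenosine to guanine
#'
#' Builds the effective transcript (reference sequence, with the variant
#' allele substituted when `allele_origin = "variant"`), requires the site to
#' be `A`, substitutes `A -> G` at the site, and compares the codon
#' translation before and after:
#' outside the CDS the site is `non_coding`; a codon translating identically
#' is `no_protein_change`; a premature stop codon (strictly upstream of the
#' CDS's final codon) turned into a coding codon is
#' `prevents_premature_termination`; everything else — including stop-loss at
#' the canonical terminal stop and start-codon disruption — is
#' `amino_acid_modification`.
#'
#' @param model A `transcript_model`.
#' @param position Spliced transcript position of the candidate adenosine.
#' @param allele_origin `"reference"` or `"variant"`.
#' @param variants Variant tibble (required when `allele_origin` is
#'   `"variant"`); see [enumerate_edit_candidates()].
#' @return A one-row tibble (an edit-site call): `transcript_id`,
#'   `transcript_position`, `genomic_position`, `allele_origin`,
#'   `codon_before`, `codon_after`, `category`.
#' @export
classify_edit <- function(model, position, allele_origin = "reference",
                          variants = NULL) {
  stopifnot(inherits(model, "transcript_model"))
  position <- as.integer(position)
  allele_origin <- match.arg(allele_origin, c("reference", "variant"))
  seqv <- tm_effective_sequence(model, position, allele_origin, variants)
  if (seqv[[position]] != "A") {
    stop("site base at transcript position ", position,
         " is not A in the effective sequence", call. = FALSE)
  }
  gpos <- tm_genomic_positions(model)[[position]]
  call_row <- function(category, codon_before = NA_character_,
                       codon_after = NA_character_) {
    tibble::tibble(transcript_id = model$transcript_id,
                   transcript_position = position, genomic_position = gpos,
                   allele_origin = allele_origin, codon_before = codon_before,
                   codon_after = codon_after,
                   category = factor(category, levels = EDIT_CATEGORIES))
  }
  if (position < model$cds_start || position > model$cds_end) {
    return(call_row("non_coding"))
  }
  offset <- position - model$cds_start
  codon_idx <- offset %/% 3L
  codon_from <- model$cds_start + codon_idx * 3L
  codon_before <- paste(seqv[codon_from:(codon_from + 2L)], collapse = "")
  edited <- seqv
  edited[[position]] <- "G"
  codon_after <- paste(edited[codon_from:(codon_from + 2L)], collapse = "")
  n_codons <- (model$cds_end - model$cds_start + 1L) %/% 3L
  aa_before <- unname(Biostrings::GENETIC_CODE[codon_before])
  aa_after <- unname(Biostrings::GENETIC_CODE[codon_after])
  category <- if (identical(aa_before, aa_after)) {
    "no_protein_change"
  } else if (identical(aa_before, "*") && codon_idx + 1L < n_codons &&
             !identical(aa_after, "*")) {
    "prevents_premature_termination"
  } else {
    "amino_acid_modification"
  }
  call_row(category, codon_before, codon_after)
}

#' Scan transcripts for A-to-G editing consequences
#'
#' Convenience pipeline: enumerates candidate adenosines on every transcript
#' ([enumerate_edit_candidates()]) and classifies each one
#' ([classify_edit()]).
#'
#' @param models A `transcript_model` or list of them.
#' @param variants Optional variant tibble; see
#'   [enumerate_edit_candidates()].
#' @return A tibble of edit-site calls, one row per candidate site.
#' @export
edit_scan <- function(models, variants = NULL) {
  if (inherits(models, "transcript_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    cand <- enumerate_edit_candidates(m, variants)
    if (nrow(cand) == 0L) return(NULL)
    dplyr::bind_rows(lapply(seq_len(nrow(cand)), function(i) {
      classify_edit(m, cand$transcript_position[[i]],
                    cand$allele_origin[[i]], variants)
    }))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(tibble::tibble(transcript_id = character(),
                          transcript_position = integer(),
                          genomic_position = integer(),
                          allele_origin = character(),
                          codon_before = character(),
                          codon_after = character(),
                          category = factor(character(),
                                            levels = EDIT_CATEGORIES)))
  }
  dplyr::bind_rows(rows)
}

#' Plot the category spectrum of an edit scan
#'
#' @param object A tibble produced by [edit_scan()].
#' @param ... Unused.
#' @return A ggplot bar chart of edit-site categories split by allele origin.
#' @export
plot_edit_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category,
                                       fill = .data$allele_origin)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = NULL, y = "candidate adenosines",
                  fill = "allele origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Match an oligonucleotide against transcripts with mismatches
#'
#' Reports every alignment window of the query on each target with Hamming
#' distance at most `max_mismatch` (no indels), 1-based on the target. With
#' `search_revcomp = TRUE` the reverse complement of the query is searched
#' too and hits are reported with orientation `"-"` (positions still on the
#' target's own coordinates).
#'
#' @param query Oligo sequence (ACGT only).
#' @param targets Named character vector of target sequences, a
#'   `DNAStringSet`, or a (list of) `transcript_model` (spliced sequences are
#'   used, named by transcript id).
#' @param max_mismatch Maximum Hamming distance (>= 0).
#' @param search_revcomp Also search the reverse complement of the query?
#' @return A tibble: `target`, `position`, `orientation` (`"+"`/`"-"`),
#'   `mismatches`, sorted by target, position, orientation.
#' @export
match_oligo <- function(query, targets, max_mismatch = 0L,
                        search_revcomp = FALSE) {
  query <- toupper(query)
  if (!grepl("^[ACGT]+$", query)) {
    stop("query must contain only A, C, G, T", call. = FALSE)
  }
  if (inherits(targets, "transcript_model")) targets <- list(targets)
  if (is.list(targets) && all(vapply(targets, inherits, logical(1),
                                     "transcript_model"))) {
    targets <- stats::setNames(
      vapply(targets, `[[`, character(1), "spliced_sequence"),
      vapply(targets, `[[`, character(1), "transcript_id"))
  }
  if (inherits(targets, "DNAStringSet")) {
    targets <- stats::setNames(as.character(targets), names(targets))
  }
  targets <- toupper(targets)
  if (is.null(names(targets))) {
    names(targets) <- paste0("target_", seq_along(targets))
  }
  if (nchar(query) > min(nchar(targets))) {
    stop("query is longer than the shortest target", call. = FALSE)
  }
  max_mismatch <- as.integer(max_mismatch)
  stopifnot(max_mismatch >= 0L)
  queries <- c("+" = query)
  if (isTRUE(search_revcomp)) queries <- c(queries, "-" = revcomp_chr(query))
  rows <- list()
  for (tn in names(targets)) {
    subject <- Biostrings::DNAString(targets[[tn]])
    for (orient in names(queries)) {
      pat <- Biostrings::DNAString(queries[[orient]])
      hits <- Biostrings::matchPattern(pat, subject,
                                       max.mismatch = max_mismatch,
                                       with.indels = FALSE)
      starts <- Biostrings::start(hits)
      # windows must lie fully inside the target (no edge overhang)
      starts <- starts[starts >= 1L &
                         starts + length(pat) - 1L <= length(subject)]
      if (length(starts) == 0L) next
      mm <- vapply(starts, function(s)
        Biostrings::neditStartingAt(pat, subject, starting.at = s), integer(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = tn, position = as.integer(starts), orientation = orient,
        mismatches = mm)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(target = character(), position = integer(),
                          orientation = character(), mismatches = integer()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$target, .data$position, .data$orientation)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST (`#` comment lines, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(m) <- vapply(rows, `[[`, character(1), 1L)
  colnames(m) <- header
  m
}

#' The BLOSUM62 substitution matrix
#'
#' Loaded from the NCBI-format text file shipped with the package.
#'
#' @return A numeric matrix.
#' @export
blosum62 <- function() {
  read_substitution_matrix(system.file("extdata", "BLOSUM62.txt",
                                       package = "relmart"))
}

#' Affine-gap Smith-Waterman local alignment
#'
#' Optimal local alignment by dynamic programming with affine gap costs: a
#' gap of length L costs `gap_open + L * gap_extend` (both subtracted;
#' BLAST's convention). The score is never negative; when no residue pair
#' scores positively, the score is 0 and the alignment is empty. Traceback
#' starts from the global maximum of the DP matrix and breaks ties
#' diagonal > up > left, yielding one deterministic optimal alignment.
#'
#' @param seq_a,seq_b Non-empty sequences over the matrix alphabet.
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `local_alignment`: `score`, aligned strings
#'   `alignment_a` / `alignment_b` (with `-` for gaps), and 1-based
#'   coordinates `a_start`, `a_end`, `b_start`, `b_end` (0s when empty).
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
local_align <- function(seq_a, seq_b, submat = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) == 0L || length(b) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  alien <- setdiff(c(a, b), rownames(submat))
  if (length(alien) > 0L) {
    stop("symbol(s) absent from the substitution matrix: ",
         paste(unique(alien), collapse = ", "), call. = FALSE)
  }
  n <- length(a); m <- length(b)
  NEG <- -1e9
  open_cost <- gap_open + gap_extend  # first gapped residue pays open + extend
  # Gotoh recurrences: H = best local score at (i, j) in any state;
  # F ends in a gap in seq_b (consumes a; traceback "up"),
  # E ends in a gap in seq_a (consumes b; traceback "left").
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F_ <- matrix(NEG, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    si <- submat[a[[i]], b]
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open_cost,
                               E[i + 1L, j] - gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - open_cost,
                                F_[i, j + 1L] - gap_extend)
      H[i + 1L, j + 1L] <- max(0, H[i, j] + si[[j]],
                               F_[i + 1L, j + 1L], E[i + 1L, j + 1L])
    }
  }
  score <- max(H)
  if (score <= 0) {
    return(structure(list(score = 0, alignment_a = "", alignment_b = "",
                          a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L),
                     class = "local_alignment"))
  }
  # global maximum; among ties, the smallest (i, j)
  idx <- which(H == score, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  i <- idx[1L, 1L]; j <- idx[1L, 2L]
  a_end <- i - 1L; b_end <- j - 1L
  al_a <- character(); al_b <- character()
  state <- "H"
  repeat {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag_ok <- i > 1L && j > 1L &&
        H[i, j] == H[i - 1L, j - 1L] + submat[a[[i - 1L]], b[[j - 1L]]]
      if (diag_ok) {                       # tie-break: diagonal first
        al_a <- c(a[[i - 1L]], al_a); al_b <- c(b[[j - 1L]], al_b)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == F_[i, j]) {    # then up
        state <- "F"
      } else {                             # then left
        state <- "E"
      }
    } else if (state == "F") {
      al_a <- c(a[[i - 1L]], al_a); al_b <- c("-", al_b)
      close <- H[i - 1L, j] - open_cost == F_[i, j]
      i <- i - 1L
      state <- if (close) "H" else "F"     # prefer closing the gap on ties
    } else {
      al_a <- c("-", al_a); al_b <- c(b[[j - 1L]], al_b)
      close <- H[i, j - 1L] - open_cost == E[i, j]
      j <- j - 1L
      state <- if (close) "H" else "E"
    }
  }
  structure(list(score = score,
                 alignment_a = paste(al_a, collapse = ""),
                 alignment_b = paste(al_b, collapse = ""),
                 a_start = i, a_end = a_end,
                 b_start = j, b_end = b_end),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("Local alignment, score", x$score, "\n")
  if (nzchar(x$alignment_a)) {
    marks <- mapply(function(p, q) if (p == q) "|" else " ",
                    strsplit(x$alignment_a, "")[[1L]],
                    strsplit(x$alignment_b, "")[[1L]])
    cat("  a[", x$a_start, "-", x$a_end, "] ", x$alignment_a, "\n",
        "              ", paste(marks, collapse = ""), "\n",
        "  b[", x$b_start, "-", x$b_end, "] ", x$alignment_b, "\n", sep = "")
  } else {
    cat("  (empty alignment)\n")
  }
  invisible(x)
}

#' @export
glance.local_alignment <- function(x, ...) {
  tibble::tibble(score = x$score, length = nchar(x$alignment_a),
                 a_start = x$a_start, a_end = x$a_end,
                 b_start = x$b_start, b_end = x$b_end)
}
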