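simple_model <- function(seqstr, cds_start, cds_end, strand = "+",
                         chrom = "chr1", start = 1L) {
  transcript_model("tx1", "g1", seqstr, cds_start, cds_end,
                   data.frame(chrom = chrom, start = start,
                              end = start + nchar(seqstr) - 1L,
                              strand = strand))
}

test_that("translation follows the standard genetic code for all 64 codons", {
  for (codon in ALL_CODONS) {
    tr <- translate_cds(paste0("ATG", codon, "TAA"), 1, 9)
    expect_identical(substr(paste0(tr$protein, "*"), 2, 2),
                     NCBI_TABLE1[[codon]])
  }
  expect_identical(translate_cds("ATGTAA", 1, 6)$protein, "M")
  expect_true(is.na(translate_cds("ATGTAA", 1, 6)$premature_stop))
  expect_identical(translate_cds("ATGTAATGGTAA", 1, 12)$premature_stop, 2L)
  expect_identical(translate_cds("ATGNNNTAA", 1, 9)$protein, "MX")
  expect_error(translate_cds("ATGTA", 1, 5), "divisible by 3")
})

test_that("random CDS translation matches the naive per-codon oracle", {
  set.seed(606)
  for (rep in 1:10) {
    cds <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    tr <- translate_cds(cds, 1, 300)
    aa <- oracle_translate(cds)
    want <- paste(if (aa[[length(aa)]] == "*") aa[-length(aa)] else aa,
                  collapse = "")
    expect_identical(tr$protein, want)
  }
})

test_that("candidate enumeration finds reference and variant adenosines", {
  m <- simple_model("CCGGCC", 1, 6)
  expect_identical(nrow(enumerate_edit_candidates(m)), 0L)

  m <- simple_model("ACGTTA", 1, 6)
  cand <- enumerate_edit_candidates(m)
  expect_identical(cand$transcript_position, c(1L, 6L))
  expect_true(all(cand$allele_origin == "reference"))

  # a G>A variant adds a variant-origin candidate; reference takes precedence
  vars <- tibble::tibble(chrom = "chr1", pos = c(2L, 1L), ref = c("C", "A"),
                         alt = c("A", "G"), af = NA_real_)
  cand <- enumerate_edit_candidates(m, vars)
  expect_identical(cand$transcript_position, c(1L, 2L, 6L))
  expect_identical(cand$allele_origin[[1L]], "reference")
  expect_identical(cand$allele_origin[[2L]], "variant")

  # mismatching ref allele is skipped with a warning
  badvars <- tibble::tibble(chrom = "chr1", pos = 3L, ref = "T", alt = "A",
                            af = NA_real_)
  expect_warning(cand <- enumerate_edit_candidates(m, badvars), "skipped")
  expect_identical(nrow(cand), 2L)
})

test_that("minus-strand transcripts map and complement variants correctly", {
  # genome plus strand 11..14 is TTAC; the minus-strand transcript reads the
  # reverse complement GTAA, so sense positions 1..4 map to genomic
  # 14, 13, 12, 11
  m <- transcript_model("tx1", "g1", "GTAA", 1, 3,
                        data.frame(chrom = "chr1", start = 11, end = 14,
                                   strand = "-"))
  cand <- enumerate_edit_candidates(m)
  expect_identical(cand$transcript_position, c(3L, 4L))
  expect_identical(cand$genomic_position, c(12L, 11L))
  # a genomic A>T variant at position 13 reads T>A on the sense strand,
  # adding a variant-origin adenosine at transcript position 2
  vars <- tibble::tibble(chrom = "chr1", pos = 13L, ref = "A", alt = "T",
                         af = NA_real_)
  cand <- enumerate_edit_candidates(m, vars)
  expect_identical(cand$transcript_position, c(2L, 3L, 4L))
  expect_identical(cand$allele_origin, c("variant", "reference", "reference"))
})

test_that("brute-force position scan agrees with candidate enumeration", {
  set.seed(707)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:10) {
    n <- 60L
    genome <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1L)
    sense <- if (strand == "-") {
      paste(rev(unname(comp[strsplit(genome, "")[[1L]]])), collapse = "")
    } else genome
    m <- transcript_model("tx", "g", sense, 4, 57,
                          data.frame(chrom = "c", start = 1, end = n,
                                     strand = strand))
    # random variants consistent with the genome
    pos <- sample(n, 8L)
    gbase <- strsplit(genome, "")[[1L]][pos]
    alt <- vapply(gbase, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    vars <- tibble::tibble(chrom = "c", pos = pos, ref = gbase, alt = alt,
                           af = NA_real_)
    cand <- enumerate_edit_candidates(m, vars)
    # oracle: per-position exhaustive scan
    sense_v <- strsplit(sense, "")[[1L]]
    gpos <- if (strand == "-") seq(n, 1) else seq(1, n)
    want <- integer()
    origin <- character()
    for (tp in seq_len(n)) {
      if (sense_v[[tp]] == "A") {
        want <- c(want, tp); origin <- c(origin, "reference")
      } else {
        hit <- vars[vars$pos == gpos[[tp]], ]
        sa <- if (strand == "-") unname(comp[hit$alt]) else hit$alt
        if (nrow(hit) > 0L && any(sa == "A")) {
          want <- c(want, tp); origin <- c(origin, "variant")
        }
      }
    }
    expect_identical(cand$transcript_position, want)
    expect_identical(cand$allele_origin, origin)
  }
})

test_that("edit classification covers the synonymous / missense / stop cases", {
  # GCA codon, edit its 3rd base: GCG, Ala -> Ala
  m <- simple_model(paste0("ATG", "GCA", "TAA"), 1, 9)
  call <- classify_edit(m, 6)
  expect_identical(as.character(call$category), "no_protein_change")
  expect_identical(call$codon_before, "GCA")
  expect_identical(call$codon_after, "GCG")

  # premature TAG created by a G>A variant; editing its A gives TGG (Trp)
  m <- simple_model(paste0("ATG", "TGG", "AAA", "TAA"), 1, 12)
  vars <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "G", alt = "A",
                         af = NA_real_)
  call <- classify_edit(m, 5, "variant", vars)
  expect_identical(as.character(call$category),
                   "prevents_premature_termination")
  expect_identical(call$codon_before, "TAG")
  expect_identical(call$codon_after, "TGG")

  # editing the adenosine of a terminal TGA stop is a stop-loss
  # (TGA -> TGG, Trp), not a stop prevention
  m <- simple_model(paste0("ATG", "TGA"), 1, 6)
  call <- classify_edit(m, 6)
  expect_identical(as.character(call$category), "amino_acid_modification")
  expect_identical(call$codon_after, "TGG")

  # outside the CDS
  m <- simple_model(paste0("A", "ATGTAA", "A"), 2, 7)
  expect_identical(as.character(classify_edit(m, 1)$category), "non_coding")

  # a non-A site is an error
  expect_error(classify_edit(m, 3), "not A")
})

test_that("classification equals the translate-and-diff oracle on all codons", {
  for (codon in ALL_CODONS) {
    apos <- which(strsplit(codon, "")[[1L]] == "A")
    for (ap in apos) {
      seqstr <- paste0("CC", "ATG", codon, "TAA", "CC")
      pos <- 5L + ap
      m <- simple_model(seqstr, 3, 11)
      call <- classify_edit(m, pos)
      expect_identical(as.character(call$category),
                       oracle_classify(seqstr, 3L, 11L, pos))
    }
  }
})

test_that("oligo matching reports exact and mismatched windows", {
  t <- c(tx1 = "ACGTACGTT")
  hits <- match_oligo("GTAC", t)
  expect_identical(hits$position, 3L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(nrow(match_oligo("AAAA", t)), 0L)
  hits <- match_oligo("ACGA", t, max_mismatch = 1L)
  expect_identical(hits$position, c(1L, 5L))
  expect_identical(hits$mismatches, c(1L, 1L))
  # reverse-complement search; AACGTAC does not occur forward in t
  hits <- match_oligo("GTACGTT", t, search_revcomp = TRUE)
  expect_identical(hits$orientation, "+")
  rc_hits <- match_oligo("ACGTAC", c(tx = "GTACGT"), search_revcomp = TRUE)
  expect_identical(rc_hits$orientation, "-")
  expect_error(match_oligo("ACGN", t), "only A, C, G, T")
  expect_error(match_oligo("ACGTACGTTT", t), "longer than")
})

test_that("matching equals the naive sliding-window oracle", {
  set.seed(808)
  for (rep in 1:20) {
    t <- paste(sample(c("A", "C", "G", "T"), sample(40:90, 1L), TRUE),
               collapse = "")
    q <- paste(sample(c("A", "C", "G", "T"), sample(5:12, 1L), TRUE),
               collapse = "")
    k <- sample(0:3, 1L)
    rc <- rep %% 2L == 0L
    hits <- match_oligo(q, c(tx = t), k, rc)
    got <- sort(paste(hits$position, hits$orientation, hits$mismatches))
    expect_identical(got, oracle_match_keys(q, t, k, rc))
  }
})

test_that("no oligo hit ever crosses a target boundary", {
  set.seed(809)
  a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  q <- substr(paste0(substr(a, 26, 30), substr(b, 1, 5)), 1, 10)
  split_hits <- match_oligo(q, c(a = a, b = b), max_mismatch = 1L)
  concat_hits <- match_oligo(q, c(ab = paste0(a, b)), max_mismatch = 1L)
  # the concatenated target may gain boundary-crossing hits; per-target
  # results must not contain them
  expect_true(all(split_hits$position + nchar(q) - 1L <= 30L))
  expect_gte(nrow(concat_hits), nrow(split_hits))
})

test_that("local alignment handles identity, disjoint and gapped cases", {
  dna <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(dna) <- 1
  al <- local_align("ACGT", "ACGT", submat = dna, gap_open = 1, gap_extend = 1)
  expect_identical(al$score, 4)
  expect_identical(al$alignment_a, "ACGT")

  # no positive-scoring pair: empty alignment, score 0
  al <- local_align("AAAA", "CCCC", submat = dna, gap_open = 1, gap_extend = 1)
  expect_identical(al$score, 0)
  expect_identical(al$alignment_a, "")

  # a gap is opened when it pays
  al <- local_align("ACGTACGT", "ACGTTTACGT", submat = dna, gap_open = 0,
                    gap_extend = 1)
  expect_identical(al$score, 6)
  expect_true(grepl("-", al$alignment_a, fixed = TRUE))
  expect_error(local_align("ACGT", "ACBT", submat = dna), "absent from")
})

test_that("alignment scores equal an independent DP implementation", {
  skip_if_not_installed("Biostrings")
  set.seed(909)
  aas <- rownames(blosum62())[1:20]
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (rep in 1:25) {
    a <- paste(sample(aas, sample(3:12, 1L), TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:12, 1L), TRUE), collapse = "")
    mine <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "local")
    expect_identical(mine$score, Biostrings::score(ref))
    expect_gte(mine$score, 0)
    # symmetry for the symmetric matrix
    expect_identical(mine$score, local_align(b, a)$score)
  }
})

test_that("the shipped matrix equals the canonical BLOSUM62 values", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  m <- blosum62()
  common <- intersect(rownames(m), rownames(BLOSUM62))
  expect_true(all(m[common, common] == BLOSUM62[common, common]))
})
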