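# export a fresh small chain store used across the tests
biorj_fixture_store <- function() {
  w <- warehouse(store_test_graph())
  org <- upsert_record(w, warehouse_record("organism", list(tax_id = "9606"),
                                           attributes = list(name = "human"),
                                           source = "tax", version = "2024"))$record_id
  gene <- upsert_record(w, warehouse_record("gene", list(symbol = "HPRT1"),
                                            parent_links = list(organism = org),
                                            source = "genes", version = "r5"))$record_id
  tx <- upsert_record(w, warehouse_record("transcript",
                                          list(transcript_id = "NM_000194"),
                                          parent_links = list(gene = gene),
                                          source = "ann", version = "r2"))$record_id
  prot <- upsert_record(w, warehouse_record("protein", list(protein_id = "P1"),
                                            parent_links = list(transcript = tx,
                                                                gene = gene),
                                            source = "prot", version = "r9"))$record_id
  for (s in c("tax", "genes", "ann", "prot")) record_source_version(w, s, "x")
  list(store = w, org = org, gene = gene, tx = tx, prot = prot)
}

test_that("exporting a root record yields a one-block document", {
  fx <- biorj_fixture_store()
  doc <- export_biorj(fx$store, fx$org)
  expect_length(doc$blocks, 1L)
  expect_length(doc$blocks[[1L]]$records, 1L)
  expect_identical(doc$blocks[[1L]]$concept, "organism")
  expect_identical(doc$source_versions,
                   list(list(source = "tax", version = "2024")))
  expect_identical(nrow(validate_biorj(doc, fx$store$graph)), 0L)
})

test_that("exports carry the critical closure in topological block order", {
  fx <- biorj_fixture_store()
  doc <- export_biorj(fx$store, fx$prot, related = "none")
  concepts <- vapply(doc$blocks, `[[`, character(1), "concept")
  expect_identical(concepts, c("organism", "gene", "transcript", "protein"))
  expect_identical(nrow(validate_biorj(doc, fx$store$graph)), 0L)
  # source_versions are exactly the provenance pairs of the payload
  expect_setequal(
    vapply(doc$source_versions, function(p) paste(p$source, p$version),
           character(1)),
    c("tax 2024", "genes r5", "ann r2", "prot r9"))
  expect_error(export_biorj(fx$store, 999L), "unknown record")
})

test_that("exported record sets match the upward-reachability oracle", {
  set.seed(505)
  for (rep in 1:10) {
    rs <- random_store()
    ids <- as.integer(names(rs$store$records))
    seeds <- sample(ids, sample(1:3, 1L))
    doc <- export_biorj(rs$store, seeds, related = "transitive")
    # oracle: reachability upward over all parent links
    all_edges <- rs$edges
    for (rec in rs$store$records) {   # add related links to the snapshot
      crit <- rs$store$graph$concepts[[rec$concept]]$critical_parents
      for (dep in setdiff(names(rec$parent_links), crit)) {
        all_edges <- rbind(all_edges,
                           data.frame(child = rec$record_id,
                                      parent = rec$parent_links[[dep]]))
      }
    }
    want <- seeds
    repeat {
      more <- setdiff(all_edges$parent[all_edges$child %in% want], want)
      if (length(more) == 0L) break
      want <- c(want, more)
    }
    got_keys <- tidy(doc)$key
    want_keys <- vapply(sort(want), function(id) {
      r <- rs$store$records[[as.character(id)]]
      paste(unlist(lapply(r$key_values, as.character)), collapse = ":")
    }, character(1))
    expect_setequal(got_keys, want_keys)
  }
})

test_that("import reproduces the document and is idempotent", {
  fx <- biorj_fixture_store()
  doc <- export_biorj(fx$store, fx$prot)
  w2 <- warehouse(store_test_graph())
  rep1 <- import_biorj(w2, doc)
  expect_identical(sum(rep1$created), 4L)
  expect_identical(sum(rep1$merged), 0L)
  # re-export the corresponding record and compare canonically
  pid <- lookup_record(w2, "protein", list(protein_id = "P1"))
  doc2 <- export_biorj(w2, pid)
  expect_true(biorj_equal(doc, doc2))
  # importing again creates nothing
  rep2 <- import_biorj(w2, doc)
  expect_identical(sum(rep2$created), 0L)
  expect_identical(sum(rep2$merged), 4L)
  expect_identical(length(w2$records), 4L)
})

test_that("import order does not matter for unicity-disjoint documents", {
  fx <- biorj_fixture_store()
  doc_a <- export_biorj(fx$store, fx$gene)
  doc_b <- export_biorj(fx$store, fx$org)  # subset: shares the organism
  w1 <- warehouse(store_test_graph())
  import_biorj(w1, doc_a); import_biorj(w1, doc_b)
  w2 <- warehouse(store_test_graph())
  import_biorj(w2, doc_b); import_biorj(w2, doc_a)
  expect_identical(logical_dump(w1), logical_dump(w2))
})

test_that("the validator flags each planted violation", {
  fx <- biorj_fixture_store()
  doc <- export_biorj(fx$store, fx$prot)
  expect_identical(nrow(validate_biorj(doc, fx$store$graph)), 0L)

  # child block moved before its parent block
  mut <- doc
  mut$blocks <- mut$blocks[c(2L, 1L, 3L, 4L)]
  v <- validate_biorj(mut, fx$store$graph)
  expect_true("block_order" %in% v$type)

  # dangling parent reference
  mut <- doc
  mut$blocks[[2L]]$records[[1L]]$parent_refs$organism <- "organism:99"
  v <- validate_biorj(mut, fx$store$graph)
  expect_identical(unique(v$type), "unresolved_parent_ref")

  # duplicated local id
  mut <- doc
  mut$blocks[[1L]]$records <- rep(mut$blocks[[1L]]$records, 2L)
  v <- validate_biorj(mut, fx$store$graph)
  expect_true("duplicate_local_id" %in% v$type)

  # provenance pair missing from source_versions
  mut <- doc
  mut$source_versions <- mut$source_versions[-1L]
  v <- validate_biorj(mut, fx$store$graph)
  expect_identical(unique(v$type), "missing_source_version")

  # an invalid document is rejected on import
  expect_error(import_biorj(warehouse(store_test_graph()), mut), "validation")
})

test_that("JSON files and the linearized text form round-trip", {
  fx <- biorj_fixture_store()
  doc <- export_biorj(fx$store, fx$prot)
  f <- withr::local_tempfile(fileext = ".biorj")
  write_biorj(doc, f)
  expect_true(biorj_equal(doc, read_biorj(f)))

  txt <- linearize_biorj(doc)
  lines <- strsplit(txt, "\n")[[1L]]
  n_recs <- sum(vapply(doc$blocks, function(b) length(b$records), integer(1)))
  expect_identical(sum(!startsWith(lines, "#")), n_recs)
  expect_true(biorj_equal(doc, parse_linear(txt)))

  # degenerate: header-only document parses back
  empty <- doc
  empty$blocks <- list()
  expect_true(biorj_equal(empty, parse_linear(linearize_biorj(empty))))

  expect_error(parse_linear("#BIORJ\t1.0\nnot-a-record-line"), "line 2")
})

test_that("byte-stable JSON output for identical inputs", {
  fx1 <- biorj_fixture_store()
  fx2 <- biorj_fixture_store()
  d1 <- export_biorj(fx1$store, fx1$prot)
  d2 <- export_biorj(fx2$store, fx2$prot)
  # strip volatile generator metadata, then compare bytes
  j <- function(d) jsonlite::toJSON(biorj_canonical(d), auto_unbox = TRUE)
  expect_identical(as.character(j(d1)), as.character(j(d2)))
})
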