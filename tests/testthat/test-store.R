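test_that("upsert creates once and merges duplicate submissions", {
  w <- warehouse(store_test_graph())
  r1 <- upsert_record(w, warehouse_record("organism", list(tax_id = "9606"),
                                          source = "tax", version = "v1"))
  expect_identical(r1$status, "created")
  r2 <- upsert_record(w, warehouse_record("organism", list(tax_id = "9606"),
                                          source = "tax", version = "v1"))
  expect_identical(r2$status, "merged")
  expect_identical(r2$record_id, r1$record_id)
  expect_length(w$records, 1L)
})

test_that("upsert rejects unknown concepts and dangling critical links", {
  w <- warehouse(store_test_graph())
  expect_error(upsert_record(w, warehouse_record("nope", list(id = "1"))),
               "unknown concept")
  expect_error(
    upsert_record(w, warehouse_record("gene", list(symbol = "G1"))),
    "missing critical dependency 'organism'")
  expect_error(
    upsert_record(w, warehouse_record("gene", list(symbol = "G1"),
                                      parent_links = list(organism = 99L))),
    "does not resolve")
})

test_that("merged records keep per-source annotations side by side", {
  w <- warehouse(store_test_graph())
  upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                    attributes = list(name = "name by A"),
                                    source = "provA", version = "v1"))
  res <- upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                           attributes = list(name = "name by B"),
                                           source = "provB", version = "v3"))
  rec <- w$records[[as.character(res$record_id)]]
  expect_length(rec$attributes, 2L)            # both providers retained
  expect_length(rec$provenance, 2L)
  # idempotence: same submission again changes nothing
  upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                    attributes = list(name = "name by B"),
                                    source = "provB", version = "v3"))
  rec2 <- w$records[[as.character(res$record_id)]]
  expect_identical(rec2, rec)
})

test_that("two overlapping gene providers merge to the union of unicity keys", {
  set.seed(11)
  syms_a <- sprintf("G%02d", 1:10)
  syms_b <- c(sample(syms_a, 5), sprintf("H%02d", 1:4))
  w <- warehouse(store_test_graph())
  org <- upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                           source = "tax", version = "v1"))
  for (s in syms_a) {
    upsert_record(w, warehouse_record("gene", list(symbol = s),
                                      parent_links = list(organism = org$record_id),
                                      source = "provA", version = "v1"))
  }
  for (s in syms_b) {
    upsert_record(w, warehouse_record("gene", list(symbol = s),
                                      parent_links = list(organism = org$record_id),
                                      source = "provB", version = "v1"))
  }
  n_genes <- sum(tidy(w)$concept == "gene")
  expect_identical(n_genes, length(union(syms_a, syms_b)))
})

test_that("cascade deletion removes exactly the reverse reachability set", {
  w <- warehouse(store_test_graph())
  org <- upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                           source = "s", version = "v"))$record_id
  gene <- upsert_record(w, warehouse_record("gene", list(symbol = "G"),
                                            parent_links = list(organism = org),
                                            source = "s", version = "v"))$record_id
  tx <- upsert_record(w, warehouse_record("transcript", list(transcript_id = "T"),
                                          parent_links = list(gene = gene),
                                          source = "s", version = "v"))$record_id
  prot <- upsert_record(w, warehouse_record("protein", list(protein_id = "P"),
                                            parent_links = list(transcript = tx),
                                            source = "s", version = "v"))$record_id
  # leaf deletion removes only the leaf
  expect_identical(delete_cascade(w, prot), prot)
  prot <- upsert_record(w, warehouse_record("protein", list(protein_id = "P"),
                                            parent_links = list(transcript = tx),
                                            source = "s", version = "v"))$record_id
  # deleting the organism removes the whole chain
  expect_identical(delete_cascade(w, org), sort(c(org, gene, tx, prot)))
  expect_length(w$records, 0L)
  expect_error(delete_cascade(w, org), "unknown record")
})

test_that("cascade equals the reachability oracle on randomized stores", {
  set.seed(303)
  for (rep in 1:20) {
    rs <- random_store()
    victim <- sample(as.integer(names(rs$store$records)), 1L)
    want <- oracle_cascade(rs$edges, victim)
    got <- delete_cascade(rs$store, victim)
    expect_identical(got, want)
    expect_identical(nrow(integrity_check(rs$store)), 0L)
  }
})

test_that("atomic sequences round-trip and region queries slice correctly", {
  w <- warehouse(store_test_graph())
  org <- upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                           source = "s", version = "v"))$record_id
  chr <- upsert_record(w, warehouse_record("chromosome", list(name = "chr1"),
                                           parent_links = list(organism = org),
                                           source = "s", version = "v"))$record_id
  expect_identical(load_sequence(w, chr, "ACGT"), 4L)
  expect_identical(region_query(w, chr, 1, 4), "ACGT")
  expect_identical(region_query(w, chr, 2, 2), "C")
  expect_error(region_query(w, chr, 0, 2), "valid range")
  expect_error(region_query(w, chr, 3, 5), "valid range")
  expect_error(load_sequence(w, chr, "AAAA"), "already has")
  expect_error(load_sequence(w, org, ""), "non-empty")

  # random 5 kb round-trip plus random subrange slices against substring
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  chr2 <- upsert_record(w, warehouse_record("chromosome", list(name = "chr2"),
                                            parent_links = list(organism = org),
                                            source = "s", version = "v"))$record_id
  load_sequence(w, chr2, s)
  expect_identical(region_query(w, chr2, 1, 5000), s)
  for (i in 1:25) {
    a <- sample(5000, 1L); b <- sample(a:5000, 1L)
    expect_identical(region_query(w, chr2, a, b), substr(s, a, b))
  }
})

test_that("the versioning table keeps exactly one current entry per source", {
  w <- warehouse(store_test_graph())
  record_source_version(w, "genes", "v1")
  expect_identical(current_version(w, "genes"), "v1")
  record_source_version(w, "genes", "v2")
  expect_identical(current_version(w, "genes"), "v2")
  for (i in 3:7) record_source_version(w, "genes", paste0("v", i))
  v <- w$versions[w$versions$source == "genes", ]
  expect_identical(sum(v$status == "current"), 1L)
  expect_identical(sum(v$status == "superseded"), 6L)
  expect_true(is.na(current_version(w, "unseen")))
})

test_that("integrity_check reports planted defects and passes healthy stores", {
  rs <- random_store()
  expect_identical(nrow(integrity_check(rs$store)), 0L)
  # break a critical parent link by hand
  w <- rs$store
  gid <- tidy(w)$record_id[tidy(w)$concept == "gene"][[1L]]
  rec <- w$records[[as.character(gid)]]
  rec$parent_links$organism <- 9999L
  w$records[[as.character(gid)]] <- rec
  viol <- integrity_check(w)
  expect_true("dangling_critical_link" %in% viol$type)
})

test_that("logical dumps are deterministic for identical load sequences", {
  build <- function() {
    w <- warehouse(store_test_graph())
    org <- upsert_record(w, warehouse_record("organism", list(tax_id = "1"),
                                             source = "s", version = "v"))$record_id
    chr <- upsert_record(w, warehouse_record("chromosome", list(name = "chr1"),
                                             parent_links = list(organism = org),
                                             source = "s", version = "v"))$record_id
    load_sequence(w, chr, "ACGTACGT")
    record_source_version(w, "s", "v")
    w
  }
  expect_identical(logical_dump(build()), logical_dump(build()))
  f <- withr::local_tempfile()
  logical_dump(build(), file = f)
  expect_identical(readLines(f), logical_dump(build()))
})
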