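# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations (enumeration, brute force, second
# implementations) kept free of the code paths they check.

# ---- dependency levels: brute-force path enumeration ------------------------

# random critical-edge DAG as an edge list over nodes n1..nk (edges always
# point from lower- to higher-numbered nodes, so acyclicity is structural)
random_dag_edges <- function(n, p = 0.35) {
  edges <- list()
  for (child in seq_len(n)) {
    for (parent in seq_len(child - 1L)) {
      if (stats::runif(1) < p) {
        edges[[length(edges) + 1L]] <- c(paste0("n", parent), paste0("n", child))
      }
    }
  }
  edges
}

graph_from_edges <- function(n, edges) {
  parents <- lapply(seq_len(n), function(i) character())
  names(parents) <- paste0("n", seq_len(n))
  for (e in edges) parents[[e[[2L]]]] <- c(parents[[e[[2L]]]], e[[1L]])
  g <- concept_graph()
  for (nm in names(parents)) {
    g <- register_concept(g, concept(nm, critical = parents[[nm]]))
  }
  g
}

# level by exhaustive enumeration of all upward paths: 1 + longest path to
# any root (recursion without memoization; n <= 12 keeps this tractable)
oracle_level <- function(parents, node) {
  ps <- parents[[node]]
  if (length(ps) == 0L) return(1L)
  1L + max(vapply(ps, function(p) oracle_level(parents, p), integer(1)))
}

parents_from_edges <- function(n, edges) {
  parents <- lapply(seq_len(n), function(i) character())
  names(parents) <- paste0("n", seq_len(n))
  for (e in edges) parents[[e[[2L]]]] <- c(parents[[e[[2L]]]], e[[1L]])
  parents
}

# breadth-first upward reachability (closure oracle)
oracle_closure <- function(parents, seeds) {
  seen <- seeds
  queue <- seeds
  while (length(queue) > 0L) {
    node <- queue[[1L]]; queue <- queue[-1L]
    new <- setdiff(parents[[node]], seen)
    seen <- c(seen, new); queue <- c(queue, new)
  }
  sort(seen)
}

# ---- store fixtures and cascade oracle --------------------------------------

# small fixed graph for randomized store tests
store_test_graph <- function() {
  concept_graph(
    concept("organism", unicity_key = "tax_id"),
    concept("gene", critical = "organism", unicity_key = "symbol"),
    concept("transcript", critical = "gene", unicity_key = "transcript_id"),
    concept("protein", critical = "transcript", related = "gene",
            unicity_key = "protein_id"),
    concept("chromosome", critical = "organism", unicity_key = "name")
  )
}

# randomized store over store_test_graph(); returns list(store, edges) where
# edges is an independent snapshot of critical child -> parent links
random_store <- function(n_genes = 4L, n_tx = 6L, n_prot = 5L) {
  w <- warehouse(store_test_graph())
  orgs <- vapply(1:2, function(i)
    upsert_record(w, warehouse_record("organism", list(tax_id = as.character(i)),
                                      source = "tax", version = "v1"))$record_id,
    integer(1))
  genes <- vapply(seq_len(n_genes), function(i)
    upsert_record(w, warehouse_record(
      "gene", list(symbol = paste0("G", i)),
      parent_links = list(organism = sample(orgs, 1L)),
      source = "genes", version = "v1"))$record_id, integer(1))
  txs <- vapply(seq_len(n_tx), function(i)
    upsert_record(w, warehouse_record(
      "transcript", list(transcript_id = paste0("T", i)),
      parent_links = list(gene = sample(genes, 1L)),
      source = "ann", version = "v1"))$record_id, integer(1))
  for (i in seq_len(n_prot)) {
    upsert_record(w, warehouse_record(
      "protein", list(protein_id = paste0("P", i)),
      parent_links = list(transcript = sample(txs, 1L),
                          gene = sample(genes, 1L)),
      source = "prot", version = "v1"))
  }
  for (s in c("tax", "genes", "ann", "prot")) record_source_version(w, s, "v1")
  edges <- critical_edge_snapshot(w)
  list(store = w, edges = edges)
}

# independent snapshot of critical links: data.frame(child, parent)
critical_edge_snapshot <- function(w) {
  rows <- list()
  for (rec in w$records) {
    crit <- w$graph$concepts[[rec$concept]]$critical_parents
    for (dep in intersect(names(rec$parent_links), crit)) {
      rows[[length(rows) + 1L]] <- data.frame(child = rec$record_id,
                                              parent = rec$parent_links[[dep]])
    }
  }
  if (length(rows) == 0L) return(data.frame(child = integer(), parent = integer()))
  do.call(rbind, rows)
}

# reverse reachability over the snapshot: everything that transitively
# depends on `id` through critical links, plus `id`
oracle_cascade <- function(edges, id) {
  doomed <- id
  repeat {
    more <- setdiff(edges$child[edges$parent %in% doomed], doomed)
    if (length(more) == 0L) break
    doomed <- c(doomed, more)
  }
  sort(doomed)
}

# ---- sequence oracles -------------------------------------------------------

# frozen NCBI standard genetic code (translation table 1), typed by hand
NCBI_TABLE1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

ALL_CODONS <- names(NCBI_TABLE1)

# naive per-codon translation, independent of translate_cds
oracle_translate <- function(cds) {
  n <- nchar(cds)
  aa <- character(n %/% 3L)
  for (i in seq_along(aa)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    aa[[i]] <- if (codon %in% names(NCBI_TABLE1)) NCBI_TABLE1[[codon]] else "X"
  }
  aa
}

# definition-level edit-consequence oracle: translate the effective CDS
# before and after the single A->G substitution and compare proteins and
# stop structure
oracle_classify <- function(seqstr, cds_start, cds_end, pos) {
  if (pos < cds_start || pos > cds_end) return("non_coding")
  after <- seqstr
  substr(after, pos, pos) <- "G"
  aa_before <- oracle_translate(substr(seqstr, cds_start, cds_end))
  aa_after <- oracle_translate(substr(after, cds_start, cds_end))
  ci <- (pos - cds_start) %/% 3L + 1L
  n_codons <- length(aa_before)
  if (identical(aa_before, aa_after)) return("no_protein_change")
  if (aa_before[[ci]] == "*" && ci < n_codons && aa_after[[ci]] != "*") {
    return("prevents_premature_termination")
  }
  "amino_acid_modification"
}

# naive O(nm) sliding-window Hamming scan, canonical hit keys
oracle_match_keys <- function(query, target, k, revcomp = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(unname(comp[strsplit(x, "")[[1L]]])), collapse = "")
  queries <- c("+" = query)
  if (revcomp) queries <- c(queries, "-" = rc(query))
  keys <- character()
  tt <- strsplit(target, "")[[1L]]
  for (o in names(queries)) {
    qq <- strsplit(queries[[o]], "")[[1L]]
    if (length(qq) > length(tt)) next
    for (s in seq_len(length(tt) - length(qq) + 1L)) {
      mm <- sum(tt[s:(s + length(qq) - 1L)] != qq)
      if (mm <= k) keys <- c(keys, paste(s, o, mm))
    }
  }
  sort(keys)
}

# ---- scheduler outcome scripts and log invariants ---------------------------

# random source DAG + scripted outcomes; check_release / process consult the
# script for the current cycle
make_scripted_adapters <- function(n_sources, n_cycles, p_edge = 0.2,
                                   p_release = 0.6, p_fail = 0.25) {
  nms <- sprintf("s%02d", seq_len(n_sources))
  parents <- lapply(seq_len(n_sources), function(i) {
    cand <- nms[seq_len(i - 1L)]
    cand[stats::runif(length(cand)) < p_edge]
  })
  names(parents) <- nms
  # releases[[cycle]][source]: version token or NA; fails: should process fail
  releases <- lapply(seq_len(n_cycles), function(cy)
    stats::setNames(ifelse(stats::runif(n_sources) < p_release,
                           paste0("v", cy), NA_character_), nms))
  fails <- lapply(seq_len(n_cycles), function(cy)
    stats::setNames(stats::runif(n_sources) < p_fail, nms))
  clock <- new.env(parent = emptyenv())
  clock$cycle <- 0L
  adapters <- lapply(nms, function(nm) {
    force(nm)
    source_adapter(
      name = nm, parents = parents[[nm]],
      check_release = function() {
        v <- releases[[min(clock$cycle, n_cycles)]][[nm]]
        if (is.na(v)) NULL else v
      },
      process = function(store, payload) {
        if (fails[[min(clock$cycle, n_cycles)]][[nm]]) {
          stop("scripted failure of ", nm)
        }
        0L
      })
  })
  list(adapters = adapters, parents = parents, releases = releases,
       fails = fails, clock = clock, n_cycles = n_cycles)
}

# all transitive ancestors of each source
transitive_ancestors <- function(parents) {
  anc <- function(nm) {
    out <- parents[[nm]]
    frontier <- out
    while (length(frontier) > 0L) {
      more <- setdiff(unlist(parents[frontier]), out)
      out <- c(out, more)
      frontier <- more
    }
    out
  }
  stats::setNames(lapply(names(parents), anc), names(parents))
}

# assert the scheduler-log invariants; returns character vector of failures
check_log_invariants <- function(log, parents) {
  bad <- character()
  anc <- transitive_ancestors(parents)
  if (is.unsorted(log$seq, strictly = TRUE)) bad <- c(bad, "seq not strictly increasing")
  failed_at <- function(src, t) {
    ev <- log[log$source == src & log$seq < t &
                log$action %in% c("process_fail", "resume", "process_ok"), ]
    nrow(ev) > 0L && ev$action[[nrow(ev)]] == "process_fail"
  }
  bumped_versions <- function(src, t) {
    log$version[log$source == src & log$action == "version_bump" & log$seq < t]
  }
  for (i in which(log$action == "process_start")) {
    src <- log$source[[i]]; t <- log$seq[[i]]
    for (p in parents[[src]]) {
      # parent current: every release the parent ever reported before t has
      # been bumped, and the parent is not failed
      if (failed_at(p, t)) {
        bad <- c(bad, paste0("gating: ", src, " started while parent ", p,
                             " failed (seq ", t, ")"))
      }
    }
    for (a in anc[[src]]) {
      if (failed_at(a, t)) {
        bad <- c(bad, paste0("hold: ", src, " started while ancestor ", a,
                             " failed (seq ", t, ")"))
      }
    }
  }
  # no version_bump without an immediately preceding process_ok (possibly
  # with one cleanup in between) for the same source and version
  for (i in which(log$action == "version_bump")) {
    src <- log$source[[i]]
    prior <- log[log$source == src & log$seq < log$seq[[i]], ]
    prior <- prior[prior$action != "check", ]
    ok <- FALSE
    if (nrow(prior) > 0L) {
      last <- prior[nrow(prior), ]
      if (last$action == "cleanup" && nrow(prior) > 1L) last <- prior[nrow(prior) - 1L, ]
      ok <- last$action == "process_ok" && identical(last$version, log$version[[i]])
    }
    if (!ok) bad <- c(bad, paste0("bump without process_ok: ", src))
  }
  # cleanup strictly between process_ok and version_bump
  for (i in which(log$action == "cleanup")) {
    src <- log$source[[i]]
    srcev <- log[log$source == src & log$action != "check", ]
    j <- which(srcev$seq == log$seq[[i]])
    if (j == 1L || j == nrow(srcev) ||
        srcev$action[[j - 1L]] != "process_ok" ||
        srcev$action[[j + 1L]] != "version_bump") {
      bad <- c(bad, paste0("cleanup not between process_ok and bump: ", src))
    }
  }
  bad
}

# all permutations of a small vector
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}
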