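#' Create an empty warehouse store
#'
#' The warehouse enforces the two founding principles of the data mart:
#' *unicity* — each real-world entity has exactly one record per concept,
#' identified by the concept's unicity key, so duplicate submissions from
#' different providers merge — and *atomicity* — sequences are decomposed to
#' their most granular component, one positional row per nucleotide or amino
#' acid. It also tracks per-record provenance and a versioning table holding
#' the single current version token per data source.
#'
#' The store is an environment-backed S3 object: operations mutate it in
#' place and also return it (or their result) invisibly, so pipe-style code
#' works. A deterministic textual image of the full logical state is
#' available through [logical_dump()].
#'
#' @param graph A `concept_graph` describing the concepts the store accepts;
#'   validated on construction.
#' @return An object of class `warehouse`.
#' @examples
#' w <- warehouse(chain_graph())
#' upsert_record(w, warehouse_record("organism", list(tax_id = "9606"),
#'                                   source = "taxonomy", version = "v1"))
#' @export
warehouse <- function(graph = concept_graph()) {
  graph <- cg_validated(graph)
  w <- new.env(parent = emptyenv())
  w$graph <- graph
  w$records <- list()          # "<id>" -> record
  w$key_index <- new.env(parent = emptyenv())  # canonical key -> id
  w$sequences <- new.env(parent = emptyenv())  # "<molecule id>" -> char vector
  w$versions <- tibble::tibble(source = character(), version = character(),
                               recorded_at = as.POSIXct(character()),
                               status = character())
  w$next_id <- 1L
  class(w) <- "warehouse"
  w
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse>", length(x$records), "records over",
      length(unique(vapply(x$records, `[[`, character(1), "concept"))),
      "concepts;", length(ls(x$sequences)), "atomic sequences;",
      sum(x$versions$status == "current"), "current source versions\n")
  invisible(x)
}

#' Describe a record for insertion
#'
#' @param concept Concept name (must be registered in the store's graph).
#' @param key_values Named list: one value per field of the concept's
#'   unicity key.
#' @param attributes Named list of non-key annotation values contributed by
#'   `source`.
#' @param parent_links Named list mapping dependency (parent concept) name to
#'   the record id of the referenced parent. All critical parents are
#'   mandatory; related links are optional.
#' @param source,version Provenance of this submission.
#' @return An object of class `warehouse_record` (unsaved).
#' @export
warehouse_record <- function(concept, key_values, attributes = list(),
                             parent_links = list(), source = "manual",
                             version = "0") {
  stopifnot(is.character(concept), length(concept) == 1L)
  structure(list(concept = concept, key_values = key_values,
                 attributes = attributes, parent_links = parent_links,
                 provenance = list(list(source = source, version = version))),
            class = "warehouse_record")
}

ws_key <- function(store, concept, key_values) {
  def <- store$graph$concepts[[concept]]
  missing <- setdiff(def$unicity_key, names(key_values))
  if (length(missing) > 0L) {
    stop("record of concept '", concept, "' is missing unicity key field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(def$unicity_key, function(f) as.character(key_values[[f]]))
  names(vals) <- def$unicity_key
  paste0(concept, "\x1f", canonical_json(vals))
}

ws_record <- function(store, id) store$records[[as.character(id)]]

#' Insert or merge a record (unicity upsert)
#'
#' If no record of the same concept shares the unicity-key values, a new
#' record is created. Otherwise the submission *merges* into the existing
#' record: provenance is appended (exact duplicates collapsed), and non-key
#' attributes are kept per source alongside the existing ones — annotations
#' from different providers coexist, nothing is overwritten. Existing
#' critical links are kept on merge; new related links are added.
#'
#' @param store A `warehouse`.
#' @param record A `warehouse_record`.
#' @return Invisibly, a list with `record_id` and `status`
#'   (`"created"` or `"merged"`).
#' @export
upsert_record <- function(store, record) {
  stopifnot(inherits(store, "warehouse"), inherits(record, "warehouse_record"))
  concept <- record$concept
  def <- store$graph$concepts[[concept]]
  if (is.null(def)) stop("unknown concept '", concept, "'", call. = FALSE)
  # referential integrity over parent links
  for (dep in def$critical_parents) {
    pid <- record$parent_links[[dep]]
    if (is.null(pid)) {
      stop("record of '", concept, "' is missing critical dependency '", dep,
           "'", call. = FALSE)
    }
    parent <- ws_record(store, pid)
    if (is.null(parent) || parent$concept != dep) {
      stop("critical dependency '", dep, "' of '", concept,
           "' does not resolve to an existing '", dep, "' record", call. = FALSE)
    }
  }
  for (dep in setdiff(names(record$parent_links), def$critical_parents)) {
    parent <- ws_record(store, record$parent_links[[dep]])
    if (is.null(parent) || parent$concept != dep) {
      stop("related dependency '", dep, "' of '", concept,
           "' does not resolve to an existing '", dep, "' record", call. = FALSE)
    }
  }
  key <- ws_key(store, concept, record$key_values)
  attr_rows <- ws_attribute_rows(record)
  existing <- if (exists(key, envir = store$key_index, inherits = FALSE))
    get(key, envir = store$key_index) else NULL
  if (is.null(existing)) {
    id <- store$next_id
    store$next_id <- store$next_id + 1L
    rec <- list(record_id = id, concept = concept,
                key_values = record$key_values,
                attributes = attr_rows,
                parent_links = record$parent_links,
                provenance = unique(record$provenance))
    store$records[[as.character(id)]] <- rec
    assign(key, id, envir = store$key_index)
    return(invisible(list(record_id = id, status = "created")))
  }
  rec <- ws_record(store, existing)
  rec$provenance <- unique(c(rec$provenance, record$provenance))
  for (row in attr_rows) {
    if (!any(vapply(rec$attributes, identical, logical(1), row))) {
      rec$attributes <- c(rec$attributes, list(row))
    }
  }
  for (dep in setdiff(names(record$parent_links), names(rec$parent_links))) {
    rec$parent_links[[dep]] <- record$parent_links[[dep]]
  }
  store$records[[as.character(existing)]] <- rec
  invisible(list(record_id = existing, status = "merged"))
}

# attributes as per-source (source, field, value) rows
ws_attribute_rows <- function(record) {
  src <- record$provenance[[1L]]$source
  rows <- list()
  for (f in names(record$attributes)) {
    rows[[length(rows) + 1L]] <- list(source = src, field = f,
                                      value = as.character(record$attributes[[f]]))
  }
  rows
}

#' Look up a record id by unicity key
#'
#' @param store A `warehouse`.
#' @param concept Concept name.
#' @param key_values Named list of unicity-key values.
#' @return The record id, or `NULL` when absent.
#' @export
lookup_record <- function(store, concept, key_values) {
  key <- ws_key(store, concept, key_values)
  if (exists(key, envir = store$key_index, inherits = FALSE))
    get(key, envir = store$key_index) else NULL
}

# which parent links of a record are critical, per the store's graph
ws_critical_links <- function(store, rec) {
  crit <- store$graph$concepts[[rec$concept]]$critical_parents
  rec$parent_links[intersect(names(rec$parent_links), crit)]
}

#' Delete a record and all its critical descendants (cascade)
#'
#' When a parent record becomes obsolete, every record that critically
#' depends on it — transitively — loses its scientific integrity and is
#' removed with it. Related links pointing at deleted records are cleared
#' (related dependencies only augment a record), and atomic sequences of
#' deleted molecules are dropped.
#'
#' @param store A `warehouse`.
#' @param record_id Id of the record to delete.
#' @return Invisibly, the sorted integer vector of all deleted record ids
#'   (including `record_id`).
#' @export
delete_cascade <- function(store, record_id) {
  stopifnot(inherits(store, "warehouse"))
  if (is.null(ws_record(store, record_id))) {
    stop("unknown record id ", record_id, call. = FALSE)
  }
  doomed <- as.integer(record_id)
  frontier <- doomed
  while (length(frontier) > 0L) {
    more <- integer()
    for (rec in store$records) {
      if (rec$record_id %in% doomed) next
      if (any(unlist(ws_critical_links(store, rec)) %in% frontier)) {
        more <- c(more, rec$record_id)
      }
    }
    doomed <- c(doomed, more)
    frontier <- more
  }
  for (id in doomed) {
    rec <- ws_record(store, id)
    rm(list = ws_key(store, rec$concept, rec$key_values), envir = store$key_index)
    store$records[[as.character(id)]] <- NULL
    if (exists(as.character(id), envir = store$sequences, inherits = FALSE)) {
      rm(list = as.character(id), envir = store$sequences)
    }
  }
  # clear related links that now dangle
  for (nm in names(store$records)) {
    rec <- store$records[[nm]]
    crit <- store$graph$concepts[[rec$concept]]$critical_parents
    keep <- vapply(names(rec$parent_links), function(dep) {
      dep %in% crit || !(rec$parent_links[[dep]] %in% doomed)
    }, logical(1))
    if (!all(keep)) {
      rec$parent_links <- rec$parent_links[keep]
      store$records[[nm]] <- rec
    }
  }
  invisible(sort(doomed))
}

#' Load a sequence as atomic per-residue rows
#'
#' Decomposes `residues` into one positional row per residue (1..N), attached
#' to an owning molecule record (a chromosome or a protein). A molecule can
#' hold at most one sequence; re-loading without deleting first is an error.
#'
#' @param store A `warehouse`.
#' @param molecule_id Record id of the owning molecule.
#' @param residues Non-empty string of IUPAC nucleotide or amino-acid codes.
#' @return Invisibly, the number of atomic rows stored (the sequence length).
#' @export
load_sequence <- function(store, molecule_id, residues) {
  stopifnot(inherits(store, "warehouse"))
  if (is.null(ws_record(store, molecule_id))) {
    stop("unknown record id ", molecule_id, call. = FALSE)
  }
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) == 0L) {
    stop("residues must be a single non-empty string", call. = FALSE)
  }
  key <- as.character(molecule_id)
  if (exists(key, envir = store$sequences, inherits = FALSE)) {
    stop("molecule ", molecule_id,
         " already has a stored sequence; delete it first", call. = FALSE)
  }
  assign(key, strsplit(toupper(residues), "", fixed = TRUE)[[1L]],
         envir = store$sequences)
  invisible(nchar(residues))
}

#' Retrieve residues of a stored molecule by region
#'
#' Coordinates are 1-based and the interval is closed on both ends, matching
#' the per-residue atomic rows and common genomics convention.
#'
#' @param store A `warehouse`.
#' @param molecule_id Record id of the molecule.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end <= N`.
#' @return The residue string of length `end - start + 1`.
#' @export
region_query <- function(store, molecule_id, start, end) {
  stopifnot(inherits(store, "warehouse"))
  key <- as.character(molecule_id)
  if (!exists(key, envir = store$sequences, inherits = FALSE)) {
    stop("molecule ", molecule_id, " has no stored sequence", call. = FALSE)
  }
  seqv <- get(key, envir = store$sequences)
  n <- length(seqv)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop("invalid region [", start, ", ", end, "]; valid range is [1, ", n,
         "] with start <= end", call. = FALSE)
  }
  paste(seqv[start:end], collapse = "")
}

ws_molecule_length <- function(store, molecule_id) {
  key <- as.character(molecule_id)
  if (!exists(key, envir = store$sequences, inherits = FALSE)) return(NA_integer_)
  length(get(key, envir = store$sequences))
}

#' Record a data-source version in the versioning table
#'
#' The versioning table holds exactly one *current* entry per source; the
#' previous current entry, if any, is marked superseded. The version is only
#' ever bumped by the orchestrator after a successful processing run.
#'
#' @param store A `warehouse`.
#' @param source Data-source name.
#' @param version Opaque version token.
#' @return Invisibly, a one-row tibble: the new current entry.
#' @export
record_source_version <- function(store, source, version) {
  stopifnot(inherits(store, "warehouse"))
  v <- store$versions
  v$status[v$source == source & v$status == "current"] <- "superseded"
  entry <- tibble::tibble(source = source, version = as.character(version),
                          recorded_at = Sys.time(), status = "current")
  store$versions <- dplyr::bind_rows(v, entry)
  invisible(entry)
}

#' Current version of a data source
#'
#' @param store A `warehouse`.
#' @param source Data-source name.
#' @return The current version token, or `NA` when the source has none.
#' @export
current_version <- function(store, source) {
  v <- store$versions
  hit <- v$version[v$source == source & v$status == "current"]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

#' Check warehouse integrity
#'
#' Sweeps the whole store for violations of its structural invariants:
#' dangling or wrongly-typed critical links, unicity collisions,
#' non-contiguous atomic sequences, orphan sequences and multiple current
#' versions for one source.
#'
#' @param store A `warehouse`.
#' @return A tibble of violations (`type`, `detail`); zero rows when healthy.
#' @export
integrity_check <- function(store) {
  stopifnot(inherits(store, "warehouse"))
  bad <- list()
  note <- function(type, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(type = type, detail = detail)
  }
  seen_keys <- character()
  for (rec in store$records) {
    def <- store$graph$concepts[[rec$concept]]
    if (is.null(def)) {
      note("unknown_concept", paste0("record ", rec$record_id, ": concept '",
                                     rec$concept, "' not registered"))
      next
    }
    key <- ws_key(store, rec$concept, rec$key_values)
    if (key %in% seen_keys) {
      note("unicity_collision", paste0("duplicate (concept, key) for record ",
                                       rec$record_id))
    }
    seen_keys <- c(seen_keys, key)
    if (!exists(key, envir = store$key_index, inherits = FALSE) ||
        get(key, envir = store$key_index) != rec$record_id) {
      note("index_mismatch", paste0("key index does not point at record ",
                                    rec$record_id))
    }
    for (dep in def$critical_parents) {
      pid <- rec$parent_links[[dep]]
      parent <- if (is.null(pid)) NULL else ws_record(store, pid)
      if (is.null(parent) || parent$concept != dep) {
        note("dangling_critical_link",
             paste0("record ", rec$record_id, " ('", rec$concept,
                    "'): critical dependency '", dep, "' unresolved"))
      }
    }
    for (dep in setdiff(names(rec$parent_links), def$critical_parents)) {
      parent <- ws_record(store, rec$parent_links[[dep]])
      if (is.null(parent) || parent$concept != dep) {
        note("dangling_related_link",
             paste0("record ", rec$record_id, " ('", rec$concept,
                    "'): related dependency '", dep, "' unresolved"))
      }
    }
  }
  for (mid in ls(store$sequences)) {
    if (is.null(ws_record(store, mid))) {
      note("orphan_sequence", paste0("sequence stored for missing molecule ", mid))
    }
    seqv <- get(mid, envir = store$sequences)
    if (length(seqv) == 0L || any(is.na(seqv)) || any(nchar(seqv) != 1L)) {
      note("non_contiguous_sequence",
           paste0("molecule ", mid, ": positions are not exactly 1..N"))
    }
  }
  multi <- dplyr::count(dplyr::filter(store$versions, .data$status == "current"),
                        .data$source)
  for (s in multi$source[multi$n > 1L]) {
    note("multiple_current_versions", paste0("source '", s,
                                             "' has more than one current version"))
  }
  if (length(bad) == 0L) {
    tibble::tibble(type = character(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Deterministic logical dump of a warehouse
#'
#' Serializes the complete logical state — records in canonical (concept,
#' key) order with surrogate ids remapped to canonical ordinals, atomic
#' sequences, and the versioning table without timestamps — as one canonical
#' JSON string. Two stores loaded from the same inputs in the same order
#' produce byte-identical dumps, which is how database-level determinism is
#' asserted.
#'
#' @param store A `warehouse`.
#' @param file Optional path; when given the dump is also written there.
#' @return The dump as a single character string (invisibly when `file` is
#'   given).
#' @export
logical_dump <- function(store, file = NULL) {
  stopifnot(inherits(store, "warehouse"))
  recs <- store$records
  keys <- vapply(recs, function(r) ws_key(store, r$concept, r$key_values),
                 character(1))
  ord <- order(keys)
  recs <- recs[ord]
  id_map <- stats::setNames(seq_along(recs),
                            vapply(recs, function(r) as.character(r$record_id),
                                   character(1)))
  dump_rec <- function(r) {
    links <- lapply(sort_named(r$parent_links), function(pid)
      unname(id_map[[as.character(pid)]]))
    attrs <- r$attributes[order(vapply(r$attributes, canonical_json, character(1)))]
    prov <- r$provenance[order(vapply(r$provenance, canonical_json, character(1)))]
    seqstr <- if (!is.na(ws_molecule_length(store, r$record_id)))
      paste(get(as.character(r$record_id), envir = store$sequences),
            collapse = "") else NULL
    list(id = unname(id_map[[as.character(r$record_id)]]), concept = r$concept,
         key_values = sort_named(lapply(r$key_values, as.character)),
         attributes = attrs, parent_links = links, provenance = prov,
         sequence = seqstr)
  }
  versions <- dplyr::arrange(store$versions, .data$source, .data$version,
                             .data$status)[, c("source", "version", "status")]
  out <- canonical_json(list(
    records = lapply(recs, dump_rec),
    versions = lapply(seq_len(nrow(versions)), function(i) as.list(versions[i, ]))
  ))
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Tidy a warehouse into a per-record tibble
#'
#' @param x A `warehouse`.
#' @param ... Unused.
#' @return A tibble with one row per record: id, concept, unicity key (as a
#'   compact string), numbers of attributes and parent links, and the
#'   contributing sources.
#' @export
tidy.warehouse <- function(x, ...) {
  if (length(x$records) == 0L) {
    return(tibble::tibble(record_id = integer(), concept = character(),
                          key = character(), n_attributes = integer(),
                          n_parents = integer(), sources = character()))
  }
  recs <- x$records
  tibble::tibble(
    record_id = vapply(recs, `[[`, integer(1), "record_id"),
    concept = vapply(recs, `[[`, character(1), "concept"),
    key = vapply(recs, function(r)
      paste(unlist(lapply(r$key_values, as.character)), collapse = ":"),
      character(1)),
    n_attributes = vapply(recs, function(r) length(r$attributes), integer(1)),
    n_parents = vapply(recs, function(r) length(r$parent_links), integer(1)),
    sources = vapply(recs, function(r)
      paste(sort(unique(vapply(r$provenance, `[[`, character(1), "source"))),
            collapse = ","), character(1))
  ) |>
    dplyr::arrange(.data$concept, .data$key)
}

#' One-row summary of a warehouse
#'
#' @param x A `warehouse`.
#' @param ... Unused.
#' @return A one-row tibble: record, concept, molecule and source counts.
#' @export
glance.warehouse <- function(x, ...) {
  tibble::tibble(
    n_records = length(x$records),
    n_concepts = length(unique(vapply(x$records, `[[`, character(1), "concept"))),
    n_molecules = length(ls(x$sequences)),
    n_sources = length(unique(x$versions$source)),
    n_violations = nrow(integrity_check(x))
  )
}
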