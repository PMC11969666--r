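#' BIORJ: dependency-closure exchange documents
#'
#' A BIORJ document packages a set of warehouse records together with the
#' complete closure of their parent records, their provenance and the
#' versions of every contributing data source, as plain JSON that can be
#' shared between warehouses and re-imported with unicity merge. Records are
#' grouped into concept blocks in topological order (a block's concept comes
#' after all of its critical-parent concepts present in the document) and
#' reference each other only through document-local ids, so no store-internal
#' surrogate ids leak. The schema is frozen as format_version "1.0"; a
#' JSON-Schema description ships with the package
#' (`system.file("extdata", "biorj-schema.json", package = "relmart")`).
#'
#' @name biorj
NULL

BIORJ_FORMAT_VERSION <- "1.0"

#' Export records with their dependency closure as a BIORJ document
#'
#' The export always contains the requested records plus, transitively, every
#' record reachable through critical parent links — the information without
#' which the requested records would lose scientific integrity. Related
#' (annotation) records are included according to `related`:
#' `"one_hop"` (default) adds the related parents of every record in the
#' critical closure (plus *their* critical closures, to keep the document
#' closure-complete); `"transitive"` follows related links all the way up;
#' `"none"` exports the critical closure only. Related references pointing
#' outside the document are dropped — they only augment a record.
#'
#' @param store A `warehouse`.
#' @param record_ids Integer ids of the records to export.
#' @param related One of `"one_hop"`, `"none"`, `"transitive"`.
#' @param include_related Convenience flag: `TRUE` is shorthand for
#'   `related = "transitive"`. Ignored when `NULL`.
#' @return An object of class `biorj_document`.
#' @export
export_biorj <- function(store, record_ids,
                         related = c("one_hop", "none", "transitive"),
                         include_related = NULL) {
  stopifnot(inherits(store, "warehouse"))
  related <- if (isTRUE(include_related)) "transitive" else match.arg(related)
  for (id in record_ids) {
    if (is.null(ws_record(store, id))) {
      stop("unknown record id ", id, call. = FALSE)
    }
  }
  crit_closure <- function(ids) {
    seen <- integer()
    queue <- as.integer(ids)
    while (length(queue) > 0L) {
      id <- queue[[1L]]; queue <- queue[-1L]
      if (id %in% seen) next
      seen <- c(seen, id)
      rec <- ws_record(store, id)
      queue <- c(queue, unlist(ws_critical_links(store, rec)) %||% integer())
    }
    seen
  }
  ids <- crit_closure(record_ids)
  if (related == "one_hop") {
    hop <- unlist(lapply(ids, function(id) {
      rec <- ws_record(store, id)
      crit <- store$graph$concepts[[rec$concept]]$critical_parents
      unlist(rec$parent_links[setdiff(names(rec$parent_links), crit)])
    })) %||% integer()
    ids <- crit_closure(unique(c(ids, hop)))
  } else if (related == "transitive") {
    seen <- integer(); queue <- as.integer(record_ids)
    while (length(queue) > 0L) {
      id <- queue[[1L]]; queue <- queue[-1L]
      if (id %in% seen) next
      seen <- c(seen, id)
      rec <- ws_record(store, id)
      queue <- c(queue, unlist(rec$parent_links) %||% integer())
    }
    ids <- seen
  }
  ids <- sort(unique(as.integer(ids)))
  recs <- lapply(ids, function(id) ws_record(store, id))
  concepts <- unique(vapply(recs, `[[`, character(1), "concept"))
  block_order <- update_order(store$graph, concepts)
  # local ids: concept plus rank of the record's canonical key within block
  local_ids <- character()
  by_concept <- split(recs, vapply(recs, `[[`, character(1), "concept"))
  blocks <- lapply(block_order, function(cn) {
    brecs <- by_concept[[cn]]
    keyjson <- vapply(brecs, function(r) canonical_json(sort_named(
      lapply(r$key_values, as.character))), character(1))
    brecs <- brecs[order(keyjson)]
    for (i in seq_along(brecs)) {
      local_ids[[as.character(brecs[[i]]$record_id)]] <<- paste0(cn, ":", i)
    }
    brecs
  })
  names(blocks) <- block_order
  prov_pairs <- list()
  blocks_out <- lapply(block_order, function(cn) {
    list(concept = cn, records = lapply(blocks[[cn]], function(r) {
      crit <- store$graph$concepts[[r$concept]]$critical_parents
      refs <- list()
      for (dep in sort(names(r$parent_links))) {
        pid <- as.character(r$parent_links[[dep]])
        lid <- if (pid %in% names(local_ids)) local_ids[[pid]] else NA_character_
        if (!is.na(lid)) {
          refs[[dep]] <- lid
        } else if (dep %in% crit) {
          stop("internal error: critical parent of record ", r$record_id,
               " missing from export closure", call. = FALSE)
        }
      }
      prov <- r$provenance[order(vapply(r$provenance, canonical_json,
                                        character(1)))]
      for (p in prov) prov_pairs[[canonical_json(p)]] <<- p
      attrs <- r$attributes[order(vapply(r$attributes, canonical_json,
                                         character(1)))]
      list(local_id = local_ids[[as.character(r$record_id)]],
           key_values = sort_named(lapply(r$key_values, as.character)),
           attributes = attrs, parent_refs = refs, provenance = prov)
    }))
  })
  sv <- prov_pairs[order(names(prov_pairs))]
  doc <- structure(list(
    format_version = BIORJ_FORMAT_VERSION,
    generator = list(instance = "relmart",
                     schema_version = BIORJ_FORMAT_VERSION,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    source_versions = unname(sv),
    blocks = blocks_out
  ), class = "biorj_document")
  doc
}

#' Validate a BIORJ document
#'
#' Checks the document invariants: unique local ids, parent references
#' resolving to a record in the same or an earlier block, blocks in
#' topological order with respect to the critical-parent concepts present in
#' the document (requires `graph`), and source_versions covering every
#' provenance pair in the payload.
#'
#' @param doc A `biorj_document`.
#' @param graph Optional `concept_graph`; when supplied, block order is
#'   checked against the critical edges of the graph.
#' @return A tibble of violations (`type`, `where`, `detail`); zero rows when
#'   the document is well-formed.
#' @export
validate_biorj <- function(doc, graph = NULL) {
  stopifnot(inherits(doc, "biorj_document"))
  bad <- list()
  note <- function(type, where, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(type = type, where = where,
                                               detail = detail)
  }
  seen_ids <- character()
  sv_keys <- vapply(doc$source_versions, function(p)
    paste0(p$source, "\x1f", p$version), character(1))
  if (length(doc$source_versions) == 0L) sv_keys <- character()
  concepts_so_far <- character()
  for (bi in seq_along(doc$blocks)) {
    block <- doc$blocks[[bi]]
    if (!is.null(graph)) {
      present_parents <- intersect(
        graph$concepts[[block$concept]]$critical_parents,
        vapply(doc$blocks, `[[`, character(1), "concept"))
      late <- setdiff(present_parents, concepts_so_far)
      for (p in late) {
        note("block_order", block$concept,
             paste0("critical-parent concept '", p, "' appears in a later block"))
      }
    }
    concepts_so_far <- c(concepts_so_far, block$concept)
    for (r in block$records) {
      if (r$local_id %in% seen_ids) {
        note("duplicate_local_id", r$local_id, "local_id reused")
      }
      for (dep in names(r$parent_refs)) {
        if (!(r$parent_refs[[dep]] %in% c(seen_ids, r$local_id))) {
          note("unresolved_parent_ref", r$local_id,
               paste0("parent_ref '", dep, "' -> '", r$parent_refs[[dep]],
                      "' not found in an earlier or same block"))
        }
      }
      seen_ids <- c(seen_ids, r$local_id)
      for (p in r$provenance) {
        if (!(paste0(p$source, "\x1f", p$version) %in% sv_keys)) {
          note("missing_source_version", r$local_id,
               paste0("provenance (", p$source, ", ", p$version,
                      ") not listed in source_versions"))
        }
      }
    }
  }
  if (length(bad) == 0L) {
    tibble::tibble(type = character(), where = character(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Import a BIORJ document into a warehouse
#'
#' Validates the document (rejecting it with the violation list otherwise),
#' then upserts its records block by block: local parent references are
#' rewritten to target record ids, unicity merge applies, and provenance
#' travels with each record. Re-importing the same document creates zero
#' records.
#'
#' @param store A `warehouse` whose concept graph covers every concept in the
#'   document.
#' @param doc A `biorj_document`.
#' @return An import report tibble: one row per concept with `created` and
#'   `merged` counts.
#' @export
import_biorj <- function(store, doc) {
  stopifnot(inherits(store, "warehouse"), inherits(doc, "biorj_document"))
  viol <- validate_biorj(doc, graph = store$graph)
  if (nrow(viol) > 0L) {
    stop("BIORJ document failed validation: ",
         paste(unique(viol$detail), collapse = "; "), call. = FALSE)
  }
  unknown <- setdiff(vapply(doc$blocks, `[[`, character(1), "concept"),
                     names(store$graph$concepts))
  if (length(unknown) > 0L) {
    stop("document contains concept(s) unknown to the target graph: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  id_map <- new.env(parent = emptyenv())
  report <- list()
  for (block in doc$blocks) {
    created <- 0L; merged <- 0L
    for (r in block$records) {
      links <- lapply(r$parent_refs, function(ref) get(ref, envir = id_map))
      rec <- structure(list(concept = block$concept, key_values = r$key_values,
                            attributes = list(), parent_links = links,
                            provenance = r$provenance),
                       class = "warehouse_record")
      res <- upsert_record(store, rec)
      # attributes come with their own per-source rows; attach them verbatim
      if (length(r$attributes) > 0L) {
        stored <- ws_record(store, res$record_id)
        for (row in r$attributes) {
          row <- row[c("source", "field", "value")]
          if (!any(vapply(stored$attributes, identical, logical(1), row))) {
            stored$attributes <- c(stored$attributes, list(row))
          }
        }
        store$records[[as.character(res$record_id)]] <- stored
      }
      assign(r$local_id, res$record_id, envir = id_map)
      if (res$status == "created") created <- created + 1L else merged <- merged + 1L
    }
    report[[length(report) + 1L]] <- tibble::tibble(
      concept = block$concept, created = created, merged = merged)
  }
  if (length(report) == 0L) {
    return(tibble::tibble(concept = character(), created = integer(),
                          merged = integer()))
  }
  dplyr::bind_rows(report)
}

#' Canonical form of a BIORJ document
#'
#' Strips volatile generator metadata (instance id, creation timestamp),
#' renames local ids to sequential canonical ids and sorts records and
#' source versions; two documents describing the same logical payload have
#' identical canonical forms. Used by [biorj_equal()].
#'
#' @param doc A `biorj_document`.
#' @return A plain list (no class).
#' @export
biorj_canonical <- function(doc) {
  stopifnot(inherits(doc, "biorj_document"))
  rename <- new.env(parent = emptyenv())
  blocks <- lapply(doc$blocks, function(block) {
    keyjson <- vapply(block$records, function(r)
      canonical_json(sort_named(lapply(r$key_values, as.character))),
      character(1))
    recs <- block$records[order(keyjson)]
    for (i in seq_along(recs)) {
      assign(recs[[i]]$local_id, paste0(block$concept, "#", i), envir = rename)
    }
    recs
  })
  names(blocks) <- vapply(doc$blocks, `[[`, character(1), "concept")
  out_blocks <- lapply(names(blocks), function(cn) {
    list(concept = cn, records = lapply(blocks[[cn]], function(r) {
      refs <- lapply(sort_named(r$parent_refs), function(ref)
        get(ref, envir = rename))
      list(local_id = get(r$local_id, envir = rename),
           key_values = sort_named(lapply(r$key_values, as.character)),
           attributes = r$attributes[order(vapply(r$attributes, canonical_json,
                                                  character(1)))],
           parent_refs = refs,
           provenance = r$provenance[order(vapply(r$provenance, canonical_json,
                                                  character(1)))])
    }))
  })
  sv <- doc$source_versions[order(vapply(doc$source_versions, canonical_json,
                                         character(1)))]
  list(format_version = doc$format_version, source_versions = unname(sv),
       blocks = out_blocks)
}

#' Compare two BIORJ documents up to local-id renaming and timestamps
#'
#' @param a,b `biorj_document` objects.
#' @return `TRUE` when the canonical forms are identical.
#' @export
biorj_equal <- function(a, b) {
  identical(canonical_json(biorj_canonical(a)), canonical_json(biorj_canonical(b)))
}

#' Write / read a BIORJ document as JSON
#'
#' `.biorj` files are UTF-8 JSON with sorted keys for byte-stable output
#' given identical inputs.
#'
#' @param doc A `biorj_document`.
#' @param path File path (conventionally `*.biorj`).
#' @return `write_biorj` returns `path` invisibly; `read_biorj` returns a
#'   `biorj_document`.
#' @export
write_biorj <- function(doc, path) {
  stopifnot(inherits(doc, "biorj_document"))
  writeLines(canonical_json(unclass(doc)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_biorj
#' @export
read_biorj <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  biorj_from_list(raw)
}

biorj_from_list <- function(raw) {
  need <- c("format_version", "generator", "source_versions", "blocks")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("not a BIORJ document; missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$blocks <- lapply(raw$blocks, function(block) {
    block$records <- lapply(block$records, function(r) {
      r$key_values <- lapply(r$key_values, as.character)
      r$parent_refs <- lapply(r$parent_refs %||% list(), as.character)
      r$attributes <- lapply(r$attributes %||% list(), function(a)
        lapply(a, as.character))
      r$provenance <- lapply(r$provenance %||% list(), function(p)
        lapply(p, as.character))
      r
    })
    block
  })
  structure(raw[need], class = "biorj_document")
}

#' Linearize a BIORJ document to plain text / parse it back
#'
#' The linear form is line-oriented: `#BIORJ`, `#GENERATOR` and `#SOURCES`
#' header lines, one `#CONCEPT <name>` header per block, and one
#' tab-delimited line per record whose five cells (local id, key values,
#' attributes, parent refs, provenance) are JSON-encoded.
#' `parse_linear(linearize_biorj(doc))` is isomorphic to `doc`.
#'
#' @param doc A `biorj_document`.
#' @param text Character vector of lines (or a single string with newlines).
#' @return `linearize_biorj` returns a single string;
#'   `parse_linear` returns a `biorj_document`.
#' @export
linearize_biorj <- function(doc) {
  stopifnot(inherits(doc, "biorj_document"))
  lines <- c(
    paste0("#BIORJ\t", doc$format_version),
    paste0("#GENERATOR\t", canonical_json(doc$generator)),
    paste0("#SOURCES\t", canonical_json(doc$source_versions))
  )
  for (block in doc$blocks) {
    lines <- c(lines, paste0("#CONCEPT\t", block$concept))
    for (r in block$records) {
      lines <- c(lines, paste(
        canonical_json(r$local_id), canonical_json(r$key_values),
        canonical_json(r$attributes), canonical_json(r$parent_refs),
        canonical_json(r$provenance), sep = "\t"))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname linearize_biorj
#' @export
parse_linear <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(lines)]
  fail <- function(i, why) {
    stop("malformed linearized BIORJ at line ", i, ": ", why, call. = FALSE)
  }
  parse_cell <- function(i, cell) {
    tryCatch(jsonlite::fromJSON(cell, simplifyVector = FALSE),
             error = function(e) fail(i, paste0("bad JSON cell: ",
                                                conditionMessage(e))))
  }
  doc <- list(format_version = NULL, generator = NULL,
              source_versions = list(), blocks = list())
  current <- NULL
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (startsWith(lines[[i]], "#")) {
      if (length(parts) != 2L) fail(i, "header line must have two cells")
      switch(parts[[1L]],
        "#BIORJ" = { doc$format_version <- parts[[2L]] },
        "#GENERATOR" = { doc$generator <- parse_cell(i, parts[[2L]]) },
        "#SOURCES" = { doc$source_versions <- parse_cell(i, parts[[2L]]) },
        "#CONCEPT" = {
          if (!is.null(current)) doc$blocks <- c(doc$blocks, list(current))
          current <- list(concept = parts[[2L]], records = list())
        },
        fail(i, paste0("unknown header '", parts[[1L]], "'"))
      )
    } else {
      if (is.null(current)) fail(i, "record line before any #CONCEPT header")
      if (length(parts) != 5L) fail(i, "record line must have five cells")
      current$records <- c(current$records, list(list(
        local_id = as.character(parse_cell(i, parts[[1L]])),
        key_values = parse_cell(i, parts[[2L]]),
        attributes = parse_cell(i, parts[[3L]]),
        parent_refs = parse_cell(i, parts[[4L]]),
        provenance = parse_cell(i, parts[[5L]]))))
    }
  }
  if (!is.null(current)) doc$blocks <- c(doc$blocks, list(current))
  if (is.null(doc$format_version)) stop("missing #BIORJ header", call. = FALSE)
  biorj_from_list(doc)
}

#' @export
print.biorj_document <- function(x, ...) {
  n <- sum(vapply(x$blocks, function(b) length(b$records), integer(1)))
  cat("<biorj_document> format", x$format_version, "-", length(x$blocks),
      "concept blocks,", n, "records,", length(x$source_versions),
      "source versions\n")
  invisible(x)
}

#' Tidy a BIORJ document into a per-record tibble
#'
#' @param x A `biorj_document`.
#' @param ... Unused.
#' @return A tibble: block order, concept, local id, key values (compact
#'   string), parent refs and sources per record.
#' @export
tidy.biorj_document <- function(x, ...) {
  rows <- list()
  for (bi in seq_along(x$blocks)) {
    block <- x$blocks[[bi]]
    concept_name <- block$concept
    for (r in block$records) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = bi, concept = concept_name, local_id = r$local_id,
        key = paste(unlist(r$key_values), collapse = ":"),
        parent_refs = paste(unlist(r$parent_refs), collapse = ","),
        sources = paste(sort(unique(vapply(r$provenance, function(p)
          as.character(p$source), character(1)))), collapse = ","))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(block = integer(), concept = character(),
                          local_id = character(), key = character(),
                          parent_refs = character(), sources = character()))
  }
  dplyr::bind_rows(rows)
}
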