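#' Define a scientific concept
#'
#' A scientific concept is a unit of biological meaning (an organism, a gene,
#' a protein, a cell-based assay, ...) modelled as a node of the dependency
#' graph. Its parents are split into *critical* dependencies, without which a
#' record of this concept loses scientific integrity (a gene requires the
#' organism it is defined in), and *related* dependencies that merely augment
#' a record (publications, external identifiers, evidence codes).
#'
#' The annotation flags `"publications"` and `"evidence_ontology"` are
#' shorthand for related dependencies on the `publication` and
#' `evidence_ontology` concepts; they are expanded into related-parent edges
#' when the graph is validated.
#'
#' @param name Unique concept name within a graph.
#' @param ecosystem Free-text ecosystem tag (e.g. `"genomic"`, `"assay"`).
#' @param critical Character vector of critical parent concept names.
#' @param related Character vector of related parent concept names.
#' @param unicity_key Ordered character vector of field names whose values
#'   identify a record of this concept. Must be non-empty.
#' @param annotation_flags Subset of `c("publications", "evidence_ontology")`.
#' @return An object of class `concept_def`.
#' @examples
#' concept("gene", "genomic", critical = "organism", unicity_key = "symbol")
#' @export
concept <- function(name, ecosystem = "general", critical = character(),
                    related = character(), unicity_key = "id",
                    annotation_flags = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(unicity_key) == 0L) {
    stop("concept '", name, "': unicity_key must be non-empty", call. = FALSE)
  }
  critical <- unique(as.character(critical))
  related <- unique(as.character(related))
  bad_flags <- setdiff(annotation_flags, c("publications", "evidence_ontology"))
  if (length(bad_flags) > 0L) {
    stop("concept '", name, "': unknown annotation flags: ",
         paste(bad_flags, collapse = ", "), call. = FALSE)
  }
  both <- intersect(critical, related)
  if (length(both) > 0L) {
    stop("concept '", name, "': parents cannot be both critical and related: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, ecosystem = ecosystem, critical_parents = critical,
         related_parents = related, unicity_key = as.character(unicity_key),
         annotation_flags = as.character(annotation_flags)),
    class = "concept_def"
  )
}

#' Create a concept dependency graph
#'
#' @param ... `concept_def` objects to register, in any order. Forward
#'   references to not-yet-registered parents are allowed until
#'   [validate_graph()] is called.
#' @return An object of class `concept_graph`.
#' @seealso [register_concept()], [validate_graph()], [dependency_level()]
#' @export
concept_graph <- function(...) {
  g <- structure(list(concepts = list(), levels = NULL), class = "concept_graph")
  for (def in list(...)) g <- register_concept(g, def)
  g
}

#' Register a concept in a graph
#'
#' @param graph A `concept_graph`.
#' @param def A `concept_def`.
#' @return The graph with the concept added (levels cache invalidated).
#' @export
register_concept <- function(graph, def) {
  stopifnot(inherits(graph, "concept_graph"), inherits(def, "concept_def"))
  if (def$name %in% names(graph$concepts)) {
    stop("concept '", def$name, "' is already registered", call. = FALSE)
  }
  graph$concepts[[def$name]] <- def
  graph$levels <- NULL
  graph
}

# Related parents with annotation-flag edges expanded.
cg_related_parents <- function(def) {
  extra <- character()
  if ("publications" %in% def$annotation_flags) extra <- c(extra, "publication")
  if ("evidence_ontology" %in% def$annotation_flags) extra <- c(extra, "evidence_ontology")
  setdiff(unique(c(def$related_parents, extra)), def$name)
}

# Kahn's algorithm over critical edges: returns list(levels, cyclic_concepts).
# Levels follow the root-at-one rule: no critical parent -> 1, otherwise
# 1 + max over critical parents.
cg_kahn <- function(graph) {
  nms <- names(graph$concepts)
  parents <- lapply(graph$concepts, function(d) intersect(d$critical_parents, nms))
  names(parents) <- nms
  indeg <- vapply(parents, length, integer(1))
  children <- stats::setNames(vector("list", length(nms)), nms)
  for (child in nms) {
    for (p in parents[[child]]) children[[p]] <- c(children[[p]], child)
  }
  levels <- stats::setNames(rep(NA_integer_, length(nms)), nms)
  queue <- nms[indeg == 0L]
  levels[queue] <- 1L
  done <- character()
  while (length(queue) > 0L) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    done <- c(done, node)
    for (child in children[[node]]) {
      levels[[child]] <- max(levels[[child]], levels[[node]] + 1L, na.rm = TRUE)
      indeg[[child]] <- indeg[[child]] - 1L
      if (indeg[[child]] == 0L) queue <- c(queue, child)
    }
  }
  list(levels = levels, cyclic = setdiff(nms, done))
}

#' Validate a concept graph
#'
#' Checks that every parent reference (critical and related, including edges
#' induced by annotation flags) resolves to a registered concept and that the
#' directed graph over *critical* edges is acyclic. Related edges are excluded
#' from cycle detection and level computation: levels are defined by critical
#' dependencies only, and related dependencies may legitimately form cycles
#' across ecosystems (a publication citing a gene that cites the publication).
#'
#' On success, dependency levels are computed for every concept and stored in
#' the returned graph.
#'
#' @param graph A `concept_graph`.
#' @return An object of class `graph_validation`: a list with elements
#'   `valid` (logical), `problems` (tibble with columns `type`, `concept`,
#'   `detail`) and `graph` (the input graph, with `$levels` populated when
#'   valid).
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "concept_graph"))
  nms <- names(graph$concepts)
  problems <- list()
  for (def in graph$concepts) {
    missing <- setdiff(c(def$critical_parents, cg_related_parents(def)), nms)
    for (m in missing) {
      problems[[length(problems) + 1L]] <- tibble::tibble(
        type = "unresolved_parent", concept = def$name,
        detail = paste0("parent '", m, "' is not registered"))
    }
  }
  kahn <- cg_kahn(graph)
  for (cyc in sort(kahn$cyclic)) {
    problems[[length(problems) + 1L]] <- tibble::tibble(
      type = "critical_cycle", concept = cyc,
      detail = "concept participates in a cycle of critical dependencies")
  }
  problems <- if (length(problems) > 0L) dplyr::bind_rows(problems) else
    tibble::tibble(type = character(), concept = character(), detail = character())
  valid <- nrow(problems) == 0L
  if (valid) graph$levels <- kahn$levels[sort(nms)]
  structure(list(valid = valid, problems = problems, graph = graph),
            class = "graph_validation")
}

#' @export
print.graph_validation <- function(x, ...) {
  if (x$valid) {
    cat("Valid concept graph:", length(x$graph$concepts), "concepts, max level",
        if (length(x$graph$levels)) max(x$graph$levels) else 0L, "\n")
  } else {
    cat("Invalid concept graph:", nrow(x$problems), "problem(s)\n")
    print(x$problems)
  }
  invisible(x)
}

# Returns a graph with levels populated, erroring when invalid.
cg_validated <- function(graph) {
  if (!is.null(graph$levels)) return(graph)
  v <- validate_graph(graph)
  if (!v$valid) {
    stop("concept graph is invalid: ",
         paste(unique(v$problems$detail), collapse = "; "), call. = FALSE)
  }
  v$graph
}

cg_check_known <- function(graph, names, what = "concept") {
  unknown <- setdiff(names, names(graph$concepts))
  if (length(unknown) > 0L) {
    stop("unknown ", what, "(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Dependency level of a concept
#'
#' A concept without critical dependencies sits at root level 1; any other
#' concept sits one level above the deepest of its critical parents
#' (`1 + max(parent levels)`), i.e. at one plus the length of the longest
#' critical-dependency path up to a root.
#'
#' @param graph A validated (or validatable) `concept_graph`.
#' @param concept Concept name.
#' @return Integer dependency level (>= 1).
#' @examples
#' g <- chain_graph()
#' dependency_level(g, "organism")         # 1
#' dependency_level(g, "genomic_sequence") # 3
#' @export
dependency_level <- function(graph, concept) {
  graph <- cg_validated(graph)
  cg_check_known(graph, concept)
  unname(graph$levels[[concept]])
}

#' Valid update order over a subset of concepts
#'
#' Returns a topological order of `subset` over critical edges: every critical
#' parent precedes its children, so processing in this order guarantees all
#' parent concepts are handled first. Ties are broken by ascending
#' `(level, name)`, which makes the output deterministic.
#'
#' @param graph A `concept_graph`.
#' @param subset Concept names; must be closed under critical parents.
#'   Defaults to all concepts.
#' @return Character vector: `subset` in a valid processing order.
#' @export
update_order <- function(graph, subset = NULL) {
  graph <- cg_validated(graph)
  if (is.null(subset)) subset <- names(graph$concepts)
  cg_check_known(graph, subset)
  subset <- unique(subset)
  missing <- character()
  for (nm in subset) {
    missing <- c(missing, setdiff(
      intersect(graph$concepts[[nm]]$critical_parents, names(graph$concepts)),
      subset))
  }
  missing <- unique(missing)
  if (length(missing) > 0L) {
    stop("subset is not closed under critical parents; missing: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  # Levels strictly increase along critical edges, so ordering by
  # (level, name) is itself a topological order.
  subset[order(graph$levels[subset], subset)]
}

#' Dependency closure of a set of concepts
#'
#' The set of concepts needed to fully describe the seeds: the seeds plus
#' everything reachable by repeatedly following critical-parent edges. With
#' `include_related = TRUE`, related-parent edges (including annotation-flag
#' edges) are followed transitively as well.
#'
#' @param graph A `concept_graph`.
#' @param seeds Concept names.
#' @param include_related Follow related edges too? Default `FALSE`.
#' @return Sorted character vector of concept names (a superset of `seeds`).
#' @export
dependency_closure <- function(graph, seeds, include_related = FALSE) {
  graph <- cg_validated(graph)
  cg_check_known(graph, seeds, "seed concept")
  seen <- unique(seeds)
  queue <- seen
  while (length(queue) > 0L) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    def <- graph$concepts[[node]]
    parents <- def$critical_parents
    if (include_related) parents <- c(parents, cg_related_parents(def))
    parents <- intersect(parents, names(graph$concepts))
    new <- setdiff(parents, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  sort(seen)
}

#' Read a concept graph from a YAML config file
#'
#' The file maps each concept name to a block with optional keys `ecosystem`,
#' `critical`, `related`, `unicity_key` and `flags` (annotation flags).
#'
#' @param path Path to the YAML file.
#' @return A validated `concept_graph`.
#' @export
read_concept_graph <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("concept graph config must be a named mapping", call. = FALSE)
  }
  g <- concept_graph()
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    g <- register_concept(g, concept(
      name = nm,
      ecosystem = entry$ecosystem %||% "general",
      critical = unlist(entry$critical) %||% character(),
      related = unlist(entry$related) %||% character(),
      unicity_key = unlist(entry$unicity_key) %||% "id",
      annotation_flags = unlist(entry$flags) %||% character()
    ))
  }
  cg_validated(g)
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> with", length(x$concepts), "concepts")
  if (!is.null(x$levels) && length(x$levels)) {
    cat(" (validated, max level ", max(x$levels), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a concept graph into a tibble
#'
#' @param x A `concept_graph`.
#' @param ... Unused.
#' @return A tibble with one row per concept: `concept`, `ecosystem`,
#'   `level` (NA when the graph has not been validated), list-columns of
#'   critical and related parents, and the unicity key.
#' @importFrom generics tidy
#' @export
tidy.concept_graph <- function(x, ...) {
  lv <- tryCatch(cg_validated(x)$levels, error = function(e) NULL)
  tibble::tibble(
    concept = names(x$concepts),
    ecosystem = vapply(x$concepts, `[[`, character(1), "ecosystem"),
    level = if (is.null(lv)) NA_integer_ else unname(lv[names(x$concepts)]),
    critical_parents = lapply(x$concepts, `[[`, "critical_parents"),
    related_parents = lapply(x$concepts, cg_related_parents),
    unicity_key = vapply(x$concepts, function(d)
      paste(d$unicity_key, collapse = ","), character(1))
  ) |>
    dplyr::arrange(.data$level, .data$concept)
}

#' Plot a concept graph layered by dependency level
#'
#' Concepts are laid out on horizontal layers (level 1 at the top); critical
#' edges are drawn solid, related edges dashed.
#'
#' @param object A validated `concept_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.concept_graph <- function(object, ...) {
  g <- cg_validated(object)
  td <- tidy(g)
  td <- dplyr::group_by(td, .data$level) |>
    dplyr::mutate(x = seq_along(.data$concept) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  pos <- stats::setNames(split(c(td$x, -td$level), rep(1:2, each = nrow(td))), c("x", "y"))
  nodes <- tibble::tibble(concept = td$concept, x = td$x, y = -td$level)
  edge_rows <- list()
  for (i in seq_len(nrow(td))) {
    for (kind in c("critical", "related")) {
      ps <- if (kind == "critical") td$critical_parents[[i]] else td$related_parents[[i]]
      for (p in intersect(ps, nodes$concept)) {
        edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
          x = nodes$x[nodes$concept == p], y = nodes$y[nodes$concept == p],
          xend = td$x[i], yend = -td$level[i], kind = kind)
      }
    }
  }
  edges <- if (length(edge_rows)) dplyr::bind_rows(edge_rows) else
    tibble::tibble(x = numeric(), y = numeric(), xend = numeric(),
                   yend = numeric(), kind = character())
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$kind),
      colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$concept), size = 2.6) +
    ggplot2::scale_y_continuous(
      breaks = -seq_len(max(g$levels)),
      labels = function(b) paste0("L", -b)) +
    ggplot2::labs(x = NULL, y = "dependency level", linetype = "dependency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
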