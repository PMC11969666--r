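#' Define a data-source adapter
#'
#' An adapter is the per-source update contract: `check_release()` reports
#' the newest available version token (or `NULL` when the source is
#' unreachable / has none), `download(version)` fetches a payload handle, and
#' `process(store, payload)` loads the payload into the warehouse and returns
#' record counts. Version tokens are opaque strings compared for inequality
#' only — real sources mix dates, release numbers and checksums.
#'
#' @param name Source name (unique within a scheduler).
#' @param produces Concept names this source populates (informational).
#' @param parents Names of parent sources that must be current before this
#'   source may process (the source-level critical dependencies).
#' @param check_release Function `()` returning the newest version token or
#'   `NULL`.
#' @param download Function `(version)` returning a payload handle; defaults
#'   to returning the version itself.
#' @param process Function `(store, payload)`; any error marks the source
#'   failed and puts its descendants on hold.
#' @return An object of class `source_adapter`.
#' @export
source_adapter <- function(name, produces = character(), parents = character(),
                           check_release = function() NULL,
                           download = NULL, process = function(store, payload) 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(download)) download <- function(version) version
  structure(list(name = name, produces = produces, parents = parents,
                 check_release = check_release, download = download,
                 process = process),
            class = "source_adapter")
}

#' Create a scheduler over a set of adapters
#'
#' Verifies that the parent-source graph is acyclic (erroring before any side
#' effect otherwise) and initializes every source as `up_to_date` with no
#' known version. The scheduler is environment-backed: [run_cycle()] and
#' [mark_resolved()] mutate it in place.
#'
#' @param adapters List of `source_adapter` objects.
#' @return An object of class `scheduler`.
#' @export
scheduler <- function(adapters) {
  stopifnot(all(vapply(adapters, inherits, logical(1), "source_adapter")))
  nms <- vapply(adapters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate adapter names", call. = FALSE)
  names(adapters) <- nms
  unknown <- setdiff(unlist(lapply(adapters, `[[`, "parents")), nms)
  if (length(unknown) > 0L) {
    stop("unknown parent source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # reuse the concept-graph machinery to order sources and reject cycles
  g <- concept_graph()
  for (a in adapters) {
    g <- register_concept(g, concept(a$name, "source", critical = a$parents))
  }
  v <- validate_graph(g)
  if (!v$valid) {
    stop("source graph contains a cycle of parent dependencies: ",
         paste(v$problems$concept[v$problems$type == "critical_cycle"],
               collapse = ", "), call. = FALSE)
  }
  s <- new.env(parent = emptyenv())
  s$adapters <- adapters
  s$order <- update_order(v$graph)
  s$graph <- v$graph
  s$state <- lapply(adapters, function(a)
    list(status = "up_to_date", current = NA_character_,
         pending = NA_character_, payload = NULL, prev_payload = NULL,
         last_error = NA_character_))
  s$log <- orch_empty_log()
  s$seq <- 0L
  s$cycle <- 0L
  class(s) <- "scheduler"
  s
}

orch_empty_log <- function() {
  tibble::tibble(seq = integer(), cycle = integer(), source = character(),
                 action = character(), version = character(),
                 detail = character())
}

orch_event <- function(sched, source, action, version = NA_character_,
                       detail = NA_character_) {
  sched$seq <- sched$seq + 1L
  sched$log <- dplyr::bind_rows(sched$log, tibble::tibble(
    seq = sched$seq, cycle = sched$cycle, source = source, action = action,
    version = as.character(version), detail = as.character(detail)))
}

# transitive ancestors of a source over parent edges
orch_ancestors <- function(sched, source) {
  setdiff(dependency_closure(sched$graph, source), source)
}

#' Run one update cycle
#'
#' Visits every source once, parents before children (a topological order of
#' the source graph). For each source: the release check runs; a new version
#' becomes pending work; pending work is processed only when *every* direct
#' parent is current — no unprocessed release, not failed — and no transitive
#' ancestor is failed. On success the previous payload is cleaned up and the
#' version is bumped in the warehouse's versioning table; on failure the
#' source is marked failed (its payload kept for diagnosis) and its
#' descendants with pending work are held until [mark_resolved()].
#'
#' @param sched A `scheduler`.
#' @param store The `warehouse` that processing hooks load into and whose
#'   versioning table records the bumps.
#' @return The tibble of events emitted during this cycle (the full log lives
#'   in `event_log(sched)`).
#' @export
run_cycle <- function(sched, store) {
  stopifnot(inherits(sched, "scheduler"), inherits(store, "warehouse"))
  sched$cycle <- sched$cycle + 1L
  first_seq <- sched$seq + 1L
  for (nm in sched$order) {
    a <- sched$adapters[[nm]]
    st <- sched$state[[nm]]
    orch_event(sched, nm, "check")
    newest <- a$check_release()
    if (!is.null(newest) && !identical(newest, st$current) &&
        !identical(newest, st$pending)) {
      st$pending <- newest
      st$payload <- NULL
      if (st$status != "failed") st$status <- "new_release"
    }
    if (st$status == "failed" || is.na(st$pending)) {
      sched$state[[nm]] <- st
      next
    }
    parents_ok <- all(vapply(a$parents, function(p) {
      ps <- sched$state[[p]]
      ps$status != "failed" && is.na(ps$pending)
    }, logical(1)))
    ancestor_failed <- any(vapply(orch_ancestors(sched, nm), function(p)
      sched$state[[p]]$status == "failed", logical(1)))
    if (!parents_ok || ancestor_failed) {
      st$status <- "held"
      sched$state[[nm]] <- st
      orch_event(sched, nm, "hold", st$pending)
      next
    }
    if (is.null(st$payload)) {
      st$status <- "downloading"
      st$payload <- a$download(st$pending)
      orch_event(sched, nm, "download", st$pending)
    }
    st$status <- "processing"
    orch_event(sched, nm, "process_start", st$pending)
    res <- tryCatch(a$process(store, st$payload), error = function(e) e)
    if (inherits(res, "error")) {
      st$status <- "failed"
      st$last_error <- conditionMessage(res)
      sched$state[[nm]] <- st
      orch_event(sched, nm, "process_fail", st$pending, st$last_error)
      next
    }
    orch_event(sched, nm, "process_ok", st$pending)
    if (!is.null(st$prev_payload)) {
      orch_event(sched, nm, "cleanup", st$current,
                 "previous payload removed after successful processing")
    }
    record_source_version(store, nm, st$pending)
    orch_event(sched, nm, "version_bump", st$pending)
    st$current <- st$pending
    st$pending <- NA_character_
    st$prev_payload <- st$payload
    st$status <- "up_to_date"
    st$last_error <- NA_character_
    sched$state[[nm]] <- st
  }
  dplyr::filter(sched$log, .data$seq >= first_seq)
}

#' Resolve a failed source
#'
#' Resets a failed source to `new_release` (its pending version is retained)
#' so that it — and its held descendants — become eligible again on the next
#' [run_cycle()].
#'
#' @param sched A `scheduler`.
#' @param source Name of a source currently in the `failed` state.
#' @return The scheduler, invisibly.
#' @export
mark_resolved <- function(sched, source) {
  stopifnot(inherits(sched, "scheduler"))
  st <- sched$state[[source]]
  if (is.null(st)) stop("unknown source '", source, "'", call. = FALSE)
  if (st$status != "failed") {
    stop("source '", source, "' is not failed (status: ", st$status, ")",
         call. = FALSE)
  }
  st$status <- "new_release"
  st$last_error <- NA_character_
  sched$state[[source]] <- st
  orch_event(sched, source, "resume", st$pending)
  invisible(sched)
}

#' Per-source scheduler status
#'
#' @param sched A `scheduler`.
#' @return A tibble: `source`, `status`, `current`, `pending`, `last_error`,
#'   in update order.
#' @export
scheduler_status <- function(sched) {
  stopifnot(inherits(sched, "scheduler"))
  dplyr::bind_rows(lapply(sched$order, function(nm) {
    st <- sched$state[[nm]]
    tibble::tibble(source = nm, status = st$status, current = st$current,
                   pending = st$pending, last_error = st$last_error)
  }))
}

#' Full event log of a scheduler
#'
#' Append-only, strictly increasing sequence numbers; one row per event with
#' actions among check, download, process_start, process_ok, process_fail,
#' cleanup, version_bump, hold and resume.
#'
#' @param sched A `scheduler`.
#' @return A tibble.
#' @export
event_log <- function(sched) {
  stopifnot(inherits(sched, "scheduler"))
  sched$log
}

#' @export
print.scheduler <- function(x, ...) {
  cat("<scheduler>", length(x$adapters), "sources,", x$cycle,
      "cycle(s) run,", nrow(x$log), "events\n")
  print(scheduler_status(x))
  invisible(x)
}

#' @export
tidy.scheduler <- function(x, ...) scheduler_status(x)

#' @export
glance.scheduler <- function(x, ...) {
  st <- scheduler_status(x)
  tibble::tibble(n_sources = nrow(st), n_cycles = x$cycle,
                 n_events = nrow(x$log),
                 n_failed = sum(st$status == "failed"),
                 n_held = sum(st$status == "held"))
}
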