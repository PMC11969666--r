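#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Canonical JSON serialization used for unicity keys and logical dumps:
# sorted names, unboxed scalars, no digits lost.
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

# Sort a named list by name (recursively at the top level only).
sort_named <- function(x) {
  if (is.null(names(x)) || length(x) == 0L) return(x)
  x[order(names(x))]
}
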