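#' Create or load a registry of beyond-atlas ("U") graphs
#'
#' Coiled coils with more than seven helices fall outside the atlas. They
#' are catalogued on first encounter: the first such graph is named "U1",
#' and every later graph is either isomorphic to a registered one (and
#' reuses its name) or opens the next "U" category. The registry can be
#' persisted as JSON so that names are stable across runs.
#'
#' @param path optional JSON file; if it exists it is loaded, and every
#'   later addition is written back to it. `NULL` keeps the registry
#'   in-memory only.
#' @return a `u_registry` object (environment with `entries` and `path`).
#' @examples
#' reg <- u_registry()
#' c8 <- simple_graph(8, cbind(1:8, c(2:8, 1)))
#' classify_component(c8, registry = reg)  # "U1"
#' @export
u_registry <- function(path = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$entries <- list()
  reg$path <- path
  if (!is.null(path) && file.exists(path)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    reg$entries <- lapply(raw, function(e) {
      edges <- if (length(e$edges)) {
        matrix(as.integer(unlist(e$edges)), ncol = 2L, byrow = TRUE)
      } else NULL
      list(name = e$name, graph = simple_graph(as.integer(e$n), edges))
    })
  }
  class(reg) <- "u_registry"
  reg
}

#' @export
print.u_registry <- function(x, ...) {
  cat("U-registry:", length(x$entries), "beyond-atlas graphs")
  if (!is.null(x$path)) cat(" (persisted at ", x$path, ")", sep = "")
  cat("\n")
  for (e in x$entries)
    cat(" ", e$name, ":", e$graph$n, "nodes,", nrow(e$graph$edges), "edges\n")
  invisible(x)
}

#' @export
length.u_registry <- function(x) length(x$entries)

registry_save <- function(reg) {
  if (is.null(reg$path)) return(invisible(FALSE))
  payload <- lapply(reg$entries, function(e) {
    list(name = e$name, n = e$graph$n,
         edges = apply(e$graph$edges, 1L, function(r) as.list(r), simplify = FALSE))
  })
  ok <- tryCatch({
    jsonlite::write_json(payload, reg$path, auto_unbox = TRUE)
    TRUE
  }, error = function(e) {
    warning("U-registry could not be persisted to ", reg$path, ": ",
            conditionMessage(e))
    FALSE
  })
  invisible(ok)
}

#' Name a connected component graph
#'
#' Returns the atlas name ("G<index>") for graphs of at most seven nodes.
#' Larger graphs are looked up in the U-registry by isomorphism; an
#' unrecognised graph is appended as the next "U" category (and persisted
#' when the registry has a file path).
#'
#' @param g a connected [simple_graph()] (or a component from
#'   [simplify_graph()]).
#' @param atlas an [enumerate_atlas()] table.
#' @param registry a [u_registry()]; required only for graphs with more
#'   than seven nodes.
#' @return the category name, e.g. `"G105"` or `"U1"`.
#' @export
classify_component <- function(g, atlas = enumerate_atlas(),
                               registry = u_registry()) {
  if (inherits(g, "cc_component")) g <- component_graph(g)
  idx <- atlas_index(g, atlas)
  if (!is.na(idx)) return(paste0("G", idx))
  for (e in registry$entries)
    if (is_isomorphic(g, e$graph)) return(e$name)
  name <- paste0("U", length(registry$entries) + 1L)
  registry$entries[[length(registry$entries) + 1L]] <- list(name = name, graph = g)
  registry_save(registry)
  name
}
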