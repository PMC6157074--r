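#' Build the helix-interaction graph under (scut, kcut)
#'
#' Interactions tighter than `scut` are grouped by unordered helix pair; a
#' pair retains its edges only when its total KIH count — knobs in both
#' directions summed — is strictly greater than `kcut` (so kcut = 2 demands
#' three or more shared interactions). Nodes are the helices left with at
#' least one retained edge.
#'
#' @param kih_set a [find_kih()] result.
#' @param scut SOCKET cutoff in Angstrom (<= the collection cutoff).
#' @param kcut knob cutoff, a non-negative integer.
#' @return a `helix_graph`: list with `nodes` (helix ids), `edges` (the
#'   retained directed interaction records), `pair_counts` (per unordered
#'   pair: counts in each direction, total, orientation), `scut`, `kcut`,
#'   and the `helices` object.
#' @examples
#' b <- make_bundle("triangle")
#' k <- find_kih(assign_helices(b$structure))
#' build_graph(k, scut = 7.0, kcut = 2)
#' @export
build_graph <- function(kih_set, scut, kcut) {
  if (kcut < 0) stop("kcut must be a non-negative integer")
  kcut <- as.integer(kcut)
  flt <- filter_kih(kih_set, scut)
  it <- flt$interactions
  if (nrow(it)) {
    pi_ <- pmin(it$knob_helix, it$hole_helix)
    pj <- pmax(it$knob_helix, it$hole_helix)
    key <- paste(pi_, pj)
    tot <- table(key)
    keep <- key %in% names(tot)[tot > kcut]
    it <- it[keep, , drop = FALSE]
    key <- key[keep]
  } else {
    key <- character(0)
  }
  pair_counts <- if (nrow(it)) {
    uk <- unique(key)
    i <- as.integer(sub(" .*", "", uk)); j <- as.integer(sub(".* ", "", uk))
    h <- kih_set$helices
    data.frame(
      helix_i = i, helix_j = j,
      n_i_to_j = vapply(seq_along(uk), function(q)
        sum(it$knob_helix == i[q] & it$hole_helix == j[q]), integer(1)),
      n_j_to_i = vapply(seq_along(uk), function(q)
        sum(it$knob_helix == j[q] & it$hole_helix == i[q]), integer(1)),
      n_total = as.integer(tot[uk]),
      orientation = vapply(seq_along(uk), function(q)
        pair_orientation(h, i[q], j[q]), character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(helix_i = integer(0), helix_j = integer(0),
               n_i_to_j = integer(0), n_j_to_i = integer(0),
               n_total = integer(0), orientation = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(
    nodes = sort(unique(c(it$knob_helix, it$hole_helix))),
    edges = it,
    pair_counts = pair_counts,
    scut = scut, kcut = kcut,
    structure_id = kih_set$structure_id,
    helices = kih_set$helices
  ), class = "helix_graph")
}

#' @export
print.helix_graph <- function(x, ...) {
  cat("helix_graph (scut ", x$scut, " A, kcut ", x$kcut, "): ",
      length(x$nodes), " node(s), ", nrow(x$edges),
      " directed KIH edge(s), ", nrow(x$pair_counts),
      " retained pair(s)\n", sep = "")
  invisible(x)
}

#' Simplify to undirected components
#'
#' Collapses directions and multiplicities to simple undirected edges,
#' drops isolated nodes, and splits the result into connected components —
#' one per coiled coil. Components are ordered by decreasing size, then by
#' smallest helix id.
#'
#' @param graph a [build_graph()] result.
#' @return list of `cc_component` objects; each holds the member helix ids,
#'   the simple edge set, and per-helix metadata (chain, residue range) plus
#'   per-edge orientation and KIH counts.
#' @export
simplify_graph <- function(graph) {
  pc <- graph$pair_counts
  if (!nrow(pc)) return(list())
  ids <- sort(unique(c(pc$helix_i, pc$helix_j)))
  ig <- igraph::make_empty_graph(length(ids), directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(match(pc$helix_i, ids), match(pc$helix_j, ids)))
  comp <- igraph::components(ig)
  h <- graph$helices
  out <- list()
  for (c_i in seq_len(comp$no)) {
    members <- ids[comp$membership == c_i]
    sel <- pc$helix_i %in% members & pc$helix_j %in% members
    meta <- h[h$helix_id %in% members,
              c("helix_id", "chain", "n_res", "first", "last"), drop = FALSE]
    out[[length(out) + 1L]] <- structure(list(
      nodes = members,
      edges = cbind(pc$helix_i[sel], pc$helix_j[sel]),
      pair_counts = pc[sel, , drop = FALSE],
      helix_metadata = meta,
      structure_id = graph$structure_id,
      scut = graph$scut, kcut = graph$kcut
    ), class = "cc_component")
  }
  sizes <- vapply(out, function(cp) length(cp$nodes), integer(1))
  minid <- vapply(out, function(cp) min(cp$nodes), numeric(1))
  out[order(-sizes, minid)]
}

#' @export
print.cc_component <- function(x, ...) {
  cat("cc_component:", length(x$nodes), "helices,", nrow(x$edges),
      "edges (helix ids:", paste(x$nodes, collapse = ", "), ")\n")
  invisible(x)
}

## relabel a component's helix ids to 1..k and return a simple_graph
component_graph <- function(component) {
  ids <- sort(component$nodes)
  e <- component$edges
  simple_graph(length(ids), cbind(match(e[, 1L], ids), match(e[, 2L], ids)))
}

#' Export components as JSON or edge-list text
#'
#' @param components list from [simplify_graph()].
#' @param path output file.
#' @param format `"json"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path, format = c("json", "edgelist")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- lapply(components, function(cp) list(
      nodes = cp$nodes,
      helices = cp$helix_metadata,
      edges = cp$pair_counts,
      scut = cp$scut, kcut = cp$kcut))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- unlist(lapply(seq_along(components), function(i) {
      cp <- components[[i]]
      sprintf("component %d: %s", i,
              paste(cp$edges[, 1L], cp$edges[, 2L], sep = "-", collapse = " "))
    }))
    writeLines(lines, path)
  }
  invisible(path)
}
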