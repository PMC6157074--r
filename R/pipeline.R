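#' Classify the coiled-coil composition of a structure
#'
#' Runs the full chain: helix assignment, KIH collection at the generous
#' 10-Angstrom cutoff, (scut, kcut) filtering, graph simplification, and
#' atlas naming of every connected component. Each component is one coiled
#' coil.
#'
#' @param structure a [parse_structure()] result (or the `$structure` of a
#'   [make_bundle()]).
#' @param scut SOCKET cutoff in Angstrom (default 7.0).
#' @param kcut knob cutoff (default 2: pairs need 3+ shared interactions).
#' @param atlas an [enumerate_atlas()] table.
#' @param registry a [u_registry()] for components beyond seven helices.
#' @param min_helix_length forwarded to [assign_helices()].
#' @param collection_cutoff forwarded to [find_kih()].
#' @param kih_set optionally a precomputed [find_kih()] result, skipping
#'   detection (used by [grid_scan()] so coordinates are scanned once).
#' @return a `cc_composition`: list with `structure_id`, `scut`, `kcut`,
#'   `components` (data frame: `name`, `n_helices`, `n_edges`, `helices`)
#'   and the underlying component objects.
#' @examples
#' b <- make_bundle("C6")
#' classify_structure(b$structure)
#' @export
classify_structure <- function(structure, scut = 7.0, kcut = 2L,
                               atlas = enumerate_atlas(),
                               registry = u_registry(),
                               min_helix_length = 7L,
                               collection_cutoff = 10.0,
                               kih_set = NULL) {
  stopifnot(scut <= collection_cutoff, kcut >= 0)
  if (is.null(kih_set)) {
    hel <- assign_helices(structure, min_helix_length = min_helix_length)
    kih_set <- find_kih(hel, collection_cutoff = collection_cutoff)
  }
  graph <- build_graph(kih_set, scut = scut, kcut = kcut)
  comps <- simplify_graph(graph)
  df <- if (length(comps)) {
    data.frame(
      name = vapply(comps, function(cp)
        classify_component(component_graph(cp), atlas, registry), character(1)),
      n_helices = vapply(comps, function(cp) length(cp$nodes), integer(1)),
      n_edges = vapply(comps, function(cp) nrow(cp$edges), integer(1)),
      helices = vapply(comps, function(cp)
        paste(cp$nodes, collapse = "+"), character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), n_helices = integer(0),
               n_edges = integer(0), helices = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(structure_id = structure$id, scut = scut, kcut = kcut,
                 components = df, component_objects = comps),
            class = "cc_composition")
}

#' @export
print.cc_composition <- function(x, ...) {
  cat("coiled-coil composition of ", x$structure_id,
      " (scut ", x$scut, " A, kcut ", x$kcut, "): ", sep = "")
  if (nrow(x$components)) {
    cat("{", paste(x$components$name, collapse = ", "), "}\n")
    print(x$components, row.names = FALSE)
  } else cat("{}\n")
  invisible(x)
}

DEFAULT_SCUTS <- seq(7.0, 9.0, by = 0.5)
DEFAULT_KCUTS <- 0:3

#' Scan a structure across the cutoff grid
#'
#' Classifies one structure at every (scut, kcut) combination — by default
#' the 20-cell grid scut = 7.0..9.0 by 0.5 crossed with kcut = 0..3. KIH
#' detection runs exactly once, at the collection cutoff; each cell only
#' re-filters the collected interactions.
#'
#' @param structure a [parse_structure()] result.
#' @param scuts,kcuts cutoff vectors (defaults above).
#' @inheritParams classify_structure
#' @return a `cc_grid`: list of one `cc_composition` per cell plus a tidy
#'   per-component data frame (`$table`: structure, scut, kcut, name,
#'   n_helices, n_edges, helices).
#' @export
grid_scan <- function(structure, scuts = DEFAULT_SCUTS, kcuts = DEFAULT_KCUTS,
                      atlas = enumerate_atlas(), registry = u_registry(),
                      min_helix_length = 7L, collection_cutoff = 10.0) {
  stopifnot(all(scuts <= collection_cutoff))
  hel <- assign_helices(structure, min_helix_length = min_helix_length)
  kih <- find_kih(hel, collection_cutoff = collection_cutoff)
  cells <- expand.grid(kcut = kcuts, scut = scuts)[, c("scut", "kcut")]
  comps <- vector("list", nrow(cells))
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    comp <- classify_structure(structure, scut = cells$scut[i],
                               kcut = cells$kcut[i], atlas = atlas,
                               registry = registry, kih_set = kih)
    comps[[i]] <- comp
    if (nrow(comp$components))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(structure = structure$id, scut = cells$scut[i],
                   kcut = cells$kcut[i], stringsAsFactors = FALSE),
        comp$components)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0), scut = numeric(0), kcut = integer(0),
               name = character(0), n_helices = integer(0),
               n_edges = integer(0), helices = character(0),
               stringsAsFactors = FALSE)
  structure(list(structure_id = structure$id, cells = cells,
                 compositions = comps, table = tab),
            class = "cc_grid")
}

#' @export
print.cc_grid <- function(x, ...) {
  cat("grid scan of", x$structure_id, ":", nrow(x$cells),
      "(scut, kcut) cells,", nrow(x$table), "component records\n")
  invisible(x)
}

#' Extract alpha-helical barrels
#'
#' A barrel appears as a cyclic component: connected with every helix
#' packing against exactly two neighbours. All cycle lengths from 3 up are
#' reported (with C3/C4 flagged), and `min_helices = 5` applies the usual
#' barrel definition.
#'
#' @param x a `cc_grid` or `cc_composition`.
#' @param min_helices smallest cycle reported (default 3; use 5 for the
#'   strict barrel definition).
#' @return data frame of barrel records: `structure_id`, `n_helices`,
#'   `scut`, `kcut`, `name`, `small_cycle` flag; one row per distinct helix
#'   set.
#' @export
find_barrels <- function(x, min_helices = 3L) {
  comps <- if (inherits(x, "cc_grid")) x$compositions else list(x)
  rows <- list()
  for (comp in comps) {
    for (i in seq_along(comp$component_objects)) {
      cp <- comp$component_objects[[i]]
      cyc <- is_cycle(component_graph(cp))
      if (!cyc$cycle || cyc$length < min_helices) next
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = cp$structure_id, n_helices = cyc$length,
        scut = comp$scut, kcut = comp$kcut,
        name = comp$components$name[i],
        small_cycle = cyc$length < 5L,
        helices = paste(cp$nodes, collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(structure_id = character(0), n_helices = integer(0),
                      scut = numeric(0), kcut = integer(0),
                      name = character(0), small_cycle = logical(0),
                      helices = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # deduplicate per structure: keep one record per distinct helix set
  out[!duplicated(paste(out$structure_id, out$helices)), , drop = FALSE]
}

#' Batch-classify structure files
#'
#' Runs [grid_scan()] on every input file, writing one JSON per structure
#' and an aggregated CSV (one row per structure, cell and component).
#' Unparseable files are logged and skipped.
#'
#' @param paths structure file paths.
#' @param out_dir output directory (created if needed).
#' @param scuts,kcuts cutoff grid.
#' @param atlas,registry,min_helix_length,collection_cutoff as in
#'   [grid_scan()].
#' @return the aggregated data frame, invisibly, with attribute `failures`
#'   (named character vector of error messages, empty on full success).
#' @export
run_batch <- function(paths, out_dir, scuts = DEFAULT_SCUTS,
                      kcuts = DEFAULT_KCUTS, atlas = enumerate_atlas(),
                      registry = u_registry(), min_helix_length = 7L,
                      collection_cutoff = 10.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_rows <- list()
  failures <- character(0)
  for (p in paths) {
    res <- tryCatch({
      s <- parse_structure(p)
      g <- grid_scan(s, scuts = scuts, kcuts = kcuts, atlas = atlas,
                     registry = registry,
                     min_helix_length = min_helix_length,
                     collection_cutoff = collection_cutoff)
      jsonlite::write_json(g$table,
                           file.path(out_dir, paste0(s$id, ".json")),
                           auto_unbox = TRUE, digits = NA)
      g$table
    }, error = function(e) {
      failures[[p]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res) && nrow(res)) all_rows[[length(all_rows) + 1L]] <- res
  }
  agg <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(structure = character(0), scut = numeric(0), kcut = integer(0),
               name = character(0), n_helices = integer(0),
               n_edges = integer(0), helices = character(0),
               stringsAsFactors = FALSE)
  utils::write.csv(agg, file.path(out_dir, "compositions.csv"),
                   row.names = FALSE)
  if (length(failures)) {
    writeLines(paste(names(failures), failures, sep = "\t"),
               file.path(out_dir, "failures.log"))
  }
  attr(agg, "failures") <- failures
  invisible(agg)
}
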