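## Synthetic ideal-helix bundle generator. Bundles with a prescribed
## interaction topology exercise every stage of the pipeline (helix
## assignment, KIH detection, graph building, atlas naming) without any
## external structure files.

# frozen generator geometry (calibrated once against the KIH detector so
# that facing helix pairs at the default spacing fire the four-nearest-
# centroid rule at scut 7.0 while all non-edge pairs stay silent)
SYNTH_CA_RADIUS <- 2.3       # A, CA helix radius
SYNTH_RISE <- 1.5            # A per residue
SYNTH_TWIST <- 100           # degrees per residue
SYNTH_CB_RADIUS <- 3.83      # A, CB radial distance from the axis
SYNTH_N_RES <- 25L           # default residues per helix (about 3.5 heptads)
SYNTH_AXIS_DIST <- 8.6       # A, default inter-axis distance for edges
SYNTH_NONEDGE_DIST <- 25     # A, minimum non-edge spacing for free layouts

#' Generate one ideal alpha-helix
#'
#' Poly-alanine backbone on an ideal alpha-helical curve: CA atoms at radius
#' 2.3 Angstrom, rise 1.5 Angstrom and 100 degrees of twist per residue; N
#' and C placed on the same curve slightly behind/ahead of each CA so the
#' backbone is complete; CB placed radially 1.53 Angstrom beyond the CA.
#' The side-chain centroid of each residue is therefore its CB.
#'
#' @param n_residues number of residues (>= 1).
#' @param origin 3-vector: position of the first CA's axis point.
#' @param direction unit 3-vector: axis direction (N- to C-terminus).
#' @param phase rotation (degrees) of the first CA about the axis; 0 points
#'   along the reference perpendicular.
#' @param chain chain identifier for the emitted residues.
#' @param jitter_sd optional isotropic Gaussian coordinate noise (Angstrom);
#'   0 (default) is exactly deterministic.
#' @param seed RNG seed used only when `jitter_sd > 0`.
#' @return atom data frame in `cc_structure` layout.
#' @export
make_ideal_helix <- function(n_residues, origin = c(0, 0, 0),
                             direction = c(0, 0, 1), phase = 0,
                             chain = "A", jitter_sd = 0, seed = 1L) {
  stopifnot(n_residues >= 1L)
  direction <- direction / sqrt(sum(direction^2))
  fr <- axis_frame(direction)
  curve <- function(t, radius) {
    th <- (phase + SYNTH_TWIST * t) * pi / 180
    sweep(outer(radius * cos(th), fr$e1) + outer(radius * sin(th), fr$e2) +
            outer(SYNTH_RISE * t, direction), 2L, origin, `+`)
  }
  k <- seq_len(n_residues) - 1L
  ca <- curve(k, SYNTH_CA_RADIUS)
  nn <- curve(k - 0.35, 1.8)
  cc <- curve(k + 0.35, 2.0)
  oo <- curve(k + 0.50, 2.6)
  cb <- curve(k, SYNTH_CB_RADIUS)
  per <- c("N", "CA", "C", "O", "CB")
  coords <- do.call(rbind, lapply(seq_len(n_residues), function(i)
    rbind(nn[i, ], ca[i, ], cc[i, ], oo[i, ], cb[i, ])))
  if (jitter_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                              ncol = 3L)
  }
  data.frame(
    elety = rep(per, n_residues),
    resid = "ALA",
    chain = chain,
    resno = rep(seq_len(n_residues), each = length(per)),
    insert = "",
    x = round(coords[, 1L], 3L), y = round(coords[, 2L], 3L),
    z = round(coords[, 3L], 3L),
    o = 1, elesy = rep(c("N", "C", "C", "O", "C"), n_residues),
    stringsAsFactors = FALSE)
}

axis_frame <- function(e3) {
  ref <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(e3, e1)
  list(e1 = e1, e2 = e2)
}

## 2-D layouts for the named fixture topologies; `d` is the edge spacing
bundle_layout <- function(topology, d, nonedge_dist, seed = 1L) {
  polygon <- function(k) {
    R <- d / (2 * sin(pi / k))
    t(vapply(0:(k - 1L), function(i)
      R * c(cos(2 * pi * i / k), sin(2 * pi * i / k)), numeric(2L)))
  }
  line <- function(k) cbind((0:(k - 1L)) * d, 0)
  cyc_edges <- function(k) cbind(1:k, c(2:k, 1L))
  path_edges <- function(k) cbind(1:(k - 1L), 2:k)
  tri <- polygon(3L)
  r_tri <- sqrt(sum(tri[1L, ]^2))
  known <- list(
    edge = list(pos = rbind(c(0, 0), c(d, 0)), edges = rbind(c(1L, 2L))),
    path3 = list(pos = line(3L), edges = path_edges(3L)),
    path4 = list(pos = line(4L), edges = path_edges(4L)),
    triangle = list(pos = tri, edges = cyc_edges(3L)),
    C4 = list(pos = polygon(4L), edges = cyc_edges(4L)),
    C5 = list(pos = polygon(5L), edges = cyc_edges(5L)),
    C6 = list(pos = polygon(6L), edges = cyc_edges(6L)),
    C7 = list(pos = polygon(7L), edges = cyc_edges(7L)),
    C8 = list(pos = polygon(8L), edges = cyc_edges(8L)),
    star3 = list(
      pos = rbind(c(0, 0), d * c(1, 0),
                  d * c(cos(2 * pi / 3), sin(2 * pi / 3)),
                  d * c(cos(4 * pi / 3), sin(4 * pi / 3))),
      edges = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))),
    # triangle with one pendant helix on each vertex, radially outward (G94)
    net = list(
      pos = rbind(tri, tri * (1 + d / r_tri)),
      edges = rbind(cyc_edges(3L), c(1L, 4L), c(2L, 5L), c(3L, 6L))),
    # triangle core with each outer helix mirrored across one core edge so
    # it packs against two core helices (the viral six-helix bundle, G163)
    g163 = list(
      pos = rbind(tri, -2 * tri),
      edges = rbind(cyc_edges(3L),
                    c(4L, 2L), c(4L, 3L), c(5L, 1L), c(5L, 3L),
                    c(6L, 1L), c(6L, 2L)))
  )
  if (is.character(topology) && length(topology) == 1L) {
    if (!topology %in% names(known))
      stop("unknown topology '", topology, "'; available: ",
           paste(names(known), collapse = ", "))
    lay <- known[[topology]]
    lay$graph <- simple_graph(nrow(lay$pos), lay$edges)
    return(lay)
  }
  # arbitrary simple_graph: disjoint unions of the above are not supported;
  # place nodes by scaled spring layout and verify the distance contract
  g <- topology
  stopifnot(inherits(g, "simple_graph"))
  ig <- as_igraph(g)
  set.seed(seed)
  xy <- igraph::layout_with_fr(ig, niter = 500,
                               start.temp = sqrt(g$n),
                               weights = rep(1, nrow(g$edges)))
  # rescale so the shortest edge equals d
  ed <- sqrt(rowSums((xy[g$edges[, 1L], , drop = FALSE] -
                        xy[g$edges[, 2L], , drop = FALSE])^2))
  xy <- xy * (d / min(ed))
  list(pos = xy, edges = g$edges, graph = g)
}

#' Generate an ideal helix bundle with a prescribed topology
#'
#' Places one ideal helix (its own chain) per node of the requested
#' interaction topology: nodes joined by an edge sit at the calibrated
#' inter-axis spacing, non-edge nodes are kept apart, each helix is phased
#' so its side chains face the centroid of its layout neighbours, and
#' orientations alternate up/down around the layout (mimicking antiparallel
#' coiled coils; the detector is distance-only, so orientation does not
#' change the detected topology). At the default detector parameters
#' (scut 7.0, kcut 2) the detected simplified graph is isomorphic to the
#' requested topology for every named fixture.
#'
#' Named topologies: `edge`, `path3`, `path4`, `triangle`, `C4`..`C8`,
#' `star3`, `net` (triangle plus three pendant helices, G94), `g163` (the
#' viral six-helix bundle: trimer core with three bridging outer helices).
#'
#' @param topology a name from the list above, or a [simple_graph()].
#' @param n_residues residues per helix (default 25).
#' @param inter_axis_distance spacing for interacting pairs in Angstrom
#'   (default 8.6, calibrated to the detector).
#' @param nonedge_distance target spacing between non-interacting helices
#'   (default 25 Angstrom). Connected layouts cannot always achieve it
#'   (e.g. a cycle's diagonals are fixed by the polygon), so the enforced
#'   floor is the smaller of this value and 1.4x the edge spacing — enough
#'   to keep every non-edge pair below the kcut threshold at the default
#'   detector parameters.
#' @param orientations `"alternate"` (default), `"up"`, or an explicit
#'   vector of `"up"`/`"down"` per helix.
#' @param jitter_sd,seed forwarded to [make_ideal_helix()].
#' @param id structure identifier.
#' @return list with `structure` (a `cc_structure`), `topology` (the
#'   intended [simple_graph()]), and `layout` (node positions).
#' @examples
#' b <- make_bundle("C6")
#' classify_structure(b$structure)$components$name  # "G105"
#' @export
make_bundle <- function(topology, n_residues = SYNTH_N_RES,
                        inter_axis_distance = SYNTH_AXIS_DIST,
                        nonedge_distance = SYNTH_NONEDGE_DIST,
                        orientations = "alternate",
                        jitter_sd = 0, seed = 1L, id = NULL) {
  lay <- bundle_layout(topology, inter_axis_distance, nonedge_distance,
                       seed = seed)
  k <- nrow(lay$pos)
  g <- lay$graph
  # distance contract: no non-edge pair may come nearer than 1.4x the edge
  # spacing (the detector is silent well beyond that at its default scut);
  # connected layouts cannot honour `nonedge_distance` for second
  # neighbours (a 2-path caps the gap at twice the edge spacing), so the
  # larger floor is demanded only where the layout can deliver it
  floor_dist <- min(nonedge_distance, 1.4 * inter_axis_distance)
  prs <- pair_table(k)
  for (q in seq_len(nrow(prs))) {
    i <- prs[q, 1L]; j <- prs[q, 2L]
    dd <- sqrt(sum((lay$pos[i, ] - lay$pos[j, ])^2))
    is_edge <- any(g$edges[, 1L] == i & g$edges[, 2L] == j)
    if (!is_edge && dd < floor_dist)
      stop("layout violates the non-edge distance contract for helix pair ",
           i, "-", j, " (", round(dd, 2), " A)")
  }
  ori <- if (identical(orientations, "alternate")) {
    rep(c("up", "down"), length.out = k)
  } else if (identical(orientations, "up")) {
    rep("up", k)
  } else {
    stopifnot(length(orientations) == k, all(orientations %in% c("up", "down")))
    orientations
  }
  adj <- adjacency_list(g)
  span <- SYNTH_RISE * (n_residues - 1L)
  atoms <- list()
  for (i in seq_len(k)) {
    nb <- adj[[i]]
    target <- if (length(nb)) colMeans(lay$pos[nb, , drop = FALSE]) else c(0, 0)
    up <- ori[i] == "up"
    origin <- c(lay$pos[i, ], if (up) 0 else span)
    dir <- if (up) c(0, 0, 1) else c(0, 0, -1)
    # phase measured in the axis frame so side chains face the neighbours
    fr <- axis_frame(dir)
    v <- c(target - lay$pos[i, ], 0)
    ph <- atan2(sum(v * fr$e2), sum(v * fr$e1)) * 180 / pi
    atoms[[i]] <- make_ideal_helix(n_residues, origin = origin,
                                   direction = dir, phase = ph,
                                   chain = LETTERS[(i - 1L) %% 26L + 1L],
                                   jitter_sd = jitter_sd, seed = seed + i)
  }
  at <- do.call(rbind, atoms)
  if (k > 26L) stop("layouts beyond 26 helices are not supported (chain ids)")
  sid <- if (is.null(id)) {
    if (is.character(topology)) paste0("synthetic_", topology) else "synthetic_bundle"
  } else id
  list(
    structure = structure(list(id = sid, source_format = "pdb", atoms = at),
                          class = "cc_structure"),
    topology = g,
    layout = lay$pos)
}
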