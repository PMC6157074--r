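# Shared fixtures: tiny hand-written structure files, fake helix/KIH
# containers with prescribed centroids, and independent oracles (exhaustive
# permutation isomorphism, double-loop KIH search, BFS connectivity).

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = "", elesy = NULL, record = "ATOM") {
  if (is.null(elesy)) elesy <- substr(trimws(name), 1L, 1L)
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resid, chain, resno, "", x, y, z,
          occ, 0, elesy)
}

write_ala_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 1.4, 0.0, elesy = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.0, 0.0, 0.0, elesy = "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 1.4, -0.6, 0.0, elesy = "C"),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 2.3, 0.1, 0.0, elesy = "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, -1.0, -0.8, 1.0, elesy = "C"),
    "END")
  writeLines(lines, path)
  path
}

write_ala_cif <- function(path) {
  lines <- c(
    "data_ALA1", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 1.400 0.000 1.00 0.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 1.400 -0.600 0.000 1.00 0.00 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 2.300 0.100 0.000 1.00 0.00 1 ALA A O 1",
    "ATOM 5 C CB . ALA A 1 1 ? -1.000 -0.800 1.000 1.00 0.00 1 ALA A CB 1",
    "#")
  writeLines(lines, path)
  path
}

# fake cc_helices with prescribed side-chain centroids (one row per residue)
fake_helices <- function(centroid_sets, directions = NULL) {
  k <- length(centroid_sets)
  if (is.null(directions)) directions <- replicate(k, c(0, 0, 1), simplify = FALSE)
  res <- lapply(seq_len(k), function(i) {
    m <- centroid_sets[[i]]
    data.frame(chain = LETTERS[i], resno = seq_len(nrow(m)), insert = "",
               resid = "ALA", cax = m[, 1], cay = m[, 2], caz = m[, 3],
               cx = m[, 1], cy = m[, 2], cz = m[, 3],
               n_atoms_used = 1L, stringsAsFactors = FALSE)
  })
  df <- data.frame(
    helix_id = seq_len(k) - 1L, chain = LETTERS[seq_len(k)],
    n_res = vapply(res, nrow, integer(1)),
    first = "1", last = vapply(res, function(r) as.character(nrow(r)), character(1)),
    ax = 0, ay = 0, az = 0,
    dx = vapply(directions, `[`, numeric(1), 1L),
    dy = vapply(directions, `[`, numeric(1), 2L),
    dz = vapply(directions, `[`, numeric(1), 3L),
    stringsAsFactors = FALSE)
  structure(df, residues = res, structure_id = "fake",
            class = c("cc_helices", "data.frame"))
}

# fake kih_set with explicit directed interaction records
fake_kih_set <- function(knob_helix, hole_helix, max_distance,
                         collection_cutoff = 10, n_helices = NULL) {
  if (is.null(n_helices)) n_helices <- max(knob_helix, hole_helix) + 1L
  h <- fake_helices(replicate(n_helices, matrix(0, 1, 3), simplify = FALSE))
  n <- length(knob_helix)
  it <- data.frame(
    knob_helix = as.integer(knob_helix), hole_helix = as.integer(hole_helix),
    knob_chain = "A", knob_resno = seq_len(n), knob_insert = "",
    knob_resid = "ALA", hole_chain = "B", hole_resnos = "1,2,3,4",
    d1 = max_distance - 0.3, d2 = max_distance - 0.2,
    d3 = max_distance - 0.1, d4 = max_distance,
    max_distance = max_distance, stringsAsFactors = FALSE)
  structure(list(structure_id = "fake", collection_cutoff = collection_cutoff,
                 interactions = it, helices = h), class = "kih_set")
}

# --- independent oracles ---------------------------------------------------

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

adj_matrix <- function(g) {
  A <- matrix(FALSE, g$n, g$n)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}

# exhaustive-permutation isomorphism oracle (n <= 7)
brute_isomorphic <- function(g1, g2) {
  if (g1$n != g2$n || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (g1$n <= 1L) return(TRUE)
  A1 <- adj_matrix(g1); A2 <- adj_matrix(g2)
  for (p in all_permutations(g1$n)) {
    if (identical(A2, A1[p, p, drop = FALSE])) return(TRUE)
  }
  FALSE
}

random_graph <- function(n, p) {
  prs <- t(combn(n, 2))
  keep <- stats::runif(nrow(prs)) < p
  simple_graph(n, prs[keep, , drop = FALSE])
}

relabel_graph <- function(g) {
  p <- sample(g$n)
  e <- g$edges
  simple_graph(g$n, cbind(p[e[, 1]], p[e[, 2]]))
}

# plain double-loop KIH search over centroid clouds: for each ordered helix
# pair and knob, sort all distances and apply the strict 4-nearest rule
brute_kih <- function(clouds, cutoff) {
  out <- list()
  k <- length(clouds)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b || nrow(clouds[[b]]) < 4L) next
    for (r in seq_len(nrow(clouds[[a]]))) {
      d <- numeric(nrow(clouds[[b]]))
      for (s in seq_len(nrow(clouds[[b]])))
        d[s] <- sqrt(sum((clouds[[a]][r, ] - clouds[[b]][s, ])^2))
      ord <- order(d)[1:4]
      if (max(d[ord]) < cutoff)
        out[[length(out) + 1L]] <- c(a - 1L, b - 1L, r, sort(d[ord]))
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 7))
  do.call(rbind, out)
}

bfs_connected <- function(g) {
  if (g$n == 0L) return(FALSE)
  A <- adj_matrix(g)
  seen <- logical(g$n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] & !seen)
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  all(seen)
}

cycle_graph <- function(n) simple_graph(n, cbind(1:n, c(2:n, 1L)))
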