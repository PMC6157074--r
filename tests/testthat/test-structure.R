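test_that("a minimal one-residue PDB file parses to one chain, one residue, five atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ala_pdb(f)
  s <- parse_structure(f)
  expect_s3_class(s, "cc_structure")
  expect_equal(s$source_format, "pdb")
  expect_equal(length(unique(s$atoms$chain)), 1L)
  expect_equal(nrow(residue_table(s)), 1L)
  expect_equal(nrow(s$atoms), 5L)
  expect_setequal(s$atoms$elety, c("N", "CA", "C", "O", "CB"))
})

test_that("the same residue parses identically from the mmCIF dialect", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_ala_pdb(fp); write_ala_cif(fc)
  sp <- parse_structure(fp)
  sc <- parse_structure(fc)
  expect_equal(sc$source_format, "mmcif")
  cols <- c("elety", "resid", "chain", "resno", "insert", "x", "y", "z")
  expect_equal(sc$atoms[, cols], sp$atoms[, cols], ignore_attr = TRUE)
})

test_that("a file containing only waters raises an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, elesy = "O", record = "HETATM"),
    pdb_atom_line(2, "O", "HOH", "A", 2, 3, 0, 0, elesy = "O", record = "HETATM"),
    "END"), f)
  expect_error(parse_structure(f), "no polymer residues")
})

test_that("altloc conformers resolve to highest occupancy, ties alphabetically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  "SER", "A", 1, 0, 1.4, 0, elesy = "N"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 0, 0, 0, elesy = "C"),
    pdb_atom_line(3, "C",  "SER", "A", 1, 1.4, -0.6, 0, elesy = "C"),
    pdb_atom_line(4, "OG", "SER", "A", 1, 5, 0, 0, occ = 0.4, alt = "A", elesy = "O"),
    pdb_atom_line(5, "OG", "SER", "A", 1, 6, 0, 0, occ = 0.6, alt = "B", elesy = "O"),
    pdb_atom_line(6, "CB", "SER", "A", 1, 7, 0, 0, occ = 0.5, alt = "B", elesy = "C"),
    pdb_atom_line(7, "CB", "SER", "A", 1, 8, 0, 0, occ = 0.5, alt = "A", elesy = "C"),
    "END"), f)
  s <- parse_structure(f)
  og <- s$atoms[s$atoms$elety == "OG", ]
  expect_equal(nrow(og), 1L)
  expect_equal(og$x, 6)       # higher occupancy wins
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(cb$x, 8)       # occupancy tie: altloc "A" wins
})

test_that("MSE is kept as methionine with its selenium", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  "MSE", "A", 1, 0, 1.4, 0, elesy = "N", record = "HETATM"),
    pdb_atom_line(2, "CA", "MSE", "A", 1, 0, 0, 0, elesy = "C", record = "HETATM"),
    pdb_atom_line(3, "C",  "MSE", "A", 1, 1.4, -0.6, 0, elesy = "C", record = "HETATM"),
    pdb_atom_line(4, "CB", "MSE", "A", 1, 2, 0, 0, elesy = "C", record = "HETATM"),
    pdb_atom_line(5, "SE", "MSE", "A", 1, 4, 0, 0, elesy = "SE", record = "HETATM"),
    "END"), f)
  s <- parse_structure(f)
  expect_equal(unique(s$atoms$resid), "MET")
  cen <- side_chain_centroids(s)
  expect_equal(cen$n_atoms_used, 2L)           # CB + SE
  expect_equal(cen$x, 3)                       # mean of 2 and 4
})

test_that("side-chain centroids follow the CB-and-beyond rule with CA fallback", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ala_pdb(f)
  s <- parse_structure(f)
  cen <- side_chain_centroid(s, "A", 1)
  expect_equal(cen$position, c(-1.0, -0.8, 1.0))  # alanine: centroid is CB
  expect_equal(cen$n_atoms_used, 1L)

  # two side-chain atoms at (0,0,0) and (2,0,0) average to the midpoint
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  "CYS", "A", 1, 0, 1.4, 0, elesy = "N"),
    pdb_atom_line(2, "CA", "CYS", "A", 1, 5, 5, 5, elesy = "C"),
    pdb_atom_line(3, "C",  "CYS", "A", 1, 1.4, -0.6, 0, elesy = "C"),
    pdb_atom_line(4, "CB", "CYS", "A", 1, 0, 0, 0, elesy = "C"),
    pdb_atom_line(5, "SG", "CYS", "A", 1, 2, 0, 0, elesy = "S"),
    "END"), f2)
  cen2 <- side_chain_centroid(parse_structure(f2), "A", 1)
  expect_equal(cen2$position, c(1, 0, 0))
  expect_equal(cen2$n_atoms_used, 2L)

  # glycine: no side chain, centroid falls back to CA
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0, 1.4, 0, elesy = "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1, 2, 3, elesy = "C"),
    pdb_atom_line(3, "C",  "GLY", "A", 1, 1.4, -0.6, 0, elesy = "C"),
    "END"), f3)
  cen3 <- side_chain_centroid(parse_structure(f3), "A", 1)
  expect_equal(cen3$position, c(1, 2, 3))
})

test_that("write -> parse round trip preserves inventories and coordinates to 1e-3 A", {
  b <- make_bundle("triangle")
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(b$structure, f, format = fmt)
    s2 <- parse_structure(f)
    expect_equal(nrow(s2$atoms), nrow(b$structure$atoms))
    expect_equal(residue_table(s2), residue_table(b$structure),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(b$structure$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("centroids are equivariant under rigid motions", {
  b <- make_bundle("edge")
  s <- b$structure
  cen <- side_chain_centroids(s)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 11)
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1] + tr[1]
  s2$atoms$y <- xyz[, 2] + tr[2]
  s2$atoms$z <- xyz[, 3] + tr[3]
  cen2 <- side_chain_centroids(s2)
  expected <- as.matrix(cen[, c("x", "y", "z")]) %*% t(R)
  expected <- sweep(expected, 2, tr, `+`)
  expect_equal(as.matrix(cen2[, c("x", "y", "z")]), expected,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gzip-compressed input is accepted", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ala_pdb(f)
  fgz <- withr::local_tempfile(fileext = ".pdb.gz")
  con <- gzfile(fgz, "w")
  writeLines(readLines(f), con)
  close(con)
  s <- parse_structure(fgz)
  expect_equal(nrow(s$atoms), 5L)
})

test_that("empty structures are refused on write", {
  s <- structure(list(id = "empty", source_format = "pdb",
                      atoms = make_ideal_helix(1)[0, ]),
                 class = "cc_structure")
  expect_error(write_structure(s, tempfile(fileext = ".pdb")), "empty")
})
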