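#' Parse a protein structure from PDB or mmCIF
#'
#' Reads the first coordinate model of a PDB or mmCIF file (optionally
#' gzip-compressed) into a uniform atom table. Waters and hetero molecules
#' are dropped, with two exceptions: selenomethionine (MSE) is kept and
#' treated as methionine, and any other HETATM-coded polymer residue is kept
#' if it carries a CA atom. Alternate locations are resolved per atom name
#' to the highest-occupancy conformer (ties broken alphabetically by altloc
#' identifier). Author residue numbering and insertion codes are preserved
#' as identity and never used arithmetically.
#'
#' @param source path to a `.pdb`, `.cif`, or gzipped variant.
#' @param format `"auto"` (from the file extension), `"pdb"`, or `"mmcif"`.
#' @param id structure identifier; defaults to the file base name.
#' @return a `cc_structure`: list with `id`, `source_format`, and `atoms`
#'   (data frame with columns `elety`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o`, `elesy`).
#' @examples
#' b <- make_bundle("edge")
#' f <- tempfile(fileext = ".pdb")
#' write_structure(b$structure, f)
#' s <- parse_structure(f)
#' nrow(residue_table(s))
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif"),
                            id = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("cannot read structure file: ", source)
  path <- source
  gz <- grepl("\\.gz$", source)
  base <- sub("\\.gz$", "", source)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", base, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (gz) {
    path <- tempfile(fileext = paste0(".", if (format == "mmcif") "cif" else "pdb"))
    on.exit(unlink(path), add = TRUE)
    writeLines(readLines(gzfile(source)), path)
  }
  raw <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("failed to parse ", source, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(raw$xyz) && is.matrix(unclass(raw$xyz)) && nrow(raw$xyz) > 1L)
    warning("multi-model file; using model 1 only")
  at <- raw$atom
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  if (is.null(at$alt)) at$alt <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (is.null(at$elesy) || all(is.na(at$elesy)) || all(at$elesy == "")) {
    at$elesy <- suppressWarnings(bio3d::atom2ele(at$elety))
  }
  at$elesy[is.na(at$elesy)] <- ""
  at$chain[is.na(at$chain)] <- " "

  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # polymer = ATOM records, plus HETATM residues that carry a CA atom
  reskey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  het_keys <- unique(reskey[at$type == "HETATM"])
  ca_keys <- unique(reskey[at$elety == "CA" & at$elesy != "CA"])  # exclude calcium ions
  drop_het <- setdiff(het_keys, intersect(het_keys, ca_keys))
  at <- at[!(reskey %in% drop_het) | at$type == "ATOM", , drop = FALSE]
  at$resid[at$resid == "MSE"] <- "MET"
  if (nrow(at) == 0L) stop("no polymer residues in ", source)

  # altloc resolution: highest occupancy per atom name, ties alphabetical
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), , drop = FALSE]
  # restore file order
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  atoms <- data.frame(
    elety = at$elety, resid = at$resid, chain = at$chain,
    resno = as.integer(at$resno), insert = at$insert,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = as.numeric(at$o), elesy = at$elesy,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", source)
  structure(list(
    id = if (is.null(id)) sub("\\.(pdb|cif|mmcif)(\\.gz)?$", "",
                              basename(source), ignore.case = TRUE) else id,
    source_format = format,
    atoms = atoms
  ), class = "cc_structure")
}

#' @export
print.cc_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("cc_structure", x$id, "(", x$source_format, "):",
      length(unique(x$atoms$chain)), "chain(s),",
      nrow(rt), "residues,", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Residue inventory of a structure
#'
#' @param structure a [parse_structure()] result.
#' @return data frame with one row per residue (`chain`, `resno`, `insert`,
#'   `resid`) in file order.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Side-chain centroids of all residues
#'
#' For each residue the centroid is the unweighted mean position of its
#' side-chain heavy atoms (CB and beyond; hydrogens and deuteriums are never
#' included). Glycine, and any residue whose side chain is absent from the
#' model, falls back to the CA position. Residues with neither side-chain
#' heavy atoms nor a CA are dropped with a warning.
#'
#' @param structure a [parse_structure()] result.
#' @return data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `x`, `y`, `z`, `n_atoms_used`.
#' @export
side_chain_centroids <- function(structure) {
  a <- structure$atoms
  heavy <- !(a$elesy %in% c("H", "D"))
  side <- heavy & !(a$elety %in% BACKBONE_ATOMS)
  is_ca <- a$elety == "CA"
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  rt <- residue_table(structure)
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  n <- nrow(rt)
  out <- cbind(rt, x = NA_real_, y = NA_real_, z = NA_real_,
               n_atoms_used = NA_integer_)
  grp <- match(key, rkey)
  for (i in seq_len(n)) {
    rows <- which(grp == i & side)
    if (!length(rows)) rows <- which(grp == i & is_ca)
    if (!length(rows)) next
    out$x[i] <- mean(a$x[rows]); out$y[i] <- mean(a$y[rows])
    out$z[i] <- mean(a$z[rows]); out$n_atoms_used[i] <- length(rows)
  }
  bad <- is.na(out$n_atoms_used)
  if (any(bad)) {
    warning(sum(bad), " residue(s) lack both side-chain heavy atoms and CA; dropped")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Side-chain centroid of one residue
#'
#' @param structure a [parse_structure()] result.
#' @param chain,resno,insert residue identity.
#' @return list with `position` (3-vector) and `n_atoms_used`.
#' @export
side_chain_centroid <- function(structure, chain, resno, insert = "") {
  cen <- side_chain_centroids(structure)
  hit <- which(cen$chain == chain & cen$resno == resno & cen$insert == insert)
  if (!length(hit)) stop("residue not found or lacks usable atoms: ",
                         chain, " ", resno, insert)
  list(position = c(cen$x[hit], cen$y[hit], cen$z[hit]),
       n_atoms_used = cen$n_atoms_used[hit])
}

#' Write a structure to PDB or mmCIF
#'
#' The output round-trips through [parse_structure()] with coordinates
#' preserved to 0.001 Angstrom (the precision of both formats).
#'
#' @param structure a `cc_structure`.
#' @param path output file.
#' @param format `"pdb"` or `"mmcif"` (default from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     elety = a$elety, o = a$o, b = rep(0, nrow(a)),
                     elesy = a$elesy)
  } else {
    write_mmcif(structure, path)
  }
  invisible(path)
}

## Minimal mmCIF atom_site writer: one data block, the column subset that
## structure parsers require.
write_mmcif <- function(structure, path) {
  a <- structure$atoms
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  ins <- ifelse(structure$atoms$insert == "", "?", structure$atoms$insert)
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
                  seq_len(nrow(a)), ifelse(a$elesy == "", "C", a$elesy),
                  a$elety, a$resid, a$chain, a$resno, ins,
                  a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(lines, rows, "#"), path)
  invisible(path)
}
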