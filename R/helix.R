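#' Assign maximal alpha-helical segments
#'
#' Residues are flagged helical from CA geometry alone: residue `i` starts a
#' helical window when the CA(i)-CA(i+4) distance lies in 5.0..6.5 Angstrom
#' and the virtual dihedral over CA(i..i+3) lies in 35..75 degrees (both
#' characteristic of the alpha-helix and violated by strands and loops). A
#' maximal run of flagged window starts `a..b` yields the helical segment
#' `a..b+4`; segments of at least `min_helix_length` residues become
#' helices, numbered from 0 in chain order then residue order. Chain
#' continuity is decided by consecutive CA-CA distance (<= 4.5 Angstrom),
#' never by residue-number arithmetic.
#'
#' Alternatively a per-residue secondary-structure override (`"H"` =
#' helical) may be supplied, e.g. from an external DSSP run, bypassing the
#' geometric criterion.
#'
#' @param structure a [parse_structure()] result.
#' @param min_helix_length minimum helix length in residues (default 7).
#' @param ss optional override: character vector of `"H"`/other, one per
#'   residue of [residue_table()], or a two-column file
#'   (`chain:resno[insert]`, `H` or `-`) as path.
#' @return a `cc_helices` object: data frame with one row per helix
#'   (`helix_id`, `chain`, `n_res`, first/last residue labels, fitted axis
#'   point and direction), carrying per-helix residue coordinate tables and
#'   side-chain centroids as attributes.
#' @examples
#' b <- make_bundle("edge")
#' assign_helices(b$structure)
#' @export
assign_helices <- function(structure, min_helix_length = 7L, ss = NULL) {
  rt <- residue_table(structure)
  a <- structure$atoms
  akey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  ca_row <- match(rkey, akey[a$elety == "CA"])
  ca_idx <- which(a$elety == "CA")[ca_row]
  ca <- cbind(a$x[ca_idx], a$y[ca_idx], a$z[ca_idx])

  if (!is.null(ss)) {
    ssvec <- read_ss_override(ss, rt)
  } else {
    ssvec <- NULL
  }

  cen <- side_chain_centroids(structure)
  ckey <- paste(cen$chain, cen$resno, cen$insert, sep = "\r")

  segments <- list()
  for (ch in unique(rt$chain)) {
    ix <- which(rt$chain == ch)
    n <- length(ix)
    if (n < min_helix_length) next
    has_ca <- !is.na(ca_idx[ix])
    contig <- rep(FALSE, n)   # contig[k]: residues k and k+1 are consecutive
    if (n > 1L) {
      for (k in seq_len(n - 1L)) {
        if (has_ca[k] && has_ca[k + 1L]) {
          d <- sqrt(sum((ca[ix[k], ] - ca[ix[k + 1L], ])^2))
          contig[k] <- d <= 4.5
        }
      }
    }
    if (!is.null(ssvec)) {
      helical <- ssvec[ix] == "H" & has_ca
      runs <- flag_runs(helical, contig, extend = 0L)
    } else {
      flags <- rep(FALSE, n)
      for (k in seq_len(max(0L, n - 4L))) {
        if (!all(has_ca[k:(k + 4L)]) || !all(contig[k:(k + 3L)])) next
        d14 <- sqrt(sum((ca[ix[k], ] - ca[ix[k + 4L], ])^2))
        if (d14 < 5.0 || d14 > 6.5) next
        dh <- virtual_dihedral(ca[ix[k], ], ca[ix[k + 1L], ],
                               ca[ix[k + 2L], ], ca[ix[k + 3L], ])
        if (is.na(dh) || dh < 35 || dh > 75) next
        flags[k] <- TRUE
      }
      runs <- flag_runs(flags, contig, extend = 4L)
    }
    for (r in runs) {
      if (length(r) >= min_helix_length)
        segments[[length(segments) + 1L]] <- ix[r]
    }
  }

  res_tables <- list()
  hel <- data.frame(helix_id = integer(0), chain = character(0),
                    n_res = integer(0), first = character(0), last = character(0),
                    ax = numeric(0), ay = numeric(0), az = numeric(0),
                    dx = numeric(0), dy = numeric(0), dz = numeric(0),
                    stringsAsFactors = FALSE)
  for (s in seq_along(segments)) {
    ix <- segments[[s]]
    rsub <- rt[ix, , drop = FALSE]
    cm <- match(paste(rsub$chain, rsub$resno, rsub$insert, sep = "\r"), ckey)
    tab <- data.frame(
      chain = rsub$chain, resno = rsub$resno, insert = rsub$insert,
      resid = rsub$resid,
      cax = ca[ix, 1L], cay = ca[ix, 2L], caz = ca[ix, 3L],
      cx = cen$x[cm], cy = cen$y[cm], cz = cen$z[cm],
      n_atoms_used = cen$n_atoms_used[cm],
      stringsAsFactors = FALSE)
    axis <- fit_axis_ca(as.matrix(tab[, c("cax", "cay", "caz")]))
    hel[s, c("helix_id", "n_res")] <- c(s - 1L, nrow(tab))
    hel$chain[s] <- tab$chain[1L]
    hel$first[s] <- paste0(tab$resno[1L], tab$insert[1L])
    hel$last[s] <- paste0(tab$resno[nrow(tab)], tab$insert[nrow(tab)])
    hel[s, c("ax", "ay", "az")] <- axis$point
    hel[s, c("dx", "dy", "dz")] <- axis$direction
    res_tables[[s]] <- tab
  }
  structure(hel, residues = res_tables, structure_id = structure$id,
            class = c("cc_helices", "data.frame"))
}

#' @export
print.cc_helices <- function(x, ...) {
  cat("cc_helices:", nrow(x), "helix(es) in", attr(x, "structure_id"), "\n")
  if (nrow(x))
    print(data.frame(x[, c("helix_id", "chain", "n_res", "first", "last")]),
          row.names = FALSE)
  invisible(x)
}

read_ss_override <- function(ss, rt) {
  if (length(ss) == 1L && file.exists(ss)) {
    tab <- utils::read.table(ss, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("res", "ss"))
    key <- paste0(rt$chain, ":", rt$resno, rt$insert)
    out <- rep("-", nrow(rt))
    m <- match(key, tab$res)
    out[!is.na(m)] <- tab$ss[m[!is.na(m)]]
    out
  } else {
    if (length(ss) != nrow(rt))
      stop("ss override must have one entry per residue (", nrow(rt), ")")
    as.character(ss)
  }
}

## maximal runs of TRUE flags, each extended by `extend` residues past the
## last window start, clipped at chain breaks
flag_runs <- function(flags, contig, extend) {
  runs <- list()
  n <- length(flags)
  k <- 1L
  while (k <= n) {
    if (!flags[k]) { k <- k + 1L; next }
    j <- k
    while (j < n && flags[j + 1L] && contig[j]) j <- j + 1L
    end <- j
    for (e in seq_len(extend)) {
      if (end < n && contig[end]) end <- end + 1L else break
    }
    runs[[length(runs) + 1L]] <- k:end
    k <- end + 1L
  }
  runs
}

virtual_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  # sign convention: a right-handed (alpha) helix CA trace gives +50 degrees
  atan2(y, x) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## least-squares axis through the sliding 4-CA window midpoints
fit_axis_ca <- function(ca) {
  n <- nrow(ca)
  if (n < 4L) stop("degenerate helix: axis fit needs at least 4 residues")
  window_mids <- function(p) {
    t(vapply(seq_len(nrow(p) - 3L),
             function(i) colMeans(p[i:(i + 3L), , drop = FALSE]), numeric(3L)))
  }
  pts <- window_mids(ca)
  # a second smoothing pass shrinks the residual off-axis radius of the
  # midpoint trace by another order of magnitude (needs enough points)
  if (nrow(pts) >= 6L) pts <- window_mids(pts)
  if (nrow(pts) < 2L) pts <- ca
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  dir <- sv$v[, 1L]
  if (sum(dir * (ca[n, ] - ca[1L, ])) < 0) dir <- -dir
  list(point = ctr, direction = dir / sqrt(sum(dir^2)))
}

#' Fit the axis of one helix
#'
#' Least-squares line through the sliding-window (i..i+3) CA midpoints; the
#' direction points from the N- to the C-terminus.
#'
#' @param helices a [assign_helices()] result.
#' @param helix_id which helix (0-based id).
#' @return list with `point` (a point on the axis) and `direction` (unit
#'   3-vector).
#' @export
fit_axis <- function(helices, helix_id) {
  row <- which(helices$helix_id == helix_id)
  if (!length(row)) stop("no helix with id ", helix_id)
  tab <- attr(helices, "residues")[[row]]
  fit_axis_ca(as.matrix(tab[, c("cax", "cay", "caz")]))
}

#' Relative orientation of two helices
#'
#' Parallel when the dot product of the axis directions is non-negative
#' (perpendicular axes count as parallel by this boundary convention),
#' antiparallel otherwise.
#'
#' @param helices a [assign_helices()] result.
#' @param id1,id2 helix ids (0-based).
#' @return `"parallel"` or `"antiparallel"`.
#' @export
pair_orientation <- function(helices, id1, id2) {
  r1 <- which(helices$helix_id == id1); r2 <- which(helices$helix_id == id2)
  if (!length(r1) || !length(r2)) stop("unknown helix id")
  d <- sum(unlist(helices[r1, c("dx", "dy", "dz")]) *
           unlist(helices[r2, c("dx", "dy", "dz")]))
  if (d >= 0) "parallel" else "antiparallel"
}
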