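#' Detect knobs-into-holes interactions between helices
#'
#' For every ordered helix pair (A, B) and every residue r on A, the four
#' side-chain centroids on B nearest to the centroid of r are found. When
#' all four distances are strictly less than `collection_cutoff`, a KIH
#' interaction is recorded with r as the knob and the four residues on B as
#' the hole. Distances are stored ascending (d1..d4); ties at the fourth
#' position keep the residue earlier in sequence order. The deliberately
#' generous default of 10 Angstrom collects every interaction once, so that
#' any stricter scut can be applied afterwards with [filter_kih()] without
#' re-scanning coordinates.
#'
#' @param helices a [assign_helices()] result.
#' @param collection_cutoff collection distance in Angstrom (default 10.0).
#' @return a `kih_set`: list with `structure_id`, `collection_cutoff`,
#'   `interactions` (data frame, one row per KIH), and the `helices` object.
#' @examples
#' b <- make_bundle("edge")
#' h <- assign_helices(b$structure)
#' find_kih(h)
#' @export
find_kih <- function(helices, collection_cutoff = 10.0) {
  stopifnot(collection_cutoff > 0)
  res <- attr(helices, "residues")
  nh <- nrow(helices)
  rows <- list()
  for (ia in seq_len(nh)) for (ib in seq_len(nh)) {
    if (ia == ib) next
    A <- res[[ia]]; B <- res[[ib]]
    okA <- !is.na(A$cx); okB <- !is.na(B$cx)
    if (sum(okB) < 4L || !any(okA)) next
    CA <- as.matrix(A[okA, c("cx", "cy", "cz")])
    CB <- as.matrix(B[okB, c("cx", "cy", "cz")])
    ixA <- which(okA); ixB <- which(okB)
    for (k in seq_len(nrow(CA))) {
      d <- sqrt((CB[, 1L] - CA[k, 1L])^2 + (CB[, 2L] - CA[k, 2L])^2 +
                (CB[, 3L] - CA[k, 3L])^2)
      ord <- order(d)[1:4]          # stable: ties keep earlier residue
      d4 <- d[ord]
      if (d4[4L] >= collection_cutoff) next
      ha <- ixA[k]; hb <- ixB[ord]
      rows[[length(rows) + 1L]] <- data.frame(
        knob_helix = helices$helix_id[ia], hole_helix = helices$helix_id[ib],
        knob_chain = A$chain[ha], knob_resno = A$resno[ha],
        knob_insert = A$insert[ha], knob_resid = A$resid[ha],
        hole_chain = B$chain[hb[1L]],
        hole_resnos = paste0(B$resno[hb], B$insert[hb], collapse = ","),
        d1 = d4[1L], d2 = d4[2L], d3 = d4[3L], d4 = d4[4L],
        max_distance = d4[4L],
        stringsAsFactors = FALSE)
    }
  }
  interactions <- if (length(rows)) do.call(rbind, rows) else empty_kih_df()
  structure(list(structure_id = attr(helices, "structure_id"),
                 collection_cutoff = collection_cutoff,
                 interactions = interactions,
                 helices = helices),
            class = "kih_set")
}

empty_kih_df <- function() {
  data.frame(knob_helix = integer(0), hole_helix = integer(0),
             knob_chain = character(0), knob_resno = integer(0),
             knob_insert = character(0), knob_resid = character(0),
             hole_chain = character(0), hole_resnos = character(0),
             d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
             d4 = numeric(0), max_distance = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.kih_set <- function(x, ...) {
  cat("kih_set:", nrow(x$interactions), "KIH interaction(s) in",
      x$structure_id, "at collection cutoff", x$collection_cutoff, "A\n")
  invisible(x)
}

#' Filter a KIH set at a stricter cutoff
#'
#' Retains exactly the interactions whose largest knob-hole distance is
#' strictly below `scut`. The input is unmodified; filtering is idempotent
#' and nests (`filter_kih(filter_kih(s, 8), 7)` equals `filter_kih(s, 7)`).
#'
#' @param kih_set a [find_kih()] result.
#' @param scut SOCKET cutoff in Angstrom; must not exceed the set's
#'   collection cutoff (a larger value would silently under-report).
#' @return a `kih_set` with the surviving interactions.
#' @export
filter_kih <- function(kih_set, scut) {
  if (scut > kih_set$collection_cutoff)
    stop("scut (", scut, ") exceeds the collection cutoff (",
         kih_set$collection_cutoff, "); re-run find_kih with a larger cutoff")
  out <- kih_set
  out$interactions <- kih_set$interactions[
    kih_set$interactions$max_distance < scut, , drop = FALSE]
  out$scut <- scut
  out
}

#' Export a KIH set as JSON
#'
#' One record per interaction: knob residue identity, the four hole
#' residues, the four distances and the helix pair.
#'
#' @param kih_set a [find_kih()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
kih_to_json <- function(kih_set, path) {
  jsonlite::write_json(list(
    structure_id = kih_set$structure_id,
    collection_cutoff = kih_set$collection_cutoff,
    interactions = kih_set$interactions
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Human-readable KIH report
#'
#' SOCKET-style text listing of every knob, its hole residues and the four
#' centroid distances.
#'
#' @param kih_set a [find_kih()] result.
#' @return character vector of report lines.
#' @export
kih_report <- function(kih_set) {
  it <- kih_set$interactions
  hdr <- c(sprintf("KIH report for %s (collection cutoff %.1f A)",
                   kih_set$structure_id, kih_set$collection_cutoff),
           sprintf("%d interactions", nrow(it)))
  if (!nrow(it)) return(hdr)
  body <- sprintf(
    "knob %s%d%s %s (helix %d) -> hole [%s] on %s (helix %d)  d = %.2f %.2f %.2f %.2f",
    it$knob_chain, it$knob_resno, it$knob_insert, it$knob_resid,
    it$knob_helix, it$hole_resnos, it$hole_chain, it$hole_helix,
    it$d1, it$d2, it$d3, it$d4)
  c(hdr, body)
}
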