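#' Graph isomorphism test
#'
#' Decides whether two simple graphs are related by a node bijection that
#' maps edges exactly onto edges. The test first screens cheap invariants
#' (node count, edge count, sorted degree sequence), then refines node
#' labels by iterated neighbourhood-degree hashing (1-dimensional
#' Weisfeiler-Leman colouring) and runs a backtracking search seeded by the
#' resulting label partition. For graphs on at most seven nodes the verdict
#' agrees with exhaustive permutation search; the backtracking also handles
#' the much larger cycle graphs that arise from many-helix barrels.
#'
#' @param g1,g2 [simple_graph()] objects.
#' @return `TRUE` or `FALSE`.
#' @examples
#' c6 <- simple_graph(6, cbind(1:6, c(2:6, 1)))
#' two_triangles <- simple_graph(6, rbind(c(1,2), c(2,3), c(1,3),
#'                                        c(4,5), c(5,6), c(4,6)))
#' is_isomorphic(c6, two_triangles)  # same degree sequence, not isomorphic
#' @export
is_isomorphic <- function(g1, g2) {
  if (g1$n != g2$n) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  n <- g1$n
  if (n <= 1L) return(TRUE)
  d1 <- degrees_of(g1); d2 <- degrees_of(g2)
  if (!identical(sort(d1), sort(d2))) return(FALSE)

  lab <- wl_labels(g1, g2)
  if (is.null(lab)) return(FALSE)
  l1 <- lab$l1; l2 <- lab$l2

  a1 <- adjacency_list(g1)
  a2 <- adjacency_list(g2)
  adj2 <- matrix(FALSE, n, n)
  if (nrow(g2$edges)) {
    adj2[g2$edges] <- TRUE
    adj2[g2$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }

  # order g1's nodes rarest label class first, then by descending degree,
  # preferring nodes adjacent to already-placed ones (connectivity heuristic)
  class_size <- table(l1)
  ord <- order(class_size[as.character(l1)], -d1)
  placed <- logical(n)
  seq_nodes <- integer(0)
  remaining <- ord
  while (length(remaining)) {
    nb_placed <- vapply(remaining, function(v) any(placed[a1[[v]]]), logical(1))
    pick <- if (any(nb_placed)) remaining[which(nb_placed)[1L]] else remaining[1L]
    seq_nodes <- c(seq_nodes, pick)
    placed[pick] <- TRUE
    remaining <- setdiff(remaining, pick)
  }

  mapping <- integer(n)   # g1 node -> g2 node, 0 = unassigned
  used <- logical(n)

  backtrack <- function(k) {
    if (k > n) return(TRUE)
    v <- seq_nodes[k]
    cands <- which(!used & l2 == l1[v])
    for (w in cands) {
      ok <- TRUE
      for (u in a1[[v]]) {
        mu <- mapping[u]
        if (mu != 0L && !adj2[w, mu]) { ok <- FALSE; break }
      }
      if (ok) {
        # every mapped non-neighbour must stay a non-neighbour
        mapped <- which(mapping != 0L)
        nonnb <- setdiff(mapped, a1[[v]])
        if (length(nonnb) && any(adj2[w, mapping[nonnb]])) ok <- FALSE
      }
      if (ok) {
        mapping[v] <<- w; used[w] <<- TRUE
        if (backtrack(k + 1L)) return(TRUE)
        mapping[v] <<- 0L; used[w] <<- FALSE
      }
    }
    FALSE
  }
  backtrack(1L)
}

## Iterated neighbourhood refinement. Returns stable integer labels for both
## graphs on a shared label alphabet, or NULL when the label multisets
## already certify non-isomorphism.
wl_labels <- function(g1, g2) {
  n <- g1$n
  a1 <- adjacency_list(g1); a2 <- adjacency_list(g2)
  l1 <- degrees_of(g1); l2 <- degrees_of(g2)
  for (it in seq_len(max(1L, n))) {
    s1 <- vapply(seq_len(n), function(v)
      paste(l1[v], paste(sort(l1[a1[[v]]]), collapse = ","), sep = "|"), character(1))
    s2 <- vapply(seq_len(n), function(v)
      paste(l2[v], paste(sort(l2[a2[[v]]]), collapse = ","), sep = "|"), character(1))
    alphabet <- sort(unique(c(s1, s2)))
    new1 <- match(s1, alphabet); new2 <- match(s2, alphabet)
    if (!identical(sort(new1), sort(new2))) return(NULL)
    converged <- length(unique(new1)) == length(unique(l1))
    l1 <- new1; l2 <- new2
    if (converged) break
  }
  list(l1 = l1, l2 = l2)
}
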