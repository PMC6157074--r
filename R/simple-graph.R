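#' Construct a simple graph
#'
#' Minimal undirected simple-graph value used throughout the atlas machinery:
#' `n` labelled nodes `1..n` and an edge matrix with no self-loops or
#' duplicate edges. This is deliberately lighter than an igraph object so
#' that canonical certificates and backtracking isomorphism can work on raw
#' integer data.
#'
#' @param n number of nodes (>= 0).
#' @param edges two-column integer matrix (or vector coercible to one) of
#'   node pairs; may be `NULL` for an edgeless graph.
#' @return an object of class `simple_graph`: list with elements `n` and
#'   `edges` (two-column matrix, each row sorted, rows ordered).
#' @examples
#' simple_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))  # triangle
#' @export
simple_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must be node labels in 1..n")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed in a simple graph")
    edges <- t(apply(edges, 1L, sort))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (anyDuplicated(edges))
      stop("duplicate edges are not allowed in a simple graph")
  }
  structure(list(n = n, edges = edges), class = "simple_graph")
}

#' @export
print.simple_graph <- function(x, ...) {
  cat("simple graph:", x$n, "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0L)
    cat(" ", paste(x$edges[, 1L], x$edges[, 2L], sep = "-", collapse = " "), "\n")
  invisible(x)
}

degrees_of <- function(g) {
  d <- integer(g$n)
  if (nrow(g$edges)) {
    t1 <- tabulate(g$edges[, 1L], g$n)
    t2 <- tabulate(g$edges[, 2L], g$n)
    d <- t1 + t2
  }
  d
}

adjacency_list <- function(g) {
  a <- vector("list", g$n)
  for (i in seq_len(g$n)) a[[i]] <- integer(0)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
    a[[i]] <- c(a[[i]], j)
    a[[j]] <- c(a[[j]], i)
  }
  a
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

## ---- node-pair indexing -------------------------------------------------
## Pairs (i, j), i < j, numbered row-major: (1,2), (1,3), ..., (1,n), (2,3), ...

pair_index <- function(i, j, n) {
  sw <- i > j
  if (any(sw)) { t <- i[sw]; i[sw] <- j[sw]; j[sw] <- t }
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

pair_table <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  prs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  prs <- prs[order(prs[, 1L], prs[, 2L]), , drop = FALSE]
  dimnames(prs) <- NULL
  prs
}

graph_to_pairvec <- function(g) {
  npair <- g$n * (g$n - 1L) / 2L
  v <- logical(npair)
  if (nrow(g$edges))
    v[pair_index(g$edges[, 1L], g$edges[, 2L], g$n)] <- TRUE
  v
}

pairvec_to_graph <- function(n, v) {
  prs <- pair_table(n)
  simple_graph(n, prs[which(v), , drop = FALSE])
}

## For each permutation p of 1..n, row r of the map sends pair slot k to the
## slot occupied by (p(i), p(j)). Cached per n; exhaustive, so only for n <= 7.
perm_pair_maps <- function(n) {
  key <- paste0("ppm", n)
  if (!is.null(.ccatlas_env[[key]])) return(.ccatlas_env[[key]])
  stopifnot(n >= 2L, n <= 7L)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))[, n:1, drop = FALSE]
  perms <- perms[apply(perms, 1L, function(r) !anyDuplicated(r)), , drop = FALSE]
  npair <- n * (n - 1L) / 2L
  prs <- pair_table(n)
  m <- matrix(0L, nrow(perms), npair)
  for (k in seq_len(npair)) {
    m[, k] <- as.integer(pair_index(perms[, prs[k, 1L]], perms[, prs[k, 2L]], n))
  }
  .ccatlas_env[[key]] <- m
  m
}

## Canonical certificate (n <= 7): the adjacency bit-string of the graph,
## read as an integer over pair slots, minimised over all node permutations.
## Also yields |Aut| as the number of permutations fixing the bit-string.
canonical_certificate <- function(g) {
  n <- g$n
  if (n < 2L) return(list(cert = 0, n_automorphisms = 1L))
  if (n > 7L) stop("exhaustive canonical certificates are computed for n <= 7 only")
  v <- graph_to_pairvec(g)
  pm <- perm_pair_maps(n)
  pow2 <- 2^(seq_along(v) - 1L)
  M <- matrix(v[t(pm)], nrow = nrow(pm), byrow = TRUE)
  codes <- as.vector(M %*% pow2)
  list(cert = min(codes), n_automorphisms = sum(codes == sum(v * pow2)))
}

## inverse of the certificate: rebuild the canonical-form graph
graph_from_certificate <- function(n, cert) {
  npair <- n * (n - 1L) / 2L
  if (npair == 0L) return(simple_graph(n))
  bits <- as.logical(bitwAnd(rep(cert, npair) %/% 2^(seq_len(npair) - 1L), 1))
  pairvec_to_graph(n, bits)
}

## connectivity by breadth-first search over the adjacency list
graph_is_connected <- function(g) {
  if (g$n == 0L) return(FALSE)
  if (g$n == 1L) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(g$n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Test whether a graph is a cycle
#'
#' A graph is a cycle when it is connected and every node has degree exactly
#' two; alpha-helical barrels appear as cycle graphs in the classification.
#'
#' @param g a [simple_graph()].
#' @return list with `cycle` (logical) and `length` (node count, or `NA`
#'   when not a cycle).
#' @examples
#' is_cycle(simple_graph(6, cbind(1:6, c(2:6, 1))))
#' @export
is_cycle <- function(g) {
  ok <- g$n >= 3L && all(degrees_of(g) == 2L) && graph_is_connected(g)
  list(cycle = ok, length = if (ok) g$n else NA_integer_)
}
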