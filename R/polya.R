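## Exact counting of graph isomorphism classes by Polya / Burnside theory.
##
## The number of non-isomorphic simple graphs on n nodes is the number of
## orbits of the symmetric group S_n acting on 2-colourings of the C(n,2)
## node pairs:
##
##   count(n) = (1/n!) * sum over cycle types lambda of n
##                [ #permutations of type lambda ] * 2^c(lambda)
##
## where c(lambda) is the number of cycles of the induced action on
## unordered pairs: sum_i floor(a_i/2) + sum_{i<j} gcd(a_i, a_j) for parts
## a_i of lambda. The counts overflow double precision from n = 14, so all
## arithmetic runs on a small exact big-integer representation (little-
## endian base-10000 digit vectors).

## ---- big integers -------------------------------------------------------

BIG_BASE <- 10000

big_from_int <- function(x) {
  stopifnot(x >= 0, x < 2^53, x == floor(x))
  d <- numeric(0)
  if (x == 0) return(structure(list(d = 0), class = "ccatlas_bigint"))
  while (x > 0) { d <- c(d, x %% BIG_BASE); x <- x %/% BIG_BASE }
  structure(list(d = d), class = "ccatlas_bigint")
}

big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= BIG_BASE) {
      q <- d[i] %/% BIG_BASE
      d[i] <- d[i] %% BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + q
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_add <- function(a, b) {
  la <- length(a$d); lb <- length(b$d); l <- max(la, lb)
  d <- c(a$d, numeric(l - la)) + c(b$d, numeric(l - lb))
  structure(list(d = big_carry(d)), class = "ccatlas_bigint")
}

## multiply by a plain integer < ~2^40 (digit * m must stay exact in double)
big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m * BIG_BASE < 2^53)
  if (m == 0) return(big_from_int(0))
  d <- a$d * m
  # carries can exceed one digit; normalise iteratively
  repeat {
    if (all(d < BIG_BASE)) break
    d <- big_carry(d)
  }
  structure(list(d = d), class = "ccatlas_bigint")
}

## exact division by a plain integer; errors if a remainder is left
big_div_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m * BIG_BASE < 2^53)
  d <- rev(a$d)   # most-significant first
  out <- numeric(length(d))
  r <- 0
  for (i in seq_along(d)) {
    cur <- r * BIG_BASE + d[i]
    out[i] <- cur %/% m
    r <- cur %% m
  }
  if (r != 0) stop("big_div_small: division is not exact")
  d <- rev(out)
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(list(d = d), class = "ccatlas_bigint")
}

big_pow2 <- function(k) {
  out <- big_from_int(1)
  while (k >= 13L) { out <- big_mul_small(out, 8192); k <- k - 13L }
  if (k > 0L) out <- big_mul_small(out, 2^k)
  out
}

#' @export
as.character.ccatlas_bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1L], paste(sprintf("%04d", d[-1L]), collapse = ""))
}

#' @export
as.double.ccatlas_bigint <- function(x, ...) {
  sum(x$d * BIG_BASE^(seq_along(x$d) - 1L))
}

#' @export
print.ccatlas_bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
format.ccatlas_bigint <- function(x, ...) as.character(x)

## ---- integer partitions -------------------------------------------------

## all partitions of n as descending integer vectors
partitions_of <- function(n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(remaining, maxpart, acc) {
    if (remaining == 0L) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (p in seq(min(maxpart, remaining), 1L)) {
      recurse(remaining - p, p, c(acc, p))
    }
  }
  recurse(as.integer(n), as.integer(n), integer(0))
  out
}

## factor multiset of z_lambda = prod_j j^{m_j} * m_j!  (all factors <= n)
zlambda_factors <- function(parts) {
  tab <- table(parts)
  f <- integer(0)
  for (j in as.integer(names(tab))) {
    m <- tab[[as.character(j)]]
    f <- c(f, rep(j, m), seq_len(m)[-1L])
  }
  f[f > 1L]
}

## cycles of the induced action on unordered node pairs
pair_cycles <- function(parts) {
  c1 <- sum(parts %/% 2L)
  c2 <- 0L
  if (length(parts) >= 2L) {
    for (i in seq_len(length(parts) - 1L))
      for (j in seq(i + 1L, length(parts)))
        c2 <- c2 + gcd2(parts[i], parts[j])
  }
  c1 + c2
}

gcd2 <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

#' Count non-isomorphic simple graphs on n nodes
#'
#' Exact count of isomorphism classes of simple graphs, computed from the
#' cycle index of the symmetric group acting on unordered node pairs. All
#' arithmetic is exact (arbitrary-precision integers), so the result is
#' correct far beyond the range of double precision; the count already
#' exceeds Avogadro's number several hundredfold at 17 nodes.
#'
#' @param n number of nodes (non-negative integer; the partition sum grows
#'   quickly, but n up to a few dozen runs in seconds).
#' @return an exact big integer (class `ccatlas_bigint`); use
#'   `as.character()` for all digits or `as.numeric()` for a double
#'   approximation.
#' @examples
#' count_graphs(4)                 # 11
#' as.character(count_graphs(17))  # 27-digit exact count
#' @export
count_graphs <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  if (n <= 1L) return(big_from_int(1))
  nfact_factors <- seq(2L, n)
  nfact <- Reduce(big_mul_small, nfact_factors, big_from_int(1))
  total <- big_from_int(0)
  for (parts in partitions_of(n)) {
    term <- nfact
    for (f in zlambda_factors(parts)) term <- big_div_small(term, f)
    # term is now n!/z_lambda = number of permutations with this cycle type;
    # each partial divisor divides z_lambda, which divides n!, so every
    # intermediate quotient is an exact integer
    k <- pair_cycles(parts)
    while (k >= 13L) { term <- big_mul_small(term, 8192); k <- k - 13L }
    if (k > 0L) term <- big_mul_small(term, 2^k)
    total <- big_add(total, term)
  }
  for (f in nfact_factors) total <- big_div_small(total, f)
  total
}
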