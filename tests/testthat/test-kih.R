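test_that("a knob records its four nearest hole centroids with ascending distances", {
  knob <- matrix(c(0, 0, 0), 1, 3)
  hole <- rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5), c(6, 0, 0), c(12, 0, 0))
  h <- fake_helices(list(knob, hole))
  ks <- find_kih(h, collection_cutoff = 10)
  # knob from helix 0 into helix 1 (helix 0 has < 4 residues, so no reverse)
  expect_equal(nrow(ks$interactions), 1L)
  it <- ks$interactions
  expect_equal(it$knob_helix, 0L)
  expect_equal(it$hole_helix, 1L)
  expect_equal(c(it$d1, it$d2, it$d3, it$d4), c(3, 4, 5, 6))
  expect_equal(it$max_distance, 6)
})

test_that("a hole helix with only three residues yields no interactions", {
  knob <- matrix(c(0, 0, 0), 1, 3)
  hole <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ks <- find_kih(fake_helices(list(knob, hole)), collection_cutoff = 10)
  expect_equal(nrow(ks$interactions), 0L)
})

test_that("collection threshold and filter_kih apply strict inequality", {
  knob <- matrix(c(0, 0, 0), 1, 3)
  hole <- rbind(c(7.2, 0, 0), c(0, 8.1, 0), c(0, 0, 9.0), c(9.9, 0, 0))
  ks <- find_kih(fake_helices(list(knob, hole)), collection_cutoff = 10)
  expect_equal(nrow(ks$interactions), 1L)       # present at 10.0
  expect_equal(nrow(filter_kih(ks, 7.0)$interactions), 0L)  # absent at scut 7

  # at the boundary only strictly smaller max distances survive
  ks2 <- fake_kih_set(knob_helix = c(0, 0, 0), hole_helix = c(1, 1, 1),
                      max_distance = c(6.9, 7.0, 7.1))
  kept <- filter_kih(ks2, 7.0)$interactions
  expect_equal(kept$max_distance, 6.9)
})

test_that("filtering is the identity at the collection cutoff and nests", {
  ks <- fake_kih_set(knob_helix = rep(0, 5), hole_helix = rep(1, 5),
                     max_distance = c(5, 6.5, 7.5, 8.5, 9.5))
  expect_equal(filter_kih(ks, 10)$interactions, ks$interactions)
  nested <- filter_kih(filter_kih(ks, 8.0), 7.0)
  direct <- filter_kih(ks, 7.0)
  expect_equal(nested$interactions, direct$interactions)
  expect_error(filter_kih(ks, 12), "exceeds the collection cutoff")
})

test_that("detection matches an exhaustive double-loop search on random centroid clouds", {
  set.seed(42)
  for (rep_i in 1:5) {
    k <- sample(2:4, 1)
    clouds <- lapply(seq_len(k), function(i) {
      n <- sample(3:9, 1)
      matrix(stats::runif(3 * n, 0, 15), n, 3)
    })
    ks <- find_kih(fake_helices(clouds), collection_cutoff = 10)
    oracle <- brute_kih(clouds, 10)
    expect_equal(nrow(ks$interactions), nrow(oracle))
    if (nrow(oracle)) {
      got <- ks$interactions[order(ks$interactions$knob_helix,
                                   ks$interactions$hole_helix,
                                   ks$interactions$knob_resno), ]
      ora <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), , drop = FALSE]
      expect_equal(got$knob_helix, as.integer(ora[, 1]))
      expect_equal(got$hole_helix, as.integer(ora[, 2]))
      expect_equal(got$knob_resno, as.integer(ora[, 3]))
      expect_equal(as.matrix(got[, c("d1", "d2", "d3", "d4")]),
                   ora[, 4:7, drop = FALSE], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("scut monotonicity: tighter cutoffs keep a subset of interactions", {
  set.seed(7)
  clouds <- lapply(1:3, function(i) matrix(stats::runif(24, 0, 12), 8, 3))
  ks <- find_kih(fake_helices(clouds), collection_cutoff = 10)
  key <- function(it) paste(it$knob_helix, it$hole_helix, it$knob_resno)
  scuts <- c(6, 7, 8, 9, 10)
  for (i in seq_len(length(scuts) - 1)) {
    tight <- filter_kih(ks, scuts[i])$interactions
    loose <- filter_kih(ks, scuts[i + 1])$interactions
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("knobs are never recorded against the knob's own helix", {
  set.seed(11)
  clouds <- lapply(1:3, function(i) matrix(stats::runif(30, 0, 8), 10, 3))
  ks <- find_kih(fake_helices(clouds), collection_cutoff = 10)
  expect_true(all(ks$interactions$knob_helix != ks$interactions$hole_helix))
})

test_that("helices far beyond the collection cutoff yield an empty set", {
  a <- make_ideal_helix(15, origin = c(0, 0, 0), chain = "A")
  b <- make_ideal_helix(15, origin = c(40, 0, 0), chain = "B")
  s <- structure(list(id = "far", source_format = "pdb", atoms = rbind(a, b)),
                 class = "cc_structure")
  ks <- find_kih(assign_helices(s), collection_cutoff = 10)
  expect_equal(nrow(ks$interactions), 0L)
})

test_that("detection is invariant under rigid motion up to helix renumbering", {
  b <- make_bundle("edge")
  h1 <- assign_helices(b$structure)
  k1 <- find_kih(h1)
  s2 <- b$structure
  th <- 2.2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1] - 4; s2$atoms$y <- xyz[, 2] + 9; s2$atoms$z <- xyz[, 3] + 1
  k2 <- find_kih(assign_helices(s2))
  cols <- c("knob_helix", "hole_helix", "knob_resno", "hole_resnos")
  expect_equal(k2$interactions[, cols], k1$interactions[, cols],
               ignore_attr = TRUE)
  expect_equal(k2$interactions$max_distance, k1$interactions$max_distance,
               tolerance = 1e-9)
})

test_that("KIH sets serialize to JSON and a readable report", {
  b <- make_bundle("edge")
  ks <- find_kih(assign_helices(b$structure))
  f <- withr::local_tempfile(fileext = ".json")
  kih_to_json(ks, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$collection_cutoff, 10)
  expect_equal(nrow(back$interactions), nrow(ks$interactions))
  rep_ <- kih_report(ks)
  expect_true(any(grepl("knob", rep_)))
})
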