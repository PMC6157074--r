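# the shipped (packaged) atlas table; loaded once per session
atlas <- enumerate_atlas()

test_that("the atlas holds all 1253 simple graphs on 0..7 nodes", {
  expect_equal(nrow(atlas), 1253L)
  per_n <- as.integer(table(factor(atlas$n_nodes, levels = 0:7)))
  polya <- vapply(0:7, function(n) as.numeric(count_graphs(n)), numeric(1))
  expect_equal(per_n, as.integer(polya))
})

test_that("classical atlas positions are reproduced", {
  expect_equal(atlas_index(simple_graph(2, c(1, 2)), atlas), 3L)      # dimer edge
  expect_equal(atlas_index(simple_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3))),
                           atlas), 7L)                                # triangle
  expect_equal(atlas_index(cycle_graph(4), atlas), 16L)
  expect_equal(atlas_index(cycle_graph(5), atlas), 38L)
  expect_equal(atlas_index(cycle_graph(6), atlas), 105L)
  expect_equal(atlas_index(cycle_graph(7), atlas), 353L)
  k7 <- simple_graph(7, t(combn(7, 2)))
  expect_equal(atlas_index(k7, atlas), 1252L)
  expect_equal(atlas$n_edges[atlas$index == 1252L], 21L)
  # look-ups are invariant under relabelling
  set.seed(3)
  expect_equal(atlas_index(relabel_graph(cycle_graph(6)), atlas), 105L)
  # beyond seven nodes the atlas does not apply
  expect_true(is.na(atlas_index(cycle_graph(8), atlas)))
})

test_that("named positions agree with the published catalogue ordering", {
  for (idx in c(3L, 7L, 16L, 38L, 94L, 105L, 163L, 353L, 1252L)) {
    mine <- ccatlas:::as_igraph(atlas_graph(atlas, idx))
    published <- igraph::graph_from_atlas(idx)
    expect_true(igraph::isomorphic(mine, published),
                label = paste0("G", idx, " isomorphic to the published entry"))
  }
})

test_that("atlas entries are pairwise non-isomorphic and self-consistent", {
  # pairwise check within (n, m, degree-sequence) buckets
  bucket <- paste(atlas$n_nodes, atlas$n_edges, atlas$degree_seq)
  for (b in unique(bucket[duplicated(bucket)])) {
    members <- which(bucket == b)
    gs <- lapply(members, function(i) atlas_graph(atlas, atlas$index[i]))
    for (i in seq_along(gs)[-1]) for (j in seq_len(i - 1)) {
      expect_false(is_isomorphic(gs[[i]], gs[[j]]))
    }
  }
  # every entry looks itself up at its own index
  for (i in seq_len(nrow(atlas))) {
    g <- atlas_graph(atlas, atlas$index[i])
    expect_equal(atlas_index(g, atlas), atlas$index[i])
  }
})

test_that("automorphism counts match igraph on a sample", {
  set.seed(5)
  for (i in sample(nrow(atlas), 40)) {
    if (atlas$n_nodes[i] < 2) next
    g <- ccatlas:::as_igraph(atlas_graph(atlas, atlas$index[i]))
    expect_equal(atlas$n_automorphisms[i],
                 as.integer(igraph::count_automorphisms(g)$group_size))
  }
})

test_that("the connected max-degree-4 display subset has 461 members", {
  sub <- connected_bounded_degree_subset(atlas, max_degree = 4L)
  expect_equal(nrow(sub), 461L)
  # independent recheck: BFS connectivity and a direct degree scan
  for (i in seq_len(nrow(sub))) {
    g <- ccatlas:::graph_from_certificate(sub$n_nodes[i], sub$cert[i])
    expect_true(bfs_connected(g))
    expect_lte(max(ccatlas:::degrees_of(g)), 4L)
  }
  # the subset is exactly the complement-checked filter over the full table
  in_sub <- atlas$index %in% sub$index
  for (i in which(!in_sub)) {
    g <- ccatlas:::graph_from_certificate(atlas$n_nodes[i], atlas$cert[i])
    expect_true(atlas$n_nodes[i] < 2L || !bfs_connected(g) ||
                  max(ccatlas:::degrees_of(g)) > 4L)
  }
  # degenerate bound: no connected multi-node graph has max degree 0
  expect_equal(nrow(connected_bounded_degree_subset(atlas, 0L)), 0L)
})

test_that("Polya counts are exact and agree with direct enumeration", {
  expect_equal(as.numeric(count_graphs(0)), 1)
  expect_equal(as.numeric(count_graphs(1)), 1)
  expect_equal(as.numeric(count_graphs(2)), 2)
  expect_equal(as.numeric(count_graphs(7)), sum(atlas$n_nodes == 7))
  # seventeen nodes: the count exceeds Avogadro's number > 400-fold
  c17 <- count_graphs(17)
  expect_equal(nchar(as.character(c17)), 27L)
  expect_gt(as.numeric(c17) / 6.022e23, 400)
})

test_that("big-integer helpers are exact", {
  a <- ccatlas:::big_from_int(987654321)
  b <- ccatlas:::big_from_int(123456789)
  expect_equal(as.character(ccatlas:::big_add(a, b)), "1111111110")
  expect_equal(as.character(ccatlas:::big_mul_small(a, 1000000)),
               "987654321000000")
  expect_equal(as.character(ccatlas:::big_div_small(
    ccatlas:::big_mul_small(a, 7), 7)), "987654321")
  expect_equal(as.character(ccatlas:::big_pow2(136)),
               "87112285931760246646623899502532662132736")  # 2^136
  expect_error(ccatlas:::big_div_small(ccatlas:::big_from_int(10), 3),
               "not exact")
})

test_that("the U-registry names beyond-atlas graphs on first encounter", {
  reg <- u_registry()
  c8 <- cycle_graph(8)
  expect_equal(classify_component(c8, atlas, reg), "U1")
  expect_equal(length(reg), 1L)
  set.seed(8)
  expect_equal(classify_component(relabel_graph(c8), atlas, reg), "U1")
  expect_equal(length(reg), 1L)        # idempotent: no duplicate entry
  c9 <- cycle_graph(9)
  expect_equal(classify_component(c9, atlas, reg), "U2")
  expect_equal(length(reg), 2L)
  # repeated classification of isomorphs never grows the registry
  for (i in 1:5) classify_component(relabel_graph(c9), atlas, reg)
  expect_equal(length(reg), 2L)
})

test_that("the U-registry persists names across sessions via JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  reg <- u_registry(f)
  classify_component(cycle_graph(8), atlas, reg)
  classify_component(cycle_graph(10), atlas, reg)
  reg2 <- u_registry(f)
  expect_equal(length(reg2), 2L)
  expect_equal(classify_component(cycle_graph(10), atlas, reg2), "U2")
  expect_equal(length(reg2), 2L)
})

test_that("atlas names and small components classify correctly", {
  reg <- u_registry()
  expect_equal(classify_component(simple_graph(2, c(1, 2)), atlas, reg), "G3")
  expect_equal(classify_component(
    simple_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3))), atlas, reg), "G7")
  set.seed(21)
  g163 <- relabel_graph(atlas_graph(atlas, 163L))
  expect_equal(classify_component(g163, atlas, reg), "G163")
  expect_equal(length(reg), 0L)   # atlas hits never touch the registry
})
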