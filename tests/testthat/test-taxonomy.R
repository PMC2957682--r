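test_that("levels are edge counts from the root, computed by BFS", {
  tr <- taxonomy_tree(data.frame(
    tax_id = c(10L, 20L, 30L), parent_id = c(10L, 10L, 20L),
    rank = "no rank", name = c("root", "A", "B")))
  expect_equal(taxon_level(tr, c(10L, 20L, 30L)), c(0L, 1L, 2L))
  expect_equal(tr$root_id, 10L)

  tr50 <- make_random_taxonomy(50, seed = 11)
  g <- tree_graph(tr50)
  bfs_levels <- igraph::distances(g, v = as.character(tr50$root_id))
  expect_equal(taxon_level(tr50, tr50$nodes$tax_id),
               as.integer(bfs_levels[1, as.character(tr50$nodes$tax_id)]))
})

test_that("structural defects are rejected", {
  base <- data.frame(tax_id = c(1L, 2L), parent_id = c(1L, 1L),
                     rank = "no rank", name = c("root", "A"))
  expect_error(taxonomy_tree(rbind(base, data.frame(
    tax_id = 2L, parent_id = 1L, rank = "no rank", name = "dup"))),
    "duplicate")
  expect_error(taxonomy_tree(rbind(base, data.frame(
    tax_id = 3L, parent_id = 99L, rank = "no rank", name = "dangling"))),
    "dangling")
  expect_error(taxonomy_tree(rbind(base, data.frame(
    tax_id = c(3L, 4L), parent_id = c(4L, 3L), rank = "no rank",
    name = c("c1", "c2")))), "cycle")
  expect_error(taxonomy_tree(data.frame(
    tax_id = c(1L, 2L), parent_id = c(1L, 2L), rank = "no rank",
    name = c("r1", "r2"))), "root")
})

test_that("NCBI dump dialect and toy TSV dialect both load", {
  nodes <- tempfile(); names <- tempfile()
  writeLines(c("1\t|\t1\t|\tno rank\t|\t\t|",
               "2\t|\t131567\t|\tsuperkingdom\t|\t\t|",
               "131567\t|\t1\t|\tno rank\t|\t\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\tBacteria <bacteria>\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tgenbank common name\t|",
               "131567\t|\tcellular organisms\t|\t\t|\tscientific name\t|"),
             names)
  tr <- load_taxonomy(nodes, names)
  expect_equal(taxon_rank(tr, 2L), "superkingdom")
  expect_equal(taxon_name(tr, 2L), "Bacteria")
  expect_equal(taxon_level(tr, 2L), 2L)

  tsv <- tempfile(fileext = ".tsv")
  write_taxonomy_tsv(tr, tsv)
  tr2 <- load_taxonomy(tsv)
  expect_equal(tr2$nodes, tr$nodes)
})

test_that("lca matches the path-intersection oracle on random trees", {
  tr <- make_random_taxonomy(50, seed = 3)
  ids <- tr$nodes$tax_id
  for (a in sample(ids, 12)) {
    for (b in sample(ids, 12)) {
      expect_identical(lca(tr, a, b), oracle_lca(tr, a, b))
    }
  }
  x <- sample(ids, 1)
  expect_identical(lca(tr, x, x), x)
  expect_identical(lca(tr, tr$root_id, x), tr$root_id)
  expect_identical(lca(tr, x, tr$root_id), lca(tr, tr$root_id, x))
})

test_that("lca_set folds pairwise lca and is permutation-invariant", {
  tr <- make_random_taxonomy(60, seed = 5)
  expect_error(lca_set(tr, integer()), "non-empty")
  x <- sample(tr$nodes$tax_id, 1)
  expect_identical(lca_set(tr, x), x)
  for (k in 1:10) {
    taxa <- sample(tr$nodes$tax_id, sample(2:8, 1))
    ref <- Reduce(function(a, b) lca(tr, a, b), taxa)
    expect_identical(lca_set(tr, taxa), ref)
    expect_identical(lca_set(tr, sample(taxa)), ref)
  }
})

test_that("ancestor_at_rank projects lineages onto canonical ranks", {
  tr <- demo_taxonomy()
  # strain leaf up to its family
  expect_identical(ancestor_at_rank(tr, 11L, "family"), 7L)
  expect_equal(taxon_name(tr, ancestor_at_rank(tr, 11L, "family")),
               "Burkholderiaceae")
  # inclusive: a node projects onto its own rank
  expect_identical(ancestor_at_rank(tr, 8L, "genus"), 8L)
  # lineage lacking the rank
  expect_true(is.na(ancestor_at_rank(tr, 2L, "order")))
  expect_error(ancestor_at_rank(tr, 999L, "genus"), "unknown tax_id")
})

test_that("pairwise_distance equals BFS shortest paths and is a metric", {
  tr <- demo_taxonomy()
  expect_equal(pairwise_distance(tr, 8L, 8L), 0L)
  expect_equal(pairwise_distance(tr, 8L, 10L), 2L) # genus -> species via group
  expect_equal(pairwise_distance(tr, 10L, 8L), 2L)

  for (seed in 1:3) {
    trn <- make_random_taxonomy(80, seed = seed)
    dmat <- oracle_distances(trn)
    ids <- sample(trn$nodes$tax_id, 15)
    for (a in ids) for (b in ids) {
      expect_equal(pairwise_distance(trn, a, b),
                   as.integer(dmat[as.character(a), as.character(b)]))
    }
    # triangle property, equality when b lies on the a-c path
    trip <- replicate(20, sample(trn$nodes$tax_id, 3))
    for (k in seq_len(ncol(trip))) {
      a <- trip[1, k]; b <- trip[2, k]; c <- trip[3, k]
      expect_lte(pairwise_distance(trn, a, c),
                 pairwise_distance(trn, a, b) + pairwise_distance(trn, b, c))
    }
  }
})
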