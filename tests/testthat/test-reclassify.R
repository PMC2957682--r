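mk_assign <- function(tax_ids, tree,
                      read_id = sprintf("r%04d", seq_along(tax_ids))) {
  data.table::data.table(
    read_id = read_id, status = "Assigned", tax_id = as.integer(tax_ids),
    name = taxon_name(tree, tax_ids), rank = taxon_rank(tree, tax_ids),
    route = "MPA", tl = "species")
}

test_that("isolated-taxon size is min(cap, 1%) floored at one", {
  expect_equal(isolated_taxon_size(35000), 300L)
  expect_equal(isolated_taxon_size(10000), 100L)
  expect_equal(isolated_taxon_size(1), 1L)
  expect_equal(isolated_taxon_size(50000), 300L)
  expect_equal(isolated_taxon_size(250), 3L)  # ceiling(2.5)
})

test_that("bin table accumulates direct counts bottom-up", {
  tr <- demo_taxonomy()
  a <- mk_assign(rep(10L, 10), tr)
  bt <- build_bin_table(tr, a)
  expect_equal(bt[bt$tax_id == 10L, ]$direct, 10L)
  # whole root path carries the cumulative count
  for (t in path_to_root(tr, 10L)) {
    expect_equal(bt[bt$tax_id == t, ]$cumulative, 10L)
  }
  # two sibling genera: family cumulative is their sum
  b <- mk_assign(c(rep(18L, 4), rep(20L, 6)), tr)
  bt2 <- build_bin_table(tr, b)
  expect_equal(bt2[bt2$tax_id == 17L, ]$cumulative, 10L)
  expect_equal(bt2[bt2$tax_id == 17L, ]$direct, 0L)
  expect_equal(bt2[bt2$tax_id == tr$root_id, ]$cumulative, 10L)
  expect_error(build_bin_table(tr, mk_assign(999L, demo_taxonomy(),
                                             read_id = "x")),
               "unknown tax_id")
})

test_that("reads in isolated taxa move to the first populated ancestor", {
  spec <- scenario_spec(seed = 2, n_genera = 2, species_per_genus = 2)
  tr <- make_taxonomy(spec)
  species <- tr$nodes[tr$nodes$rank == "species", ]$tax_id
  genus <- ancestor_at_rank(tr, species[1], "genus")
  # 2 reads at one species, 320 at its sister: the small bin is isolated
  # and the genus subtree holds > 300 reads
  a <- mk_assign(c(rep(species[1], 2), rep(species[2], 320)), tr)
  out <- reclassify_assignments(tr, a, size = 300L)
  moved <- out[out$route == "reclassified", ]
  expect_equal(nrow(moved), 2L)
  expect_equal(unique(moved$tax_id), genus)
  expect_equal(unique(moved$old_tax_id), species[1])
  # the populated bin is untouched
  expect_equal(out[out$tax_id == species[2], ]$route, rep("MPA", 320))
})

test_that("a lone read with no populated ancestors becomes unassigned", {
  tr <- demo_taxonomy()
  a <- mk_assign(11L, tr, read_id = "solo")
  out <- reclassify_assignments(tr, a, size = 300L)
  expect_equal(out$status, "Unassigned")
  expect_equal(out$route, "reclassified")
  expect_equal(out$old_tax_id, 11L)
  expect_true(is.na(out$tax_id))
})

test_that("no isolated taxa means no change", {
  tr <- demo_taxonomy()
  a <- mk_assign(rep(10L, 50), tr)
  out <- reclassify_assignments(tr, a, size = 10L)
  expect_equal(out$tax_id, a$tax_id)
  expect_equal(out$route, a$route)
  # threshold 1: nothing can be below it
  out1 <- reclassify_assignments(tr, mk_assign(c(10L, 12L, 14L), tr),
                                 size = 1L)
  expect_equal(out1$route, rep("MPA", 3))
})

test_that("promotion is conservative, strictly upward, capped at superkingdom", {
  for (seed in 1:4) {
    spec <- scenario_spec(seed = seed, n_genera = 8, species_per_genus = 2,
                          reads_per_species = 12, noise_sd = 30)
    tr <- make_taxonomy(spec)
    tabs <- make_hit_tables(tr, spec)
    a <- assign_reads(tr, tabs$hits, all_read_ids = tabs$truth$read_id)
    out <- reclassify_assignments(tr, a, size = 25L)
    # conservation: same reads, none created or destroyed
    expect_equal(sort(out$read_id), sort(a$read_id))
    expect_equal(nrow(out), nrow(a))
    moved <- out[out$route == "reclassified" & out$status == "Assigned", ]
    for (r in seq_len(nrow(moved))) {
      anc <- path_to_root(tr, moved$old_tax_id[r])
      expect_true(moved$tax_id[r] %in% setdiff(anc, moved$old_tax_id[r]))
      # never above superkingdom
      expect_gte(taxon_level(tr, moved$tax_id[r]),
                 taxon_level(tr, ancestor_at_rank(tr, moved$old_tax_id[r],
                                                  "superkingdom")))
    }
  }
})

test_that("frozen-count passes are idempotent once stable", {
  tr <- demo_taxonomy()
  # 2 reads at a species, 40 directly at its species group: the promoted
  # reads land in a bin that is itself above the threshold
  a <- mk_assign(c(rep(12L, 2), rep(9L, 40)), tr)
  once <- reclassify_assignments(tr, a, size = 10L)
  expect_equal(once[once$route == "reclassified", ]$tax_id, c(9L, 9L))
  twice <- reclassify_assignments(tr, once, size = 10L)
  expect_equal(as.data.frame(twice[, c("read_id", "status", "tax_id")]),
               as.data.frame(once[, c("read_id", "status", "tax_id")]))
  # iterated mode reaches a fixed point within tree depth
  it <- reclassify_assignments(tr, a, size = 10L, iterate = TRUE)
  it2 <- reclassify_assignments(tr, it, size = 10L, iterate = TRUE)
  expect_equal(as.data.frame(it2[, c("read_id", "status", "tax_id")]),
               as.data.frame(it[, c("read_id", "status", "tax_id")]))
})
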