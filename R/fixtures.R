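# Deterministic generators of toy taxonomies and synthetic hit tables,
# including clade-deletion scenarios that emulate reads from organisms
# absent from the reference database at species, genus or family level.

#' Scenario specification for the synthetic generators
#'
#' Describes a fully reproducible binning scenario: a balanced toy
#' taxonomy, a set of simulated reads (one batch per species leaf), and a
#' synthetic hit table in which the expected bit score of a hit decays
#' linearly with the tree distance between the read's source species and
#' the reference species, with Gaussian noise. Hits whose score falls
#' below the assignment validity threshold are not emitted. Under an
#' unknown-organism mode, reference species inside the read's source
#' clade (its species, genus or family) are deleted, emulating queries
#' against a database from which that clade is absent.
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param n_genera Number of genera (grouped pairwise into families,
#'   orders, classes and phyla under one superkingdom).
#' @param species_per_genus Species leaves per genus.
#' @param reads_per_species Simulated reads per species leaf.
#' @param unknown_mode One of `"known"`, `"species-unknown"`,
#'   `"genus-unknown"`, `"family-unknown"`.
#' @param bitscore_mean Expected bit score of a hit at tree distance 0.
#' @param bitscore_decay Expected bit-score loss per tree edge.
#' @param noise_sd Standard deviation of the Gaussian score noise.
#' @param alignment_length Alignment length (columns) of every hit.
#' @param self_hits Number of hits emitted against the source species
#'   itself when it is present in the reference (a sequenced organism
#'   contributes several homologous subjects, so its own genome yields
#'   more than one strong hit).
#' @param min_bit_score Emission threshold below which hits are dropped.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, n_genera = 4L, species_per_genus = 3L,
                          reads_per_species = 50L,
                          unknown_mode = c("known", "species-unknown",
                                           "genus-unknown", "family-unknown"),
                          bitscore_mean = 300, bitscore_decay = 25,
                          noise_sd = 10, alignment_length = 90L,
                          self_hits = 2L, min_bit_score = 35) {
  unknown_mode <- match.arg(unknown_mode)
  stopifnot(n_genera >= 1, species_per_genus >= 1, reads_per_species >= 1,
            bitscore_mean > 0, bitscore_decay >= 0, noise_sd >= 0,
            self_hits >= 1)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 reads_per_species = as.integer(reads_per_species),
                 unknown_mode = unknown_mode,
                 bitscore_mean = bitscore_mean,
                 bitscore_decay = bitscore_decay, noise_sd = noise_sd,
                 alignment_length = as.integer(alignment_length),
                 self_hits = as.integer(self_hits),
                 min_bit_score = min_bit_score),
            class = "scenario_spec")
}

# evaluate code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Balanced toy taxonomy for a scenario
#'
#' Builds a tree with the seven canonical ranks: one superkingdom, genera
#' grouped pairwise into families, families into orders, orders into
#' classes, classes into phyla, and `species_per_genus` leaves per genus.
#' Every species leaf sits at level 7 (edges from the root). Generation
#' is deterministic (no randomness is involved).
#'
#' @param spec A [scenario_spec()].
#' @return A [taxonomy_tree()].
#' @export
make_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  G <- spec$n_genera
  Fm <- ceiling(G / 2); O <- ceiling(Fm / 2)
  C <- ceiling(O / 2); P <- ceiling(C / 2)
  rows <- list(data.table(tax_id = 1L, parent_id = 1L, rank = "no rank",
                          name = "root"),
               data.table(tax_id = 2L, parent_id = 1L,
                          rank = "superkingdom", name = "Superkingdom_1"))
  next_id <- 3L
  add_level <- function(count, rank, label, parent_ids) {
    ids <- next_id - 1L + seq_len(count)
    next_id <<- next_id + count
    rows[[length(rows) + 1L]] <<- data.table(
      tax_id = as.integer(ids), parent_id = as.integer(parent_ids),
      rank = rank, name = sprintf("%s_%d", label, seq_len(count)))
    ids
  }
  phyla   <- add_level(P, "phylum", "Phylum", rep(2L, P))
  classes <- add_level(C, "class", "Class", phyla[ceiling(seq_len(C) / 2)])
  orders  <- add_level(O, "order", "Order", classes[ceiling(seq_len(O) / 2)])
  fams    <- add_level(Fm, "family", "Family", orders[ceiling(seq_len(Fm) / 2)])
  genera  <- add_level(G, "genus", "Genus", fams[ceiling(seq_len(G) / 2)])
  add_level(G * spec$species_per_genus, "species", "Species",
            rep(genera, each = spec$species_per_genus))
  taxonomy_tree(rbindlist(rows))
}

#' Random taxonomy for oracle-based tests
#'
#' A random rooted tree: node `i` attaches to a uniformly chosen earlier
#' node, with arbitrary (mostly non-canonical) rank labels. Used to check
#' level/LCA/distance computations against graph-based oracles.
#'
#' @param n_nodes Number of nodes (including the root).
#' @param seed Integer seed.
#' @return A [taxonomy_tree()].
#' @export
make_random_taxonomy <- function(n_nodes, seed = 1L) {
  stopifnot(n_nodes >= 1)
  with_seed(seed, {
    parent <- c(1L, vapply(seq_len(n_nodes)[-1L], function(i) {
      sample.int(i - 1L, 1L)
    }, integer(1)))
    rank <- c("no rank", sample(c(canonical_ranks(), "no rank"),
                                n_nodes - 1L, replace = TRUE))
    taxonomy_tree(data.table(tax_id = seq_len(n_nodes),
                             parent_id = parent, rank = rank,
                             name = sprintf("node_%d", seq_len(n_nodes))))
  })
}

#' Synthetic hit and truth tables for a scenario
#'
#' For every read simulated from a species leaf, emits hits against the
#' reference species leaves that survive the scenario's clade deletion.
#' Each hit's bit score is `bitscore_mean - bitscore_decay * d + noise`,
#' where `d` is the tree distance between source and reference species;
#' scores below `min_bit_score` are not emitted. Identity and positives
#' counts are derived from the score so that better-scoring hits also
#' show better alignment fractions. Same spec (including seed) gives
#' byte-identical tables.
#'
#' @param tree The taxonomy from [make_taxonomy()].
#' @param spec A [scenario_spec()].
#' @return A list with `hits` (parsed-hit-table layout, see
#'   [read_blast_hits()]) and `truth` (`read_id`, `true_tax_id`).
#' @export
make_hit_tables <- function(tree, spec) {
  stopifnot(inherits(tree, "taxonomy_tree"), inherits(spec, "scenario_spec"))
  leaves <- tree$nodes[rank == "species", tax_id]
  del_rank <- switch(spec$unknown_mode, known = NA_character_,
                     `species-unknown` = "species",
                     `genus-unknown` = "genus",
                     `family-unknown` = "family")
  leaf_paths <- lapply(leaves, function(l) path_to_root(tree, l))
  names(leaf_paths) <- as.character(leaves)

  with_seed(spec$seed, {
    out <- vector("list", length(leaves))
    read_no <- 0L
    truth <- vector("list", length(leaves))
    for (s in seq_along(leaves)) {
      src <- leaves[s]
      refs <- leaves
      if (!is.na(del_rank)) {
        del_node <- ancestor_at_rank(tree, src, del_rank)
        refs <- refs[!vapply(as.character(refs), function(r) {
          del_node %in% leaf_paths[[r]]
        }, logical(1))]
      }
      d <- vapply(refs, function(r) pairwise_distance(tree, src, r),
                  integer(1))
      mu <- spec$bitscore_mean - spec$bitscore_decay * d
      copies <- ifelse(refs == src, spec$self_hits, 1L)
      ref_rep <- rep(refs, copies)
      mu_rep <- rep(mu, copies)
      copy_no <- sequence(copies)
      ids <- sprintf("R%06d", read_no + seq_len(spec$reads_per_species))
      read_no <- read_no + spec$reads_per_species
      truth[[s]] <- data.table(read_id = ids, true_tax_id = src)

      per_read <- lapply(seq_along(ids), function(r) {
        bit <- round(mu_rep + rnorm(length(mu_rep), 0, spec$noise_sd), 1)
        keep <- bit >= spec$min_bit_score
        if (!any(keep)) return(NULL)
        frac <- pmin(1, pmax(0.25, bit[keep] / spec$bitscore_mean))
        alen <- spec$alignment_length
        data.table(query_id = ids[r],
                   subject_id = sprintf("S%d_%d", ref_rep[keep],
                                        copy_no[keep]),
                   tax_id = ref_rep[keep],
                   bit_score = bit[keep],
                   alignment_length = alen,
                   identities = as.integer(round(frac * alen)),
                   positives = as.integer(round(pmin(1, frac + 0.05) * alen)),
                   gaps = 0L,
                   evalue = signif(10 ^ (-bit[keep] / 10), 3))
      })
      out[[s]] <- rbindlist(per_read)
    }
    hits <- rbindlist(out)
    hits <- if (nrow(hits)) order_hits(hits) else empty_hit_table()
    list(hits = hits, truth = rbindlist(truth))
  })
}

#' Generate a scenario and write its files
#'
#' Emits the four plain-text artifacts of a scenario into a directory:
#' the toy-taxonomy TSV, a 12-column BLAST tabular hit file, the
#' subject-to-taxid map, and the truth table.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the four file paths, invisibly.
#' @export
write_scenario <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- make_taxonomy(spec)
  tabs <- make_hit_tables(tree, spec)
  paths <- list(taxonomy = file.path(dir, "taxonomy.tsv"),
                hits = file.path(dir, "hits.tsv"),
                taxid_map = file.path(dir, "taxid_map.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_taxonomy_tsv(tree, paths$taxonomy)
  write_blast_hits(tabs$hits, paths$hits)
  write_taxid_map(tabs$hits, paths$taxid_map)
  fwrite(tabs$truth, paths$truth, sep = "\t")
  invisible(paths)
}

#' Worked-example taxonomy: a two-class proteobacterial lineage
#'
#' A small NCBI-like tree containing non-canonical nodes (a "cellular
#' organisms" node above the superkingdom, a species group, a strain-level
#' "no rank" leaf) and two classes of one phylum. Paired with
#' [example_read_hits()] it demonstrates how ratio scoring keeps a read at
#' the genus while a plain LCA over the same hits retreats to the phylum.
#'
#' @return A [taxonomy_tree()].
#' @export
example_taxonomy <- function() {
  taxonomy_tree(data.table(
    tax_id    = 1:21,
    parent_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 9L, 9L,
                  8L, 4L, 15L, 16L, 17L, 18L, 17L, 20L),
    rank = c("no rank", "no rank", "superkingdom", "phylum", "class",
             "order", "family", "genus", "species group", "species",
             "no rank", "species", "species", "species", "class", "order",
             "family", "genus", "species", "genus", "species"),
    name = c("root", "cellular organisms", "Bacteria", "Proteobacteria",
             "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae",
             "Burkholderia", "Burkholderia cepacia complex",
             "Burkholderia ambifaria", "Burkholderia ambifaria AMMD",
             "Burkholderia cenocepacia", "Burkholderia multivorans",
             "Burkholderia pseudomallei", "Gammaproteobacteria",
             "Enterobacterales", "Enterobacteriaceae", "Escherichia",
             "Escherichia coli", "Salmonella", "Salmonella enterica")))
}

#' Worked-example hit set for one read
#'
#' One read whose best hit is a strain of a well-represented genus, with
#' strong hits across that genus and weaker hits in a distant class of
#' the same phylum; see [example_taxonomy()].
#'
#' @return A hit table in the [read_blast_hits()] layout.
#' @export
example_read_hits <- function() {
  data.table(
    query_id = "read1",
    subject_id = sprintf("S%d", c(11L, 14L, 12L, 19L, 21L)),
    tax_id = c(11L, 14L, 12L, 19L, 21L),
    bit_score = c(95, 92, 90, 60, 55),
    alignment_length = 90L,
    identities = c(85L, 82L, 80L, 55L, 52L),
    positives = c(86L, 84L, 82L, 60L, 58L),
    gaps = 0L,
    evalue = 1e-20)
}
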