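# Taxonomy container and queries: parent navigation, levels, LCA, rank
# projection, and the edge-count path distance used for candidate scoring.

#' Canonical taxonomic ranks, shallow to deep
#'
#' The seven canonical ranks used for rank projection and for the taxonomic
#' level (TL) restriction, ordered from closest to the root (superkingdom)
#' to deepest (species). Taxonomies may contain additional non-canonical
#' ranks ("no rank", "species group", ...); those participate in levels and
#' distances but are skipped by rank projection.
#'
#' @return Character vector of rank labels.
#' @export
canonical_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Depth index of a canonical rank
#'
#' @param rank Character vector of rank labels.
#' @return Integer position within [canonical_ranks()] (superkingdom = 1,
#'   species = 7); `NA` for non-canonical labels.
#' @export
rank_depth <- function(rank) {
  match(rank, canonical_ranks())
}

#' Build a taxonomy tree from a node table
#'
#' Validates the parent-child structure and computes each node's level
#' (number of edges from the root) by breadth-first descent. The root is
#' the unique node with `tax_id == parent_id` and has level 0.
#'
#' @param nodes A data.frame with columns `tax_id`, `parent_id`, `rank`,
#'   `name`. Taxon ids are positive integers; exactly one row must be the
#'   root (`tax_id == parent_id`).
#' @return An object of class `taxonomy_tree`: a list with `nodes` (a
#'   `data.table` with an added `level` column), `root_id`, and internal
#'   index structures for fast navigation.
#' @examples
#' tr <- taxonomy_tree(data.frame(
#'   tax_id = c(1L, 2L, 3L), parent_id = c(1L, 1L, 2L),
#'   rank = c("no rank", "superkingdom", "phylum"),
#'   name = c("root", "Bacteria", "Proteobacteria")))
#' taxon_level(tr, 3L)
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as.data.table(nodes)
  required <- c("tax_id", "parent_id", "rank", "name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop("node table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- nodes[, .(tax_id = as.integer(tax_id),
                     parent_id = as.integer(parent_id),
                     rank = as.character(rank),
                     name = as.character(name))]
  if (anyNA(nodes$tax_id) || anyNA(nodes$parent_id)) {
    stop("tax_id/parent_id must be integers without NA")
  }
  if (anyDuplicated(nodes$tax_id)) {
    dup <- nodes$tax_id[duplicated(nodes$tax_id)]
    stop("duplicate tax_id: ", paste(unique(dup), collapse = ", "))
  }
  root_rows <- which(nodes$tax_id == nodes$parent_id)
  if (length(root_rows) != 1L) {
    stop("expected exactly one root row (tax_id == parent_id), found ",
         length(root_rows))
  }
  parent_idx <- match(nodes$parent_id, nodes$tax_id)
  if (anyNA(parent_idx)) {
    bad <- nodes$parent_id[is.na(parent_idx)]
    stop("dangling parent_id (no such node): ",
         paste(unique(bad), collapse = ", "))
  }

  n <- nrow(nodes)
  level <- rep.int(NA_integer_, n)
  root <- root_rows[1L]
  level[root] <- 0L
  frontier <- root
  depth <- 0L
  children <- split(seq_len(n)[-root], parent_idx[-root])
  while (length(frontier)) {
    depth <- depth + 1L
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (!is.null(frontier)) level[frontier] <- depth
  }
  if (anyNA(level)) {
    stop("cycle detected: ", sum(is.na(level)),
         " node(s) unreachable from the root")
  }
  nodes[, level := level]
  setkey(nodes, NULL)

  # root path (index space, root first) per node; taxonomy depth is small
  paths <- vector("list", n)
  ord <- order(level)
  for (i in ord) {
    paths[[i]] <- if (i == root) i else c(paths[[parent_idx[i]]], i)
  }

  structure(
    list(nodes = nodes, root_id = nodes$tax_id[root],
         parent_idx = parent_idx, paths = paths),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, depth %d, root '%s' (taxid %d)\n",
              nrow(x$nodes), max(x$nodes$level),
              x$nodes$name[x$nodes$tax_id == x$root_id], x$root_id))
  invisible(x)
}

# taxids -> row indices, erroring on unknown ids
tax_index <- function(tree, taxids, allow_na = FALSE) {
  idx <- match(as.integer(taxids), tree$nodes$tax_id)
  if (!allow_na && anyNA(idx)) {
    stop("unknown tax_id: ",
         paste(unique(taxids[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Node level (edges from the root)
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Vector of taxon ids.
#' @return Integer vector of levels.
#' @export
taxon_level <- function(tree, taxids) {
  tree$nodes$level[tax_index(tree, taxids)]
}

#' Node rank label
#' @inheritParams taxon_level
#' @return Character vector of rank labels.
#' @export
taxon_rank <- function(tree, taxids) {
  tree$nodes$rank[tax_index(tree, taxids)]
}

#' Node scientific name
#' @inheritParams taxon_level
#' @return Character vector of names.
#' @export
taxon_name <- function(tree, taxids) {
  tree$nodes$name[tax_index(tree, taxids)]
}

# LCA in index space: longest common prefix of the two root paths
lca_idx <- function(tree, i, j) {
  if (i == j) return(i)
  p <- tree$paths[[i]]
  q <- tree$paths[[j]]
  m <- min(length(p), length(q))
  common <- sum(cumprod(p[seq_len(m)] == q[seq_len(m)]))
  p[common]
}

#' Lowest common ancestor of two taxa
#'
#' The deepest node lying on the root paths of both `a` and `b`.
#'
#' @param tree A [taxonomy_tree()].
#' @param a,b Taxon ids present in the tree.
#' @return The LCA's taxon id.
#' @export
lca <- function(tree, a, b) {
  tree$nodes$tax_id[lca_idx(tree, tax_index(tree, a), tax_index(tree, b))]
}

#' Lowest common ancestor of a set of taxa
#'
#' Left fold of [lca()] over the list; the result is independent of order.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Non-empty vector of taxon ids.
#' @return The combined LCA's taxon id.
#' @export
lca_set <- function(tree, taxids) {
  if (!length(taxids)) stop("lca_set() requires a non-empty set of taxa")
  idx <- tax_index(tree, taxids)
  acc <- idx[1L]
  for (i in idx[-1L]) {
    acc <- lca_idx(tree, acc, i)
    if (acc == tree$paths[[acc]][1L]) break  # at root; cannot go shallower
  }
  tree$nodes$tax_id[acc]
}

#' Ancestor of a taxon at a given canonical rank
#'
#' Walks the lineage from `taxid` (inclusive) towards the root and returns
#' the first node whose rank equals `rank`, or `NA` when the lineage lacks
#' that rank.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxid A taxon id present in the tree.
#' @param rank A canonical rank label.
#' @return The ancestor's taxon id, or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  path <- tree$paths[[tax_index(tree, taxid)]]
  hit <- path[tree$nodes$rank[path] == rank]
  if (length(hit)) tree$nodes$tax_id[hit[length(hit)]] else NA_integer_
}

#' Path distance between two taxa
#'
#' Number of edges on the path connecting the two nodes in the taxonomy
#' tree: when one is an ancestor of the other this is their level
#' difference, otherwise the sum of each node's level difference to their
#' lowest common ancestor. Symmetric, zero iff `a == b`.
#'
#' @param tree A [taxonomy_tree()].
#' @param a,b Taxon ids present in the tree.
#' @return Non-negative integer edge count.
#' @export
pairwise_distance <- function(tree, a, b) {
  i <- tax_index(tree, a)
  j <- tax_index(tree, b)
  l <- lca_idx(tree, i, j)
  lev <- tree$nodes$level
  (lev[i] - lev[l]) + (lev[j] - lev[l])
}

#' Taxa on the path from a node up to the root
#'
#' @param tree A [taxonomy_tree()].
#' @param taxid A taxon id present in the tree.
#' @return Integer vector of taxon ids, root first, `taxid` last.
#' @export
path_to_root <- function(tree, taxid) {
  tree$nodes$tax_id[tree$paths[[tax_index(tree, taxid)]]]
}

# per-rank projection of every node: n x 7 integer matrix of taxids (NA
# where a lineage lacks the rank); used to make TL substitution O(1)
rank_projection_table <- function(tree) {
  ranks <- canonical_ranks()
  n <- nrow(tree$nodes)
  proj <- matrix(NA_integer_, nrow = n, ncol = length(ranks),
                 dimnames = list(NULL, ranks))
  node_rank <- tree$nodes$rank
  node_id <- tree$nodes$tax_id
  ord <- order(tree$nodes$level)
  root <- which(tree$nodes$level == 0L)
  for (i in ord) {
    if (i != root) proj[i, ] <- proj[tree$parent_idx[i], ]
    r <- match(node_rank[i], ranks)
    if (!is.na(r)) proj[i, r] <- node_id[i]
  }
  proj
}

#' Read a taxonomy from the toy TSV dialect
#'
#' One row per node with header `tax_id  parent_id  rank  name`; the root
#' row has `tax_id == parent_id`. This is the format written by
#' [write_taxonomy_tsv()] and by the scenario generators.
#'
#' @param path Path to a tab-separated node table.
#' @return A [taxonomy_tree()].
#' @export
read_taxonomy_tsv <- function(path) {
  nodes <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    integer = c("tax_id", "parent_id"), character = c("rank", "name")))
  taxonomy_tree(nodes)
}

#' Write a taxonomy in the toy TSV dialect
#'
#' @param tree A [taxonomy_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(tree, path) {
  fwrite(tree$nodes[, .(tax_id, parent_id, rank, name)], path, sep = "\t")
  invisible(path)
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses the `nodes.dmp` / `names.dmp` dialect (fields separated by
#' `"\t|\t"`, rows terminated by `"\t|"`). Scientific names are preferred;
#' nodes without one fall back to any available name, then to the taxid.
#'
#' @param nodes_path Path to a `nodes.dmp`-style file (tax_id, parent
#'   tax_id, rank, ...).
#' @param names_path Path to a `names.dmp`-style file (tax_id, name_txt,
#'   unique name, name class).
#' @return A [taxonomy_tree()].
#' @export
read_ncbi_taxdump <- function(nodes_path, names_path) {
  parse_dmp <- function(path, n_fields) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    parts <- strsplit(lines, "\t\\|\t")
    bad <- which(lengths(parts) < n_fields)
    if (length(bad)) {
      stop("malformed dump row at line ", bad[1L], " of ", path)
    }
    do.call(rbind, lapply(parts, function(p) p[seq_len(n_fields)]))
  }
  nd <- parse_dmp(nodes_path, 3L)
  nodes <- data.table(tax_id = as.integer(nd[, 1L]),
                      parent_id = as.integer(nd[, 2L]),
                      rank = trimws(nd[, 3L]))
  nm <- parse_dmp(names_path, 4L)
  names_dt <- data.table(tax_id = as.integer(nm[, 1L]),
                         name = trimws(nm[, 2L]),
                         name_class = trimws(nm[, 4L]))
  sci <- names_dt[name_class == "scientific name",
                  .(name = name[1L]), by = tax_id]
  any_name <- names_dt[, .(fallback = name[1L]), by = tax_id]
  nodes <- merge(nodes, sci, by = "tax_id", all.x = TRUE)
  nodes <- merge(nodes, any_name, by = "tax_id", all.x = TRUE)
  nodes[is.na(name), name := fallback]
  nodes[is.na(name), name := as.character(tax_id)]
  nodes[, fallback := NULL]
  taxonomy_tree(nodes)
}

#' Load a taxonomy from either supported format
#'
#' With both `nodes_source` and `names_source`, reads the NCBI dump
#' dialect; with only `nodes_source`, reads the toy TSV dialect.
#'
#' @param nodes_source Path to `nodes.dmp` or to a toy-TSV node table.
#' @param names_source Optional path to `names.dmp`.
#' @return A [taxonomy_tree()].
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  if (is.null(names_source)) {
    read_taxonomy_tsv(nodes_source)
  } else {
    read_ncbi_taxdump(nodes_source, names_source)
  }
}
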