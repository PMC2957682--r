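library(data.table)

# the worked-example lineage and read shipped with the package
demo_taxonomy <- function() example_taxonomy()
demo_read_hits <- function() example_read_hits()

# undirected graph view of a taxonomy for BFS oracles
tree_graph <- function(tree) {
  non_root <- tree$nodes$tax_id != tree$root_id
  igraph::graph_from_edgelist(cbind(
    as.character(tree$nodes$parent_id[non_root]),
    as.character(tree$nodes$tax_id[non_root])), directed = FALSE)
}

# all-pairs shortest-path matrix indexed by taxid strings
oracle_distances <- function(tree) {
  igraph::distances(tree_graph(tree))
}

# LCA by intersecting full root paths and taking the deepest shared node
oracle_lca <- function(tree, a, b) {
  shared <- intersect(path_to_root(tree, a), path_to_root(tree, b))
  shared[which.max(taxon_level(tree, shared))]
}
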