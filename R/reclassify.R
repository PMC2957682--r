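# Isolated-taxon reclassification: taxa holding fewer reads than the
# isolated-taxon size have their reads promoted up the lineage to the
# first sufficiently populated ancestor (at or below superkingdom),
# instead of being discarded as a minimum-bin-size filter would.

#' Isolated-taxon size threshold
#'
#' The population threshold below which a taxon counts as isolated:
#' `min(cap, ceiling(fraction * total_reads))`, floored at 1. With the
#' defaults this is 300 reads or 1% of the data set, whichever is less —
#' the cap keeps low-coverage organisms with small genomes from being
#' treated as isolated in large data sets.
#'
#' @param total_reads Total number of reads in the data set.
#' @param cap Absolute cap (default 300).
#' @param fraction Fraction of `total_reads` (default 0.01).
#' @return A positive integer threshold.
#' @examples
#' isolated_taxon_size(35000) # 300
#' isolated_taxon_size(10000) # 100
#' @export
isolated_taxon_size <- function(total_reads, cap = 300L, fraction = 0.01) {
  stopifnot(total_reads >= 1)
  max(1L, min(as.integer(cap), as.integer(ceiling(fraction * total_reads))))
}

#' Per-taxon direct and cumulative read counts
#'
#' Tabulates how many reads are assigned exactly at each taxon (`direct`)
#' and how many fall anywhere in its subtree including itself
#' (`cumulative`), via one bottom-up sweep. The root's cumulative count
#' equals the number of Assigned reads.
#'
#' @param tree A [taxonomy_tree()].
#' @param assignments An assignment table from [assign_reads()].
#' @return A `data.table` with columns `tax_id`, `direct`, `cumulative`,
#'   restricted to taxa with a non-zero cumulative count.
#' @export
build_bin_table <- function(tree, assignments) {
  assignments <- as.data.table(assignments)
  assigned <- assignments[status == "Assigned"]
  idx <- match(assigned$tax_id, tree$nodes$tax_id)
  if (anyNA(idx)) {
    stop("assigned tax_id not present in the taxonomy: ",
         paste(unique(assigned$tax_id[is.na(idx)]), collapse = ", "))
  }
  n <- nrow(tree$nodes)
  direct <- tabulate(idx, nbins = n)
  cumulative <- direct
  ord <- order(tree$nodes$level, decreasing = TRUE)
  for (i in ord) {
    if (tree$nodes$level[i] > 0L) {
      p <- tree$parent_idx[i]
      cumulative[p] <- cumulative[p] + cumulative[i]
    }
  }
  keep <- cumulative > 0L
  data.table(tax_id = tree$nodes$tax_id[keep], direct = direct[keep],
             cumulative = cumulative[keep])
}

#' Reclassify reads assigned to isolated taxa
#'
#' A taxon is isolated when its direct read count is below the threshold.
#' Reads of each isolated taxon are moved to the first ancestor — walking
#' from the immediate parent towards the root, but never above the
#' lineage's superkingdom (or other `ceiling_rank`) node — whose
#' cumulative read count on the original table exceeds the threshold. If
#' no ancestor up to the ceiling qualifies, those reads become
#' `Unassigned`. Cumulative counts are computed once on the input and
#' frozen for the whole pass, so the result does not depend on the order
#' in which isolated taxa are processed; set `iterate = TRUE` to repeat
#' passes (with recomputed counts) to a fixed point.
#'
#' @param tree A [taxonomy_tree()].
#' @param assignments An assignment table from [assign_reads()].
#' @param size Isolated-taxon size; default
#'   `isolated_taxon_size(total_reads, cap, fraction)`.
#' @param total_reads Total read count used for the default threshold;
#'   defaults to the number of rows of `assignments` (which includes
#'   Unassigned/NoHits rows when present).
#' @param cap,fraction Passed to [isolated_taxon_size()].
#' @param ceiling_rank Rank above which no read is ever promoted.
#' @param iterate Repeat passes until no assignment changes (bounded by
#'   the tree depth).
#' @return The assignment table with promoted reads carrying
#'   `route = "reclassified"` and their previous taxon in `old_tax_id`
#'   (`NA` for untouched rows).
#' @export
reclassify_assignments <- function(tree, assignments, size = NULL,
                                   total_reads = nrow(assignments),
                                   cap = 300L, fraction = 0.01,
                                   ceiling_rank = "superkingdom",
                                   iterate = FALSE) {
  assignments <- as.data.table(assignments)
  if (is.null(size)) size <- isolated_taxon_size(total_reads, cap, fraction)
  out <- copy(assignments)
  if (!"old_tax_id" %in% names(out)) out[, old_tax_id := NA_integer_]

  max_passes <- if (iterate) max(tree$nodes$level) + 1L else 1L
  for (pass in seq_len(max_passes)) {
    changed <- reclassify_pass(tree, out, size, ceiling_rank)
    out <- changed$assignments
    if (!changed$any) break
  }
  out[]
}

reclassify_pass <- function(tree, assignments, size, ceiling_rank) {
  bins <- build_bin_table(tree, assignments)
  isolated <- bins[direct > 0L & direct < size, tax_id]
  if (!length(isolated)) {
    return(list(assignments = assignments, any = FALSE))
  }
  cum <- setNames(bins$cumulative, bins$tax_id)
  lev <- tree$nodes$level
  any_change <- FALSE
  for (t in isolated) {
    i <- tax_index(tree, t)
    ceil_id <- ancestor_at_rank(tree, t, ceiling_rank)
    ceil_level <- if (is.na(ceil_id)) NA_integer_ else taxon_level(tree, ceil_id)
    target <- NA_integer_
    j <- i
    while (lev[j] > 0L) {
      j <- tree$parent_idx[j]
      if (is.na(ceil_level) || lev[j] < ceil_level) break  # above the ceiling
      cj <- cum[as.character(tree$nodes$tax_id[j])]
      if (!is.na(cj) && cj > size) {
        target <- tree$nodes$tax_id[j]
        break
      }
      if (lev[j] == ceil_level) break
    }
    rows <- which(assignments$status == "Assigned" & assignments$tax_id == t)
    if (is.na(target)) {
      assignments[rows, `:=`(status = "Unassigned",
                             old_tax_id = tax_id,
                             tax_id = NA_integer_, name = NA_character_,
                             rank = NA_character_, route = "reclassified")]
    } else {
      assignments[rows, `:=`(old_tax_id = tax_id,
                             tax_id = as.integer(target),
                             name = taxon_name(tree, target),
                             rank = taxon_rank(tree, target),
                             route = "reclassified")]
    }
    any_change <- TRUE
  }
  list(assignments = assignments, any = any_change)
}
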