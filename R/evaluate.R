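# Accuracy and specificity accounting against known read origins:
# Correct/Wrong/Unassigned/NoHits categories and the Higher/Intermediate/
# Specific depth classes of correct assignments.

#' Specificity class of an assignment depth
#'
#' `Higher` for the root, "cellular organisms"-style nodes above the
#' superkingdom, and superkingdom itself; `Intermediate` for phylum,
#' class and order; `Specific` for family and every deeper rank. A node
#' of non-canonical rank (e.g. a species group or a strain-level "no
#' rank" node) takes the class of its nearest canonically ranked
#' ancestor; nodes with no canonical ancestor at all sit above the
#' superkingdom and are `Higher`.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Vector of assigned taxon ids.
#' @return Character vector in `{"Higher", "Intermediate", "Specific"}`.
#' @export
specificity_class <- function(tree, taxids) {
  vapply(taxids, function(t) {
    path <- rev(path_to_root(tree, t))  # node first, root last
    depths <- rank_depth(taxon_rank(tree, path))
    d <- depths[!is.na(depths)][1L]
    if (is.na(d) || d == 1L) "Higher"
    else if (d <= 4L) "Intermediate"
    else "Specific"
  }, character(1))
}

#' Categorize assignments against known source taxa
#'
#' An Assigned read is `Correct` when its assigned taxon lies on the path
#' between the root and the read's true source taxon (ancestor-or-self of
#' the truth), `Wrong` otherwise; `Unassigned` and `NoHits` pass through.
#' Correct assignments additionally get a specificity class.
#'
#' @param tree A [taxonomy_tree()].
#' @param assignments Assignment table from [assign_reads()] or
#'   [reclassify_assignments()].
#' @param truth A data.frame with columns `read_id`, `true_tax_id` (or a
#'   path to such a TSV). Every assigned read must be present.
#' @return The assignment table with added `true_tax_id`, `category` and
#'   `specificity` columns.
#' @export
categorize_assignments <- function(tree, assignments, truth) {
  assignments <- as.data.table(assignments)
  if (is.character(truth) && length(truth) == 1L) {
    truth <- fread(truth, sep = "\t", header = TRUE)
  }
  truth <- as.data.table(truth)
  setnames(truth, 1:2, c("read_id", "true_tax_id"))
  truth[, read_id := as.character(read_id)]
  truth[, true_tax_id := as.integer(true_tax_id)]
  missing <- setdiff(assignments$read_id, truth$read_id)
  if (length(missing)) {
    stop("no truth record for read(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  tax_index(tree, unique(truth$true_tax_id))  # errors on unknown truth taxa

  out <- merge(assignments, truth, by = "read_id", all.x = TRUE, sort = FALSE)
  out[, category := status]
  out[, specificity := "not-applicable"]
  assigned <- which(out$status == "Assigned")
  if (length(assigned)) {
    on_path <- vapply(assigned, function(r) {
      out$tax_id[r] %in% path_to_root(tree, out$true_tax_id[r])
    }, logical(1))
    out[assigned, category := ifelse(on_path, "Correct", "Wrong")]
    corr <- assigned[on_path]
    if (length(corr)) {
      out[corr, specificity := specificity_class(tree, tax_id)]
    }
  }
  setorder(out, read_id)
  out[]
}

#' Summarize evaluation records
#'
#' Percentages per category (`Correct`, `Wrong`, `Unassigned`, `NoHits`;
#' summing to 100 over all reads) and, within the correct assignments,
#' per specificity class (`Higher`, `Intermediate`, `Specific`).
#'
#' @param records Output of [categorize_assignments()].
#' @return A list of two `data.table`s: `categories` (`category`,
#'   `n_reads`, `pct`) and `specificity` (`specificity`, `n_reads`,
#'   `pct`, percentages of all reads).
#' @export
summarize_evaluation <- function(records) {
  records <- as.data.table(records)
  if (!nrow(records)) stop("cannot summarize an empty record list")
  total <- nrow(records)
  cat_levels <- c("Correct", "Wrong", "Unassigned", "NoHits")
  categories <- records[, .(n_reads = .N), by = category]
  categories <- categories[
    data.table(category = cat_levels), on = "category"]
  categories[is.na(n_reads), n_reads := 0L]
  categories[, pct := 100 * n_reads / total]

  spec_levels <- c("Higher", "Intermediate", "Specific")
  spec <- records[category == "Correct", .(n_reads = .N), by = specificity]
  spec <- spec[data.table(specificity = spec_levels), on = "specificity"]
  spec[is.na(n_reads), n_reads := 0L]
  spec[, pct := 100 * n_reads / total]

  list(categories = categories[], specificity = spec[])
}

#' Fold coverage of a genome by a read set
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in base pairs.
#' @param genome_length Genome length in base pairs.
#' @return Fold coverage, rounded to two decimals.
#' @examples
#' fold_coverage(300, 1000, 0.6e6) # 0.5
#' fold_coverage(300, 250, 0.6e6)  # 0.13
#' @export
fold_coverage <- function(n_reads, read_length, genome_length) {
  stopifnot(read_length > 0, genome_length > 0, n_reads >= 0)
  # half-up at two decimals (0.125 -> 0.13), the usual reporting convention
  floor(n_reads * read_length / genome_length * 100 + 0.5) / 100
}
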