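# Taxonomic level (TL) restriction: the better the best hit's alignment,
# the deeper the rank at which a read may be assigned. All hit taxa are
# projected onto that rank before any LCA or scoring step.

#' Construct a TL rule table
#'
#' A TL configuration maps the best hit's alignment quality to the deepest
#' rank at which the read may be assigned. Rules are scanned in order of
#' decreasing stringency and the first rule whose identity (and, when
#' available, positives) fraction thresholds are met fires; if none fires
#' the fallback rank applies.
#'
#' @param rules A data.frame with columns `rank` (canonical rank label),
#'   `min_identity` and `min_positive` (fractions of the alignment length,
#'   in \[0, 1\]). Rows must be ordered deepest rank first and be monotone:
#'   deeper ranks require higher fractions.
#' @param fallback_rank Rank applied when no rule matches; must be at least
#'   as shallow as every rule's rank.
#' @return A `tl_config` object.
#' @export
tl_config <- function(rules, fallback_rank = "superkingdom") {
  rules <- as.data.table(rules)
  stopifnot(all(c("rank", "min_identity", "min_positive") %in% names(rules)),
            nrow(rules) >= 1L)
  if (anyNA(rank_depth(rules$rank)) || is.na(rank_depth(fallback_rank))) {
    stop("TL ranks must be canonical rank labels")
  }
  if (any(rules$min_identity < 0 | rules$min_identity > 1) ||
      any(rules$min_positive < 0 | rules$min_positive > 1)) {
    stop("TL thresholds must be fractions in [0, 1]")
  }
  if (is.unsorted(rev(rank_depth(rules$rank)), strictly = TRUE)) {
    stop("TL rules must be ordered from deepest to shallowest rank")
  }
  if (is.unsorted(rev(rules$min_identity)) ||
      is.unsorted(rev(rules$min_positive))) {
    stop("TL thresholds must decrease with shallower ranks")
  }
  if (rank_depth(fallback_rank) > min(rank_depth(rules$rank))) {
    stop("fallback_rank must be at least as shallow as every rule's rank")
  }
  structure(list(rules = rules, fallback_rank = fallback_rank),
            class = "tl_config")
}

#' Default TL rule table
#'
#' Maps best-hit identity and positives fractions to the restriction rank.
#' The thresholds are calibration constants shipped with this package (the
#' quality-to-rank idea follows earlier two-phase binners, whose exact
#' cut-offs are not published); override them via [tl_config()] or edit a
#' copy of this table.
#'
#' @return A `tl_config` object.
#' @export
default_tl_config <- function() {
  tl_config(data.frame(
    rank         = c("species", "genus", "family", "order", "class", "phylum"),
    min_identity = c(0.90,      0.80,    0.70,     0.60,    0.50,    0.40),
    min_positive = c(0.95,      0.90,    0.80,     0.70,    0.60,    0.50)),
    fallback_rank = "superkingdom")
}

#' @export
print.tl_config <- function(x, ...) {
  cat("TL rule table (first match wins):\n")
  print(x$rules)
  cat("fallback rank:", x$fallback_rank, "\n")
  invisible(x)
}

#' Determine the taxonomic level of restriction for a read
#'
#' Applies the TL rule table to the read's best (top-scoring valid) hit.
#' Fractions are computed against the full alignment length, gap columns
#' included. When the hit lacks a positives count (plain 12-column tabular
#' output) only the identity thresholds are tested.
#'
#' @param best_hit A one-row hit table (the read's best valid hit).
#' @param config A [tl_config()].
#' @return A canonical rank label: the deepest rank at which this read may
#'   be assigned.
#' @export
determine_tl <- function(best_hit, config = default_tl_config()) {
  stopifnot(inherits(config, "tl_config"))
  ident_frac <- best_hit$identities[1L] / best_hit$alignment_length[1L]
  pos_frac <- if (is.na(best_hit$positives[1L])) NA_real_ else
    best_hit$positives[1L] / best_hit$alignment_length[1L]
  rules <- config$rules
  for (k in seq_len(nrow(rules))) {
    ok <- ident_frac >= rules$min_identity[k] &&
      (is.na(pos_frac) || pos_frac >= rules$min_positive[k])
    if (ok) return(rules$rank[k])
  }
  config$fallback_rank
}

#' Substitute hit taxa by their ancestors at the TL rank
#'
#' Replaces each hit's taxon by its ancestor at rank `tl`. A hit whose
#' lineage lacks that rank is substituted by its nearest canonical-ranked
#' ancestor shallower than `tl` (falling back to the root when the lineage
#' carries no canonical rank at all), so every hit yields a node at or
#' above the TL. Hit order is preserved; re-applying at the same TL is a
#' no-op.
#'
#' @param tree A [taxonomy_tree()].
#' @param hits An ordered, valid-filtered hit table.
#' @param tl A canonical rank label.
#' @return The hit table with an added `subst_tax_id` column.
#' @export
substitute_at_tl <- function(tree, hits, tl) {
  proj <- rank_projection_table(tree)
  hits <- as.data.table(hits)
  hits[, subst_tax_id := substitute_idx(tree, proj,
                                        tax_index(tree, tax_id), tl)]
  hits[]
}

# index-space substitution against a precomputed projection table
substitute_idx <- function(tree, proj, idx, tl) {
  depth <- rank_depth(tl)
  out <- proj[idx, depth]
  if (anyNA(out)) {
    for (d in rev(seq_len(depth - 1L))) {
      miss <- is.na(out)
      if (!any(miss)) break
      out[miss] <- proj[idx[miss], d]
    }
    out[is.na(out)] <- tree$root_id
  }
  out
}
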