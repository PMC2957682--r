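# Candidate-ancestor enumeration, bit-score/distance scoring, and the
# per-read assignment routes (single-hit, two-hit LCA, most probable
# ancestor). A plain-LCA baseline is provided for comparison.

# --- index-space engine -----------------------------------------------------

# running LCA over growing prefixes of the (ordered) substituted taxa;
# a candidate is appended only when the running LCA changes
cand_chain_idx <- function(tree, idx) {
  cur <- lca_idx(tree, idx[1L], idx[2L])
  cand <- cur
  introduced <- 2L
  for (k in seq_along(idx)[-(1:2)]) {
    nxt <- lca_idx(tree, cur, idx[k])
    if (nxt != cur) {
      cand <- c(cand, nxt)
      introduced <- c(introduced, k)
      cur <- nxt
    }
  }
  list(idx = cand, introduced_at = introduced)
}

# ratio_sum(c) = sum over hits of bit / (distance(c, hit taxon) + 1);
# the +1 keeps the ratio defined when a hit taxon equals the candidate
ratio_sums_idx <- function(tree, bits, hit_idx, cand_idx) {
  lev <- tree$nodes$level
  vapply(cand_idx, function(ci) {
    d <- vapply(hit_idx, function(hi) {
      l <- lca_idx(tree, ci, hi)
      (lev[ci] - lev[l]) + (lev[hi] - lev[l])
    }, integer(1))
    sum(bits / (d + 1))
  }, numeric(1))
}

# argmax of ratio sums; exact ties resolve towards the deepest candidate
pick_mpa_idx <- function(tree, cand_idx, sums) {
  best <- which(sums == max(sums))
  if (length(best) > 1L) {
    best <- best[which.max(tree$nodes$level[cand_idx[best]])]
  }
  cand_idx[best[1L]]
}

# one read, already valid-filtered and ordered; returns list(tax_idx, route)
assign_one_idx <- function(tree, subst_idx, bits) {
  n <- length(subst_idx)
  if (n == 1L) return(list(idx = subst_idx, route = "single-hit"))
  if (n == 2L) {
    return(list(idx = lca_idx(tree, subst_idx[1L], subst_idx[2L]),
                route = "two-hit-LCA"))
  }
  if (all(subst_idx == subst_idx[1L])) {
    # degenerate chain of length one
    return(list(idx = subst_idx[1L], route = "MPA"))
  }
  chain <- cand_chain_idx(tree, subst_idx)
  sums <- ratio_sums_idx(tree, bits, subst_idx, chain$idx)
  list(idx = pick_mpa_idx(tree, chain$idx, sums), route = "MPA")
}

# --- exported operations ----------------------------------------------------

#' Enumerate candidate ancestors for a read
#'
#' Walks the score-ordered list of substituted hit taxa, maintaining the
#' running LCA of each growing prefix (top two, top three, ...). Every time
#' the running LCA changes, the new node is appended to the candidate set,
#' so the candidates form a root-ward chain whose first element is the LCA
#' of the top two taxa and whose last element is the LCA of all of them.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Taxon ids of the substituted hits, ordered by descending
#'   bit score; at least three (reads with fewer hits use the single-hit /
#'   two-hit-LCA routes instead).
#' @return A `data.table` with columns `tax_id`, `introduced_at` (index of
#'   the hit whose inclusion produced the candidate) and `level`.
#' @export
enumerate_candidate_ancestors <- function(tree, taxids) {
  if (length(taxids) < 3L) {
    stop("candidate enumeration needs >= 3 hits; ",
         "route 1- and 2-hit reads through assign_read()")
  }
  chain <- cand_chain_idx(tree, tax_index(tree, taxids))
  data.table(tax_id = tree$nodes$tax_id[chain$idx],
             introduced_at = chain$introduced_at,
             level = tree$nodes$level[chain$idx])
}

#' Score candidate ancestors by summed bit-score/distance ratios
#'
#' For every candidate, sums over all hits the hit's bit score divided by
#' the tree distance between the candidate and the hit's (substituted)
#' taxon. Distances are offset by one edge uniformly so that the ratio is
#' defined when a hit taxon coincides with the candidate; closer taxa
#' still contribute strictly larger ratios.
#'
#' @param tree A [taxonomy_tree()].
#' @param substituted A data.frame with columns `bit_score` and
#'   `subst_tax_id` (or `tax_id`), one row per hit, every hit contributing
#'   to every candidate.
#' @param candidates Output of [enumerate_candidate_ancestors()].
#' @return `candidates` with an added `ratio_sum` column (bits per edge).
#' @export
score_candidates <- function(tree, substituted, candidates) {
  substituted <- as.data.table(substituted)
  taxcol <- if ("subst_tax_id" %in% names(substituted)) "subst_tax_id" else "tax_id"
  candidates <- as.data.table(candidates)
  sums <- ratio_sums_idx(tree, substituted$bit_score,
                         tax_index(tree, substituted[[taxcol]]),
                         tax_index(tree, candidates$tax_id))
  candidates[, ratio_sum := sums]
  candidates[]
}

#' Select the Most Probable Ancestor
#'
#' The candidate with the highest summed bit-score/distance ratio; exact
#' ties resolve towards the deeper candidate, since specificity is the
#' point of the ratio scoring.
#'
#' @param scored Output of [score_candidates()].
#' @return The selected taxon id.
#' @export
select_mpa <- function(scored) {
  scored <- as.data.table(scored)
  if (!nrow(scored)) stop("select_mpa() requires a non-empty candidate list")
  best <- scored[ratio_sum == max(ratio_sum)]
  best[which.max(level), tax_id]
}

#' Assign a single read
#'
#' Runs the full per-read pipeline: validity filtering, TL determination
#' from the best valid hit, substitution of all hit taxa at the TL, then
#' one of the routes: zero rows before filtering gives `NoHits`; an empty
#' filtered set gives `Unassigned`; one valid hit is assigned to its
#' substituted taxon; two to the LCA of the two substituted taxa; three or
#' more to the most probable ancestor. The assigned taxon is always at the
#' TL or shallower.
#'
#' @param tree A [taxonomy_tree()].
#' @param read_hits Hit-table rows for one read (possibly zero rows).
#' @param config A [tl_config()].
#' @param min_bit_score,min_alignment_length Validity thresholds, see
#'   [filter_valid_hits()].
#' @return A one-row `data.table` with columns `read_id`, `status`
#'   (`Assigned`/`Unassigned`/`NoHits`), `tax_id`, `name`, `rank`, `route`
#'   (`single-hit`/`two-hit-LCA`/`MPA`), `tl`.
#' @export
assign_read <- function(tree, read_hits, config = default_tl_config(),
                        min_bit_score = 35, min_alignment_length = 25L) {
  read_hits <- as.data.table(read_hits)
  rid <- if (nrow(read_hits)) read_hits$query_id[1L] else NA_character_
  if (nrow(read_hits) &&
      length(unique(read_hits$query_id)) != 1L) {
    stop("assign_read() expects hits of a single read")
  }
  out <- assign_reads(tree, read_hits, config = config,
                      min_bit_score = min_bit_score,
                      min_alignment_length = min_alignment_length,
                      all_read_ids = rid)
  out
}

#' Assign every read in a hit table
#'
#' Vectorised driver over [assign_read()]'s logic: orders and filters the
#' hit table once, determines each read's TL from its best valid hit,
#' substitutes hit taxa at the TL, and applies the single-hit, two-hit-LCA
#' or most-probable-ancestor route. Hits whose taxid is absent from the
#' taxonomy are skipped with a warning.
#'
#' @param tree A [taxonomy_tree()].
#' @param hits A hit table (any row order; reordered internally).
#' @param config A [tl_config()].
#' @param min_bit_score,min_alignment_length Validity thresholds.
#' @param all_read_ids Optional character vector of every read in the
#'   data set; reads absent from `hits` are reported as `NoHits`. Without
#'   it only reads with at least one BLAST row appear in the output.
#' @return A `data.table`, one row per read ordered by `read_id`, with
#'   columns `read_id`, `status`, `tax_id`, `name`, `rank`, `route`, `tl`.
#' @export
assign_reads <- function(tree, hits, config = default_tl_config(),
                         min_bit_score = 35, min_alignment_length = 25L,
                         all_read_ids = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"), inherits(config, "tl_config"))
  hits <- order_hits(as.data.table(hits))

  known <- match(hits$tax_id, tree$nodes$tax_id)
  if (anyNA(known)) {
    warning(sum(is.na(known)),
            " hit(s) skipped: tax_id not present in the taxonomy")
    hits <- hits[!is.na(known)]
  }
  had_rows <- unique(hits$query_id)
  valid <- filter_valid_hits(hits, min_bit_score, min_alignment_length)

  proj <- rank_projection_table(tree)
  idx_all <- match(valid$tax_id, tree$nodes$tax_id)
  groups <- split(seq_len(nrow(valid)), valid$query_id)

  res <- vector("list", length(groups))
  rules <- config$rules
  nodes <- tree$nodes
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    ident_frac <- valid$identities[rows[1L]] / valid$alignment_length[rows[1L]]
    pos <- valid$positives[rows[1L]]
    pos_frac <- if (is.na(pos)) NA_real_ else
      pos / valid$alignment_length[rows[1L]]
    tl <- config$fallback_rank
    for (k in seq_len(nrow(rules))) {
      if (ident_frac >= rules$min_identity[k] &&
          (is.na(pos_frac) || pos_frac >= rules$min_positive[k])) {
        tl <- rules$rank[k]
        break
      }
    }
    subst <- substitute_idx(tree, proj, idx_all[rows], tl)
    a <- assign_one_idx(tree, subst, valid$bit_score[rows])
    res[[g]] <- list(read_id = names(groups)[g],
                     tax_id = nodes$tax_id[a$idx],
                     route = a$route, tl = tl)
  }
  assigned <- rbindlist(res)
  if (nrow(assigned)) {
    assigned[, `:=`(status = "Assigned",
                    name = taxon_name(tree, tax_id),
                    rank = taxon_rank(tree, tax_id))]
  } else {
    assigned <- data.table(read_id = character(), tax_id = integer(),
                           route = character(), tl = character(),
                           status = character(), name = character(),
                           rank = character())
  }

  unassigned <- setdiff(had_rows, assigned$read_id)
  nohits <- if (is.null(all_read_ids)) character() else
    setdiff(unique(as.character(all_read_ids)), had_rows)
  extra <- data.table(
    read_id = c(unassigned, nohits),
    tax_id = NA_integer_, route = NA_character_, tl = NA_character_,
    status = rep(c("Unassigned", "NoHits"),
                 c(length(unassigned), length(nohits))),
    name = NA_character_, rank = NA_character_)
  out <- rbind(assigned, extra)
  setcolorder(out, c("read_id", "status", "tax_id", "name", "rank",
                     "route", "tl"))
  setorder(out, read_id)
  out[]
}

#' Plain lowest-common-ancestor baseline
#'
#' Assigns each read to the LCA of the raw taxa of all its valid hits,
#' with no TL restriction and no scoring — the classical conservative
#' strategy. Provided for qualitative comparison with the ratio-based
#' assignment; shares the validity filter and the NoHits/Unassigned
#' accounting with [assign_reads()].
#'
#' @inheritParams assign_reads
#' @return Same layout as [assign_reads()], `route` set to
#'   `"LCA-baseline"` and `tl` to `NA`.
#' @export
assign_reads_lca <- function(tree, hits, min_bit_score = 35,
                             min_alignment_length = 25L,
                             all_read_ids = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  hits <- order_hits(as.data.table(hits))
  known <- match(hits$tax_id, tree$nodes$tax_id)
  if (anyNA(known)) hits <- hits[!is.na(known)]
  had_rows <- unique(hits$query_id)
  valid <- filter_valid_hits(hits, min_bit_score, min_alignment_length)

  idx_all <- match(valid$tax_id, tree$nodes$tax_id)
  groups <- split(seq_len(nrow(valid)), valid$query_id)
  tax <- integer(length(groups))
  for (g in seq_along(groups)) {
    acc <- idx_all[groups[[g]][1L]]
    for (i in idx_all[groups[[g]]][-1L]) acc <- lca_idx(tree, acc, i)
    tax[g] <- tree$nodes$tax_id[acc]
  }
  assigned <- data.table(read_id = names(groups), tax_id = tax)
  if (nrow(assigned)) {
    assigned[, `:=`(status = "Assigned", name = taxon_name(tree, tax_id),
                    rank = taxon_rank(tree, tax_id),
                    route = "LCA-baseline", tl = NA_character_)]
  } else {
    assigned <- data.table(read_id = character(), tax_id = integer(),
                           status = character(), name = character(),
                           rank = character(), route = character(),
                           tl = character())
  }
  unassigned <- setdiff(had_rows, assigned$read_id)
  nohits <- if (is.null(all_read_ids)) character() else
    setdiff(unique(as.character(all_read_ids)), had_rows)
  extra <- data.table(
    read_id = c(unassigned, nohits),
    tax_id = NA_integer_,
    status = rep(c("Unassigned", "NoHits"),
                 c(length(unassigned), length(nohits))),
    name = NA_character_, rank = NA_character_,
    route = NA_character_, tl = NA_character_)
  out <- rbind(assigned, extra)
  setcolorder(out, c("read_id", "status", "tax_id", "name", "rank",
                     "route", "tl"))
  setorder(out, read_id)
  out[]
}

#' Write an assignment table as TSV
#'
#' @param assignments Output of [assign_reads()] or
#'   [reclassify_assignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  fwrite(as.data.table(assignments), path, sep = "\t")
  invisible(path)
}

#' Read an assignment table written by [write_assignments()]
#'
#' @param path Path to the TSV.
#' @return A `data.table` of assignments.
#' @export
read_assignments <- function(path) {
  out <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = "read_id"))
  out[, tax_id := as.integer(tax_id)]
  out[]
}
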