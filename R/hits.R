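# BLAST tabular ingestion: outfmt-6 parsing, taxid attachment, the
# deterministic hit ordering, and the bit-score/alignment-length validity
# filter applied before any assignment.

blast6_cols <- c("query_id", "subject_id", "pident", "alignment_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bit_score")

#' Parse BLAST tabular output and attach taxon ids
#'
#' Reads outfmt-6-style tabular output (12 canonical columns, optionally
#' extended) and returns one ordered hit table. Rows for one query need not
#' be contiguous. Identity counts are recovered from the percent-identity
#' column as `round(pident * alignment_length / 100)` unless a dedicated
#' count column is given. Hits whose subject has no taxid mapping are
#' dropped with a warning that reports how many were skipped.
#'
#' @param path Path to a tab-separated BLAST hit file.
#' @param taxid_map Either a data.frame with columns `subject_id`, `tax_id`
#'   (or a path to such a two-column TSV), or `NULL` when `taxid_col` is
#'   given.
#' @param taxid_col Optional 1-based index of an extra column carrying the
#'   subject taxid (e.g. `staxids` appended after the canonical 12).
#' @param positives_col Optional 1-based index of an extra column carrying
#'   the positive-substitution count.
#' @return A `data.table` with columns `query_id`, `subject_id`, `tax_id`,
#'   `bit_score`, `alignment_length`, `identities`, `positives` (`NA` when
#'   unavailable), `gaps`, `evalue`, ordered as by [order_hits()].
#' @export
read_blast_hits <- function(path, taxid_map = NULL, taxid_col = NULL,
                            positives_col = NULL) {
  raw <- fread(path, sep = "\t", header = FALSE, fill = TRUE)
  if (nrow(raw) == 0L) {
    return(empty_hit_table())
  }
  if (ncol(raw) < 12L) {
    stop("expected >= 12 tab-separated columns (outfmt 6), got ", ncol(raw))
  }
  hits <- raw[, 1:12]
  setnames(hits, blast6_cols)
  for (col in c("pident", "alignment_length", "mismatch", "gapopen",
                "evalue", "bit_score")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v)) {
      stop("malformed numeric field '", col, "' at line ",
           which(is.na(v))[1L], " of ", path)
    }
    set(hits, j = col, value = v)
  }
  hits[, query_id := as.character(query_id)]
  hits[, subject_id := as.character(subject_id)]
  hits[, alignment_length := as.integer(alignment_length)]
  hits[, identities := as.integer(round(pident * alignment_length / 100))]
  hits[, gaps := as.integer(gapopen)]
  hits[, positives := NA_integer_]
  if (!is.null(positives_col)) {
    if (ncol(raw) < positives_col) stop("positives_col beyond last column")
    hits[, positives := as.integer(raw[[positives_col]])]
  }

  if (!is.null(taxid_col)) {
    if (ncol(raw) < taxid_col) stop("taxid_col beyond last column")
    hits[, tax_id := suppressWarnings(as.integer(raw[[taxid_col]]))]
  } else {
    if (is.null(taxid_map)) {
      stop("either taxid_map or taxid_col must be supplied")
    }
    if (is.character(taxid_map) && length(taxid_map) == 1L) {
      taxid_map <- fread(taxid_map, sep = "\t", header = TRUE)
    }
    taxid_map <- as.data.table(taxid_map)
    setnames(taxid_map, 1:2, c("subject_id", "tax_id"))
    taxid_map[, subject_id := as.character(subject_id)]
    taxid_map[, tax_id := as.integer(tax_id)]
    hits[, tax_id := taxid_map[match(hits$subject_id, subject_id), tax_id]]
  }
  n_unmapped <- sum(is.na(hits$tax_id))
  if (n_unmapped > 0L) {
    warning(n_unmapped, " hit(s) skipped: subject without a taxid mapping")
    hits <- hits[!is.na(tax_id)]
  }
  order_hits(hits[, .(query_id, subject_id, tax_id, bit_score,
                      alignment_length, identities, positives, gaps, evalue)])
}

empty_hit_table <- function() {
  data.table(query_id = character(), subject_id = character(),
             tax_id = integer(), bit_score = numeric(),
             alignment_length = integer(), identities = integer(),
             positives = integer(), gaps = integer(), evalue = numeric())
}

#' Order a hit table deterministically
#'
#' Within each query: descending bit score, ties broken by ascending
#' subject taxid, then by original row order. This total order makes every
#' downstream step (candidate enumeration, top-two LCA) reproducible and
#' insensitive to the row order of the input file.
#'
#' @param hits A hit table as returned by [read_blast_hits()].
#' @return The same table, reordered (a copy).
#' @export
order_hits <- function(hits) {
  hits <- as.data.table(hits)
  hits[, .orig := .I]
  setorder(hits, query_id, -bit_score, tax_id, .orig)
  hits[, .orig := NULL]
  hits[]
}

#' Filter hits by the assignment validity thresholds
#'
#' A hit supports assignment only when its bit score is at least
#' `min_bit_score` and its alignment length strictly exceeds
#' `min_alignment_length` (defaults 35 bits and 25 columns). A read whose
#' hits are all removed here is reported as Unassigned, which is distinct
#' from NoHits (no BLAST rows at all).
#'
#' @param hits A hit table.
#' @param min_bit_score Minimum bit score (inclusive).
#' @param min_alignment_length Alignment length must be strictly greater.
#' @return The filtered hit table, order preserved.
#' @export
filter_valid_hits <- function(hits, min_bit_score = 35,
                              min_alignment_length = 25L) {
  as.data.table(hits)[bit_score >= min_bit_score &
                        alignment_length > min_alignment_length]
}

#' Write a hit table as 12-column BLAST outfmt 6
#'
#' The inverse of [read_blast_hits()] for the canonical columns: percent
#' identity is reconstituted from the identity count, mismatches as
#' `alignment_length - identities - gaps`, and query/subject coordinates
#' as `1..alignment_length`. `positives` is not representable in the
#' 12-column layout and is dropped.
#'
#' @param hits A hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  hits <- as.data.table(hits)
  out <- hits[, .(
    query_id, subject_id,
    pident = round(100 * identities / alignment_length, 3),
    alignment_length,
    mismatch = alignment_length - identities - gaps,
    gapopen = gaps,
    qstart = 1L, qend = alignment_length,
    sstart = 1L, send = alignment_length,
    evalue, bit_score)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a subject-to-taxid mapping TSV
#'
#' @param hits A hit table with `subject_id` and `tax_id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxid_map <- function(hits, path) {
  map <- unique(as.data.table(hits)[, .(subject_id, tax_id)])
  fwrite(map, path, sep = "\t")
  invisible(path)
}
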