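# Offline taxonomy: taxid -> ranked lineage resolution and rank-level set
# questions over hit tables. No network access by design; the lineage TSV
# stands in for live taxonomy lookups.

#' Construct a lineage store
#'
#' A lookup table from taxid to ranked lineage labels. Every rank column is
#' present for every row; unknown ranks hold [TAX_UNKNOWN].
#'
#' @param df data frame with columns `taxid` and the eight [TAX_RANKS];
#'   missing rank columns are filled with the sentinel. Empty by default.
#' @return A `lineage_store` data frame.
#' @export
lineage_store <- function(df = NULL) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character()), 9), LINEAGE_HEADER),
                        stringsAsFactors = FALSE)
  }
  if (!"taxid" %in% names(df)) stop("lineage_store: 'taxid' column required")
  df$taxid <- as.character(df$taxid)
  if (any(!nzchar(df$taxid))) stop("lineage_store: empty taxid")
  for (r in TAX_RANKS) {
    df[[r]] <- if (is.null(df[[r]])) rep(TAX_UNKNOWN, nrow(df)) else {
      x <- as.character(df[[r]])
      x[is.na(x) | !nzchar(x)] <- TAX_UNKNOWN
      x
    }
  }
  if (anyDuplicated(df$taxid)) {
    stop("lineage_store: duplicate taxid(s): ",
         paste(unique(df$taxid[duplicated(df$taxid)]), collapse = ", "))
  }
  df <- df[, LINEAGE_HEADER, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("lineage_store", "data.frame"))
}

#' Resolve taxon ids to ranked lineages
#'
#' Total by design: a taxid absent from the store resolves to an
#' all-sentinel lineage (and a warning is emitted) rather than an error, so
#' the query is later reported as unidentifiable instead of being dropped
#' silently. Vectorised over `taxid`.
#'
#' @param store a [lineage_store()].
#' @param taxid character (or coercible) vector of taxon ids.
#' @return Data frame with columns `taxid` and the eight [TAX_RANKS], one
#'   row per input id, in input order.
#' @export
resolve <- function(store, taxid) {
  taxid <- as.character(taxid)
  i <- match(taxid, store$taxid)
  if (anyNA(i)) {
    warning("unknown taxid(s) resolved to all-", TAX_UNKNOWN, ": ",
            paste(unique(taxid[is.na(i)]), collapse = ", "))
  }
  out <- data.frame(taxid = taxid, stringsAsFactors = FALSE)
  for (r in TAX_RANKS) {
    out[[r]] <- ifelse(is.na(i), TAX_UNKNOWN, store[[r]][i])
  }
  out
}

#' Distinct lineage labels at a rank among sufficiently similar hits
#'
#' The set of non-sentinel labels at `rank` among hits whose percent
#' identity is strictly greater than `min_pident` (the ambiguity-discard
#' rule's "greater than" is read literally). Hits resolving to the sentinel
#' are excluded from the set but counted and reported via `message()`:
#' unknown is not evidence of conflict.
#'
#' @param store a [lineage_store()].
#' @param hits hit-table data frame (columns `pident`, `staxid` used).
#' @param rank one of [TAX_RANKS].
#' @param min_pident strict lower identity bound, percent (default 80, the
#'   ambiguity floor).
#' @return Sorted character vector of distinct labels (possibly empty).
#' @export
distinct_labels_at_rank <- function(store, hits, rank, min_pident = 80) {
  rank <- match.arg(rank, TAX_RANKS)
  keep <- hits$pident > min_pident
  if (!any(keep)) return(character(0))
  labs <- resolve(store, hits$staxid[keep])[[rank]]
  n_sent <- sum(labs == TAX_UNKNOWN)
  if (n_sent > 0L) {
    message(n_sent, " hit(s) above ", min_pident,
            "% identity resolve to no ", rank, " label; excluded")
  }
  sort(unique(labs[labs != TAX_UNKNOWN]), method = "radix")
}
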