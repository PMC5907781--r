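# Per-query taxonomic classification under an identity threshold and the
# kingdom/phylum ambiguity-discard rule, plus the multi-threshold sweep.
#
# Status semantics (checked in this order for each query):
#   no_hit          - no rows in the hit table
#   ambiguous       - hits above the ambiguity floor (default 80%, strict)
#                     span >1 phylum, or >1 superkingdom, or >1 kingdom;
#                     independent of the sweep threshold by construction
#   below_threshold - best hit's identity < threshold (threshold inclusive:
#                     pident >= t counts as identified at t)
#   unresolvable    - best hit resolves to no phylum (sentinel lineage)
#   classified      - phylum/genus/species taken from the single best hit

#' Best hit for one query
#'
#' The hit maximising `(bitscore, pident, -evalue)` with deterministic
#' tie-breaking on lexicographically smallest `sseqid`, then smallest
#' `staxid` (numeric when all taxids parse as numbers). All hits must share
#' one `qseqid`.
#'
#' @param hits hit-table data frame for a single query (possibly 0 rows).
#' @return A one-row data frame, or `NULL` for an empty input.
#' @export
best_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  if (length(unique(hits$qseqid)) > 1L) {
    stop("best_hit: hits span multiple queries: ",
         paste(unique(hits$qseqid), collapse = ", "))
  }
  tax_key <- suppressWarnings(as.numeric(hits$staxid))
  if (anyNA(tax_key)) tax_key <- hits$staxid
  o <- order(-hits$bitscore, -hits$pident, hits$evalue, hits$sseqid,
             tax_key, method = "radix")
  hits[o[1], , drop = FALSE]
}

cls_row <- function(qseqid, status, threshold, phylum = TAX_UNKNOWN,
                    genus = TAX_UNKNOWN, species = TAX_UNKNOWN,
                    best_pident = NA_real_) {
  data.frame(
    qseqid = qseqid, status = status, phylum = phylum, genus = genus,
    species = species, best_pident = best_pident, threshold = threshold,
    stringsAsFactors = FALSE
  )
}

#' Classify one query from its hit set
#'
#' Applies, in order: the no-hit check; the ambiguity-discard rule (hits
#' with identity strictly above `ambiguity_floor` spanning more than one
#' phylum, superkingdom or kingdom); the identity threshold (inclusive,
#' against the best hit); and lineage resolution of the best hit (a
#' sentinel phylum yields status `unresolvable` rather than silently
#' joining `no_hit`).
#'
#' @param hits hit-table data frame for one query (0 rows allowed).
#' @param store a [lineage_store()].
#' @param threshold identity threshold in \[0,100\]; a query is classified
#'   when its best hit's `pident >= threshold`.
#' @param ambiguity_floor strict identity floor for the ambiguity rule
#'   (default 80). Decoupled from `threshold` by design.
#' @param qseqid query id, required when `hits` has no rows.
#' @return One-row classification data frame with columns `qseqid`,
#'   `status`, `phylum`, `genus`, `species`, `best_pident`, `threshold`.
#' @export
classify_query <- function(hits, store, threshold, ambiguity_floor = 80,
                           qseqid = NULL) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100) {
    stop("classify_query: threshold must be in [0,100]")
  }
  if (!nrow(hits)) {
    if (is.null(qseqid)) {
      stop("classify_query: empty hit set needs an explicit qseqid")
    }
    return(cls_row(qseqid, "no_hit", threshold))
  }
  qid <- hits$qseqid[1]
  ambiguous <- any(vapply(
    c("phylum", "superkingdom", "kingdom"),
    function(r) {
      length(distinct_labels_at_rank(store, hits, r, ambiguity_floor)) > 1L
    },
    logical(1)
  ))
  bh <- best_hit(hits)
  if (ambiguous) {
    return(cls_row(qid, "ambiguous", threshold, best_pident = bh$pident))
  }
  if (bh$pident < threshold) {
    return(cls_row(qid, "below_threshold", threshold,
                   best_pident = bh$pident))
  }
  lin <- resolve(store, bh$staxid)
  if (lin$phylum == TAX_UNKNOWN) {
    return(cls_row(qid, "unresolvable", threshold, best_pident = bh$pident))
  }
  cls_row(qid, "classified", threshold, phylum = lin$phylum,
          genus = lin$genus, species = lin$species, best_pident = bh$pident)
}

#' Classify every query in a hit table
#'
#' Splits the hit table by `qseqid` and applies [classify_query()]. Queries
#' listed in `queries` but absent from the table (reads with no alignment
#' at all) are reported as `no_hit`, so the output always partitions the
#' query universe.
#'
#' @param hits hit-table data frame ([read_blast_tab()] output).
#' @param store a [lineage_store()].
#' @param threshold identity threshold in \[0,100\].
#' @param queries optional character vector of query ids defining the full
#'   universe (e.g. all read ids in the FASTA submitted to alignment).
#' @param ambiguity_floor strict identity floor for the ambiguity rule.
#' @return Classification data frame, one row per query. Queries appear in
#'   `queries` order (when given) followed by any extra table queries.
#' @export
classify_table <- function(hits, store, threshold, queries = NULL,
                           ambiguity_floor = 80) {
  in_table <- unique(hits$qseqid)
  qids <- if (is.null(queries)) in_table else {
    c(queries, setdiff(in_table, queries))
  }
  if (anyDuplicated(qids)) {
    stop("classify_table: duplicate query ids in 'queries'")
  }
  if (!length(qids)) {
    return(data.frame(
      qseqid = character(0), status = character(0), phylum = character(0),
      genus = character(0), species = character(0),
      best_pident = numeric(0), threshold = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  by_q <- split(seq_len(nrow(hits)),
                factor(hits$qseqid, levels = qids))
  out <- lapply(qids, function(q) {
    classify_query(hits[by_q[[q]], , drop = FALSE], store, threshold,
                   ambiguity_floor, qseqid = q)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Threshold sweep over a hit table
#'
#' Classifies every query at each identity threshold and tabulates
#' per-phylum classified counts plus totals of each non-classified status.
#' Only the classified/below-threshold boundary moves with the threshold;
#' the ambiguity floor stays fixed, so the ambiguous set is
#' threshold-invariant. At every threshold the counts satisfy the
#' bookkeeping identity: classified + ambiguous + below_threshold +
#' no_hit + unresolvable = number of queries.
#'
#' @param hits hit-table data frame.
#' @param store a [lineage_store()].
#' @param thresholds strictly increasing identity thresholds in \[0,100\]
#'   (default `c(70, 80, 85, 90, 95, 97)`).
#' @param queries optional full query universe (see [classify_table()]).
#' @param ambiguity_floor strict identity floor for the ambiguity rule.
#' @return A `rad_sweep` list: `thresholds`; `phyla` (observed classified
#'   phyla, sorted); `counts` (thresholds x phyla integer matrix);
#'   `status_totals` (thresholds x statuses matrix); `n_queries`;
#'   `base` (the threshold-0 classification the sweep is derived from).
#' @export
sweep_thresholds <- function(hits, store, thresholds = DEFAULT_THRESHOLDS,
                             queries = NULL, ambiguity_floor = 80) {
  if (length(thresholds) < 1L ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("sweep_thresholds: thresholds must be strictly increasing")
  }
  if (any(thresholds < 0 | thresholds > 100)) {
    stop("sweep_thresholds: thresholds must lie in [0,100]")
  }
  # Classify once with threshold 0 (nothing can fall below it), then derive
  # each threshold's statuses: only classified/unresolvable queries whose
  # best identity drops under t are re-labelled below_threshold.
  base <- classify_table(hits, store, threshold = 0, queries = queries,
                         ambiguity_floor = ambiguity_floor)
  phyla <- sort(unique(base$phylum[base$status == "classified"]),
                method = "radix")
  counts <- matrix(
    0L, nrow = length(thresholds), ncol = length(phyla),
    dimnames = list(threshold = as.character(thresholds), phylum = phyla)
  )
  status_totals <- matrix(
    0L, nrow = length(thresholds), ncol = length(CLASSIFY_STATUSES),
    dimnames = list(threshold = as.character(thresholds),
                    status = CLASSIFY_STATUSES)
  )
  movable <- base$status %in% c("classified", "unresolvable")
  for (i in seq_along(thresholds)) {
    st <- base$status
    st[movable & base$best_pident < thresholds[i]] <- "below_threshold"
    tab <- table(factor(base$phylum[st == "classified"], levels = phyla))
    counts[i, ] <- as.integer(tab)
    status_totals[i, ] <- as.integer(
      table(factor(st, levels = CLASSIFY_STATUSES))
    )
  }
  structure(
    list(thresholds = thresholds, phyla = phyla, counts = counts,
         status_totals = status_totals, n_queries = nrow(base),
         ambiguity_floor = ambiguity_floor, base = base),
    class = "rad_sweep"
  )
}

#' Long-format view of a threshold sweep
#'
#' @param x a `rad_sweep` object.
#' @param ... unused.
#' @return Data frame with columns `threshold`, `phylum`, `count`
#'   (|thresholds| x |phyla| rows).
#' @export
as.data.frame.rad_sweep <- function(x, ...) {
  if (!length(x$phyla)) {
    return(data.frame(threshold = numeric(0), phylum = character(0),
                      count = integer(0)))
  }
  data.frame(
    threshold = rep(x$thresholds, each = length(x$phyla)),
    phylum = rep(x$phyla, times = length(x$thresholds)),
    count = as.integer(t(x$counts)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.rad_sweep <- function(x, ...) {
  cat("Threshold sweep over", x$n_queries, "queries",
      sprintf("(ambiguity floor %g%%)\n", x$ambiguity_floor))
  print(cbind(x$counts, x$status_totals[, c("ambiguous", "below_threshold",
                                            "no_hit", "unresolvable"),
                                        drop = FALSE]))
  invisible(x)
}

#' Write a per-query classification table as TSV
#'
#' @param classifications data frame from [classify_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_classifications <- function(classifications, path) {
  write.table(classifications, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a per-query classification TSV
#'
#' @param path path written by [write_classifications()].
#' @return Classification data frame.
#' @export
read_classifications <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(best_pident = "numeric"))
  need <- c("qseqid", "status", "phylum", "genus", "species",
            "best_pident", "threshold")
  if (!all(need %in% names(df))) {
    stop("classification table '", path, "' is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- setdiff(unique(df$status), CLASSIFY_STATUSES)
  if (length(bad)) {
    stop("classification table '", path, "' has unknown status value(s): ",
         paste(bad, collapse = ", "))
  }
  df
}
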