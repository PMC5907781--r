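# Community summaries: per-sample phylum count tables, cross-host shared
# presence/absence matrices, and genus-level community matrices (the input
# to rarefaction).

#' Construct a community matrix
#'
#' Samples x taxa table of non-negative integer counts with unique row and
#' column labels.
#'
#' @param counts integer matrix; rownames are sample ids, colnames taxon
#'   labels.
#' @return A `community_matrix` (integer matrix subclass).
#' @export
community_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("community_matrix: a matrix is required")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("community_matrix: row (sample) and column (taxon) names required")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("community_matrix: duplicate sample or taxon labels")
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != as.integer(counts))) {
    stop("community_matrix: cells must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("community_matrix", "matrix", "array"))
}

check_one_threshold <- function(classifications, what) {
  thr <- unique(classifications$threshold)
  if (length(thr) > 1L) {
    stop(what, ": classifications mix thresholds (",
         paste(thr, collapse = ", "), ")")
  }
  thr
}

#' Per-sample phylum count table
#'
#' One row per sample; one column per phylum of interest holding the number
#' of that sample's queries classified to the phylum at the (single, shared)
#' threshold; a final `Total` column with the sample's total query count,
#' classified or not. Classified phyla outside `phyla` contribute to
#' `Total` only.
#'
#' @param classifications classification data frame carrying a `sample`
#'   column in addition to the [classify_table()] columns; all rows must
#'   share one threshold.
#' @param phyla phylum columns to report (default [PHYLA_OF_INTEREST]).
#' @return A [community_matrix()], samples in first-appearance order, with
#'   the threshold attached as attribute `threshold`.
#' @export
phylum_count_table <- function(classifications,
                               phyla = PHYLA_OF_INTEREST) {
  if (!"sample" %in% names(classifications)) {
    stop("phylum_count_table: classifications need a 'sample' column")
  }
  thr <- check_one_threshold(classifications, "phylum_count_table")
  samples <- unique(classifications$sample)
  sf <- factor(classifications$sample, levels = samples)
  cl <- classifications$status == "classified"
  m <- table(
    sf[cl],
    factor(classifications$phylum[cl], levels = phyla)
  )
  counts <- matrix(as.integer(m), nrow = length(samples),
                   dimnames = list(samples, phyla))
  total <- as.integer(table(sf))
  out <- community_matrix(cbind(counts, Total = total))
  attr(out, "threshold") <- thr
  out
}

#' Cross-host shared-sequence presence/absence matrix
#'
#' Rows are across-sample loci classified to a metagenomic (non-host)
#' phylum; columns are samples; a cell is `TRUE` when any member of the
#' locus came from that sample. Loci present in fewer than `min_samples`
#' samples are dropped (default 2: sequences with two or more host
#' representatives). Each retained row carries its phylum label.
#'
#' @param loci a `rad_loci` list ([read_loci()]).
#' @param classifications classification data frame whose `qseqid` values
#'   are locus representative ids (`locus_<id>`).
#' @param samples character vector of all sample ids (column order). A
#'   locus member naming a sample outside this list is an error.
#' @param min_samples minimum number of distinct samples a locus must be
#'   present in (default 2).
#' @param min_members minimum number of member sequences per locus
#'   (default 1; exposed because "two or more representatives" can be read
#'   either way).
#' @param host_phylum the host phylum excluded from "metagenomic"
#'   (default "Chordata").
#' @return A `presence_matrix` list: `presence` (logical loci x samples
#'   matrix) and `phylum` (named character vector, one label per row).
#' @export
shared_presence_matrix <- function(loci, classifications, samples,
                                   min_samples = 2L, min_members = 1L,
                                   host_phylum = "Chordata") {
  if (anyDuplicated(samples)) {
    stop("shared_presence_matrix: duplicate sample ids")
  }
  ids <- vapply(loci, function(l) paste0("locus_", l$locus_id), character(1))
  row_i <- match(ids, classifications$qseqid)
  keep <- !is.na(row_i) &
    classifications$status[row_i] == "classified" &
    !(classifications$phylum[row_i] %in% host_phylum)
  empty <- function() {
    list(
      presence = matrix(logical(0), nrow = 0, ncol = length(samples),
                        dimnames = list(NULL, samples)),
      phylum = setNames(character(0), character(0))
    )
  }
  if (!any(keep)) return(structure(empty(), class = "presence_matrix"))
  kept <- which(keep)
  pres <- t(vapply(kept, function(i) {
    ms <- loci[[i]]$members$sample_id
    unknown <- setdiff(ms, samples)
    if (length(unknown)) {
      stop("shared_presence_matrix: locus ", ids[i],
           " names unknown sample '", unknown[1], "'")
    }
    samples %in% ms
  }, logical(length(samples))))
  colnames(pres) <- samples
  rownames(pres) <- ids[kept]
  phylum <- setNames(classifications$phylum[row_i[kept]], ids[kept])
  n_mem <- vapply(loci[kept], function(l) nrow(l$members), integer(1))
  ok <- rowSums(pres) >= min_samples & n_mem >= min_members
  structure(
    list(presence = pres[ok, , drop = FALSE], phylum = phylum[ok]),
    class = "presence_matrix"
  )
}

#' Write a presence/absence matrix as CSV
#'
#' Columns: `locus`, `phylum`, then one 0/1 column per sample.
#'
#' @param pm a `presence_matrix` ([shared_presence_matrix()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_presence_matrix <- function(pm, path) {
  df <- data.frame(
    locus = rownames(pm$presence),
    phylum = unname(pm$phylum),
    as.data.frame(pm$presence * 1L),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Genus-level community matrix
#'
#' One row per sample. A single column for the host phylum (all its
#' classified queries lumped), plus one column per genus among queries
#' classified to the parasite phyla. Parasite queries whose genus is the
#' sentinel pool into a `<phylum>_unassigned` column instead of being
#' dropped, so parasite column sums equal the number of
#' parasite-phylum-classified queries exactly.
#'
#' @param classifications classification data frame with a `sample` column;
#'   all rows must share one threshold, which must equal `threshold`.
#' @param threshold the identity threshold the classifications were
#'   computed at (default 90, the community-analysis setting).
#' @param parasite_phyla phyla treated as parasites (default
#'   [PARASITE_PHYLA]).
#' @param host_phylum label of the lumped host column (default "Chordata").
#' @return A [community_matrix()].
#' @export
genus_community_matrix <- function(classifications, threshold = 90,
                                   parasite_phyla = PARASITE_PHYLA,
                                   host_phylum = "Chordata") {
  if (!"sample" %in% names(classifications)) {
    stop("genus_community_matrix: classifications need a 'sample' column")
  }
  thr <- check_one_threshold(classifications, "genus_community_matrix")
  if (length(thr) && !isTRUE(all.equal(thr, threshold))) {
    stop("genus_community_matrix: classifications were computed at ",
         "threshold ", thr, ", not the requested ", threshold)
  }
  samples <- unique(classifications$sample)
  cl <- classifications[classifications$status == "classified", ,
                        drop = FALSE]
  host <- cl$phylum == host_phylum
  para <- cl$phylum %in% parasite_phyla
  label <- character(nrow(cl))
  label[host] <- host_phylum
  label[para] <- ifelse(
    cl$genus[para] == TAX_UNKNOWN,
    paste0(cl$phylum[para], "_unassigned"),
    cl$genus[para]
  )
  keep <- host | para
  genus_cols <- sort(setdiff(unique(label[keep]), host_phylum),
                     method = "radix")
  cols <- c(host_phylum, genus_cols)
  m <- table(
    factor(cl$sample[keep], levels = samples),
    factor(label[keep], levels = cols)
  )
  out <- community_matrix(
    matrix(as.integer(m), nrow = length(samples),
           dimnames = list(samples, cols))
  )
  attr(out, "threshold") <- threshold
  out
}
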