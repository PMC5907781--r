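# Individual-based rarefaction: expected taxon richness in a random
# subsample of n individuals drawn without replacement from a counted
# community. The classic hypergeometric expectation
#
#   E[S_n] = sum_i [ 1 - C(N - N_i, n) / C(N, n) ],   N = sum_i N_i,
#
# evaluated in log space (lchoose) so totals in the millions do not
# overflow. Exact for integer counts.

#' Expected richness of a random subsample (hypergeometric rarefaction)
#'
#' @param counts non-negative integer per-taxon counts (zeros allowed and
#'   ignored). Non-integer counts are rejected: the inputs are read counts.
#' @param n subsample size, `0 <= n <= sum(counts)`.
#' @return Expected number of distinct taxa observed, a real number in
#'   `[0, sum(counts > 0)]`.
#' @examples
#' expected_richness(c(2, 1), 2)   # 5/3
#' @export
expected_richness <- function(counts, n) {
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("expected_richness: counts must be non-negative")
  }
  if (any(counts != round(counts))) {
    stop("expected_richness: counts must be integers (read counts)")
  }
  counts <- as.numeric(counts[counts > 0])
  N <- sum(counts)
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop("expected_richness: n must be a single non-negative integer")
  }
  if (n > N) {
    stop("expected_richness: subsample size n = ", n,
         " exceeds community total N = ", N)
  }
  if (n == 0 || !length(counts)) return(0)
  # C(N - N_i, n) / C(N, n); lchoose(k, n) is -Inf when n > k, so taxa that
  # cannot be missed contribute exactly 1.
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Rarefaction curve for one sample of a community matrix
#'
#' Evaluates [expected_richness()] on the sample's row at each requested
#' depth. With `depths = NULL` an automatic grid of `n_depths` evenly
#' spaced depths from 1 to the sample total N is used. A column literally
#' named `Total` (the bookkeeping column of [phylum_count_table()]) is
#' dropped before computing.
#'
#' @param mat a [community_matrix()].
#' @param sample a sample id (row name of `mat`).
#' @param depths increasing integer subsample sizes; any depth above the
#'   sample's total is an error.
#' @param n_depths size of the automatic depth grid (default 20).
#' @return A `rarefaction_curve` data frame: `sample`, `depth`,
#'   `expected_richness`.
#' @export
rarefaction_curve <- function(mat, sample, depths = NULL, n_depths = 20L) {
  if (!sample %in% rownames(mat)) {
    stop("rarefaction_curve: sample '", sample, "' not in matrix")
  }
  counts <- mat[sample, colnames(mat) != "Total"]
  N <- sum(counts)
  if (is.null(depths)) {
    if (N < 1) {
      stop("rarefaction_curve: sample '", sample, "' has no individuals")
    }
    depths <- unique(round(seq(1, N, length.out = min(n_depths, N))))
  }
  if (any(depths > N)) {
    stop("rarefaction_curve: depth ", max(depths), " exceeds sample '",
         sample, "' total N = ", N)
  }
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("rarefaction_curve: depths must be strictly increasing")
  }
  structure(
    data.frame(
      sample = sample, depth = as.integer(depths),
      expected_richness = vapply(depths, function(d) {
        expected_richness(counts, d)
      }, numeric(1)),
      stringsAsFactors = FALSE
    ),
    class = c("rarefaction_curve", "data.frame")
  )
}

#' Rarefaction curves for every sample of a community matrix
#'
#' Samples with zero individuals are skipped with a message. Each sample
#' gets its own automatic depth grid (see [rarefaction_curve()]).
#'
#' @inheritParams rarefaction_curve
#' @return Long-format data frame: `sample`, `depth`, `expected_richness`.
#' @export
rarefaction_curves <- function(mat, depths = NULL, n_depths = 20L) {
  totals <- rowSums(mat[, colnames(mat) != "Total", drop = FALSE])
  keep <- rownames(mat)[totals > 0]
  if (length(keep) < nrow(mat)) {
    message("rarefaction_curves: skipping empty sample(s): ",
            paste(setdiff(rownames(mat), keep), collapse = ", "))
  }
  out <- do.call(rbind, lapply(keep, function(s) {
    rarefaction_curve(mat, s, depths = depths, n_depths = n_depths)
  }))
  if (is.null(out)) {
    out <- data.frame(sample = character(0), depth = integer(0),
                      expected_richness = numeric(0))
  }
  rownames(out) <- NULL
  out
}
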