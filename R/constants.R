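# Package-level constants. Kept in one file that collates first so the
# other sources can use them at load time.

#' Standard column names of the 13-column BLAST tabular dialect
#'
#' The 12 standard tabular columns (`-outfmt 6`) with a subject-taxon-id
#' column appended. No header line is expected in files.
#'
#' @export
BLAST_COLS <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore", "staxid"
)

#' The eight taxonomy ranks tracked by the package, highest first
#' @export
TAX_RANKS <- c("superkingdom", "kingdom", "phylum", "class", "order",
               "family", "genus", "species")

#' Sentinel label for an unknown rank
#' @export
TAX_UNKNOWN <- "UNKNOWN"

LINEAGE_HEADER <- c("taxid", TAX_RANKS)

#' Classification status labels, in precedence order
#' @export
CLASSIFY_STATUSES <- c("classified", "ambiguous", "below_threshold",
                       "no_hit", "unresolvable")

#' Default identity thresholds for the classification sweep (percent)
#' @export
DEFAULT_THRESHOLDS <- c(70, 80, 85, 90, 95, 97)

#' Default phyla reported in per-sample count tables
#' @export
PHYLA_OF_INTEREST <- c("Chordata", "Platyhelminthes", "Nematoda",
                       "Apicomplexa")

#' Default parasite phyla for the genus-level community matrix
#' @export
PARASITE_PHYLA <- c("Platyhelminthes", "Nematoda", "Apicomplexa")
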