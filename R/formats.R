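# File-format readers and writers for every dialect the pipeline touches:
# FASTA, pyRAD-style *.loci, BLAST tabular (outfmt-6 + staxids) TSV, lineage
# TSV, and community-matrix CSV. Parsers are deliberately strict: the
# downstream classification math assumes clean inputs, so malformed files
# fail loudly with line numbers rather than being silently repaired.

#' Construct a validated set of sequence records
#'
#' The package's sequence container: a data frame with columns `id` and
#' `sequence`. Ids must be non-empty, whitespace-free and unique; sequences
#' are uppercased and must be non-empty strings over `{A,C,G,T,N}`.
#'
#' @param id character vector of record ids.
#' @param sequence character vector of nucleotide sequences, same length.
#' @return A `seq_records` data frame with columns `id`, `sequence`.
#' @export
seq_records <- function(id = character(), sequence = character()) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("seq_records: 'id' and 'sequence' must have equal length")
  }
  if (length(id)) {
    if (any(!nzchar(id)) || any(grepl("\\s", id))) {
      stop("seq_records: ids must be non-empty and contain no whitespace")
    }
    dup <- unique(id[duplicated(id)])
    if (length(dup)) {
      stop("seq_records: duplicate sequence id(s): ",
           paste(dup, collapse = ", "))
    }
    if (any(!nzchar(sequence))) {
      stop("seq_records: zero-length sequence for id(s): ",
           paste(id[!nzchar(sequence)], collapse = ", "))
    }
    bad <- grepl("[^ACGTN]", sequence)
    if (any(bad)) {
      stop("seq_records: sequence for '", id[which(bad)[1]],
           "' contains characters outside {A,C,G,T,N}")
    }
  }
  structure(
    data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE),
    class = c("seq_records", "data.frame")
  )
}

#' Read a FASTA file
#'
#' Lines beginning `>` start records; the id is the first whitespace-delimited
#' token after `>`. Multi-line sequences are concatenated and uppercased.
#' Blank lines are ignored. A sequence line before any header is a format
#' error; an empty file yields zero records.
#'
#' @param path path to a FASTA file (plain or gzip; R connections handle
#'   gzip transparently).
#' @return A [seq_records()] data frame, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(seq_records())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("FASTA format error in '", path, "': sequence line before any header")
  }
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[is_hdr]))
  grp <- cumsum(is_hdr)
  body <- split(lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(ids)))
  seqs <- vapply(body, paste, character(1), collapse = "")
  seq_records(ids, seqs)
}

#' Write sequence records as FASTA
#'
#' One header line per record; sequences wrapped at a fixed width. Writing
#' then reading ([read_fasta()]) reproduces the input exactly. Duplicate ids
#' are an error.
#'
#' @param records a [seq_records()] data frame (or coercible: columns `id`,
#'   `sequence`).
#' @param path output path.
#' @param width line-wrap width for sequences (default 80).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 80L) {
  records <- seq_records(records$id, records$sequence)
  out <- character(0)
  if (nrow(records)) {
    chunks <- lapply(records$sequence, function(s) {
      n <- nchar(s)
      starts <- seq.int(1L, n, by = width)
      substring(s, starts, pmin(starts + width - 1L, n))
    })
    out <- unlist(
      Map(function(id, ch) c(paste0(">", id), ch), records$id, chunks),
      use.names = FALSE
    )
  }
  writeLines(out, path)
  invisible(path)
}

new_locus <- function(locus_id, sample_id, sequence) {
  sequence <- toupper(sequence)
  bad <- !nzchar(sequence) | grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("locus ", locus_id, ": member sequence for '",
         sample_id[which(bad)[1]],
         "' is empty or contains characters outside {A,C,G,T,N}")
  }
  list(
    locus_id = as.integer(locus_id),
    members = data.frame(sample_id = sample_id, sequence = sequence,
                         stringsAsFactors = FALSE)
  )
}

#' Read a pyRAD-style `*.loci` file
#'
#' Member lines are `<name><whitespace><sequence>`; a locus is terminated by
#' a separator line whose first two non-blank characters are `//`. If the
#' separator carries a trailing `|N|` tag, `N` becomes the locus id;
#' otherwise the 0-based block index is used. Alignment gap characters `-`
#' are stripped from member sequences (downstream classification operates on
#' ungapped queries). A trailing block with no separator is accepted as the
#' final locus with a warning; a separator with no members is a format error.
#'
#' @param path path to a `*.loci` file.
#' @return A `rad_loci` list; each element has `locus_id` (integer) and
#'   `members` (data frame `sample_id`, `sequence`, in file order).
#' @export
read_loci <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loci <- list()
  mem_s <- character()
  mem_q <- character()
  n_block <- 0L
  for (i in seq_along(lines)) {
    txt <- trimws(lines[i])
    if (!nzchar(txt)) next
    if (startsWith(txt, "//")) {
      if (!length(mem_s)) {
        stop("loci format error in '", path, "' at line ", i,
             ": separator with no member lines")
      }
      m <- regmatches(txt, regexec("\\|([0-9]+)\\|$", txt))[[1]]
      lid <- if (length(m) == 2L) as.integer(m[2]) else n_block
      loci[[length(loci) + 1L]] <- new_locus(lid, mem_s, mem_q)
      n_block <- n_block + 1L
      mem_s <- character()
      mem_q <- character()
    } else {
      f <- strsplit(txt, "\\s+")[[1]]
      if (length(f) != 2L) {
        stop("loci format error in '", path, "' at line ", i,
             ": expected '<name> <sequence>', found ", length(f), " field(s)")
      }
      mem_s <- c(mem_s, f[1])
      mem_q <- c(mem_q, gsub("-", "", f[2], fixed = TRUE))
    }
  }
  if (length(mem_s)) {
    warning("'", path, "': trailing locus block without '//' separator; ",
            "accepted as final locus")
    loci[[length(loci) + 1L]] <- new_locus(n_block, mem_s, mem_q)
  }
  structure(loci, class = "rad_loci")
}

#' Write loci in the `*.loci` dialect
#'
#' Emits the dialect [read_loci()] consumes (member lines, then a
#' `//  |id|` separator), so a write-then-read round trip reproduces locus
#' membership and order.
#'
#' @param loci a `rad_loci` list as returned by [read_loci()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_loci <- function(loci, path) {
  out <- unlist(lapply(loci, function(l) {
    c(sprintf("%s  %s", l$members$sample_id, l$members$sequence),
      sprintf("//  |%d|", l$locus_id))
  }), use.names = FALSE)
  writeLines(if (is.null(out)) character(0) else out, path)
  invisible(path)
}

#' Take the first sequence of each locus as its representative
#'
#' One record per locus, id `locus_<locus_id>`, sequence taken from the
#' first member in file order. This is the set of sequences submitted to
#' alignment for across-sample loci.
#'
#' @param loci a `rad_loci` list.
#' @return A [seq_records()] data frame, one row per locus.
#' @export
extract_locus_representatives <- function(loci) {
  if (!length(loci)) return(seq_records())
  seq_records(
    id = vapply(loci, function(l) paste0("locus_", l$locus_id), character(1)),
    sequence = vapply(loci, function(l) l$members$sequence[1], character(1))
  )
}

empty_hits <- function() {
  data.frame(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    staxid = character(), stringsAsFactors = FALSE
  )
}

#' Read a 13-column BLAST tabular hit table
#'
#' Expects tab-separated rows with the 12 standard tabular columns plus a
#' trailing subject-taxon-id column ([BLAST_COLS]), no header. A `staxids`
#' cell containing `;`-separated ids is split into one hit row per id,
#' duplicating the row's other fields. Malformed rows (wrong column count,
#' unparseable numbers, identity outside \[0,100\], `qstart > qend`) raise a
#' format error naming the line number.
#'
#' @param path path to the TSV.
#' @return A data frame with columns [BLAST_COLS] (`staxid` singular after
#'   splitting), rows in file order.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 13L)) {
    i <- which(nf != 13L)[1]
    stop("hit-table format error in '", path, "' at line ", lineno[i],
         ": expected 13 tab-separated columns, found ", nf[i])
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 13L, byrow = TRUE)
  num <- function(col, name, as_int = FALSE) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      i <- which(is.na(x))[1]
      stop("hit-table format error in '", path, "' at line ", lineno[i],
           ": unparseable ", name, " '", m[i, col], "'")
    }
    if (as_int) as.integer(x) else x
  }
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num(3, "pident"),
    length = num(4, "length", TRUE), mismatch = num(5, "mismatch", TRUE),
    gapopen = num(6, "gapopen", TRUE),
    qstart = num(7, "qstart", TRUE), qend = num(8, "qend", TRUE),
    sstart = num(9, "sstart", TRUE), send = num(10, "send", TRUE),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    staxid = m[, 13], stringsAsFactors = FALSE
  )
  bad <- hits$pident < 0 | hits$pident > 100
  if (any(bad)) {
    stop("hit-table format error in '", path, "' at line ",
         lineno[which(bad)[1]], ": pident outside [0,100]")
  }
  bad <- hits$qstart > hits$qend
  if (any(bad)) {
    stop("hit-table format error in '", path, "' at line ",
         lineno[which(bad)[1]], ": qstart > qend")
  }
  tax <- strsplit(hits$staxid, ";", fixed = TRUE)
  reps <- lengths(tax)
  if (any(reps == 0L)) {
    stop("hit-table format error in '", path, "' at line ",
         lineno[which(reps == 0L)[1]], ": empty staxids cell")
  }
  hits <- hits[rep.int(seq_len(nrow(hits)), reps), , drop = FALSE]
  hits$staxid <- trimws(unlist(tax, use.names = FALSE))
  rownames(hits) <- NULL
  hits
}

#' Write a hit table in the 13-column tabular dialect
#'
#' Counterpart of [read_blast_tab()], used by the simulator. Numeric fields
#' are formatted deterministically (`pident` to 4 decimals, `bitscore` to 1,
#' `evalue` in scientific notation).
#'
#' @param hits data frame with columns [BLAST_COLS].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(BLAST_COLS %in% names(hits)))
  out <- sprintf(
    "%s\t%s\t%.4f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f\t%s",
    hits$qseqid, hits$sseqid, hits$pident, hits$length, hits$mismatch,
    hits$gapopen, hits$qstart, hits$qend, hits$sstart, hits$send,
    hits$evalue, hits$bitscore, hits$staxid
  )
  writeLines(out, path)
  invisible(path)
}

#' Read an offline taxonomy lineage table
#'
#' Tab-separated with the mandatory header
#' `taxid superkingdom kingdom phylum class order family genus species`.
#' Empty cells mean "rank unknown" and become the sentinel
#' [TAX_UNKNOWN]. Duplicate taxid rows: last wins, with a warning.
#'
#' @param path path to the lineage TSV.
#' @return A [lineage_store()].
#' @export
read_lineage_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("lineage table format error in '", path, "': missing header")
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), LINEAGE_HEADER)) {
    stop("lineage table format error in '", path,
         "': missing or malformed header (expected '",
         paste(LINEAGE_HEADER, collapse = "\\t"), "')")
  }
  body <- lines[-1]
  if (!length(body)) return(lineage_store())
  parts <- lapply(strsplit(body, "\t", fixed = TRUE), function(f) {
    length(f) <- 9L          # pad dropped trailing empties
    f[is.na(f)] <- ""
    f
  })
  nf <- lengths(parts)
  if (any(nf > 9L)) {
    stop("lineage table format error in '", path, "' at line ",
         which(nf > 9L)[1] + 1L, ": more than 9 columns")
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 9L, byrow = TRUE)
  m[!nzchar(m)] <- TAX_UNKNOWN
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- LINEAGE_HEADER
  dup <- duplicated(df$taxid, fromLast = TRUE)
  if (any(dup)) {
    warning("lineage table '", path, "': duplicate taxid(s) ",
            paste(unique(df$taxid[dup]), collapse = ", "),
            "; keeping the last occurrence")
    df <- df[!dup, , drop = FALSE]
  }
  lineage_store(df)
}

#' Write a lineage store as a lineage TSV
#'
#' @param store a [lineage_store()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_lineage_table <- function(store, path) {
  df <- as.data.frame(store)
  out <- c(paste(LINEAGE_HEADER, collapse = "\t"),
           do.call(paste, c(unname(df[LINEAGE_HEADER]), sep = "\t")))
  writeLines(out, path)
  invisible(path)
}

#' Write a community matrix as CSV
#'
#' First column `sample` (row names of the matrix), remaining columns the
#' taxon labels, integer cells.
#'
#' @param mat a [community_matrix()] (samples x taxa integer matrix).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_community_matrix <- function(mat, path) {
  df <- data.frame(sample = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a community matrix CSV
#'
#' @param path path written by [write_community_matrix()] (first column
#'   `sample`).
#' @return A [community_matrix()].
#' @export
read_community_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df) || names(df)[1] != "sample") {
    stop("community matrix format error in '", path,
         "': first column must be 'sample'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  storage.mode(m) <- "integer"
  community_matrix(m)
}
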