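# In-silico ddRAD simulator: random genomes, double restriction digest,
# size selection, mutated reads and truth-labelled hit tables. Emulates the
# wet-lab parameters of a typical EcoRI/MspI ddRAD library (200-300 bp
# inserts, 125 bp reads) so every downstream module can be exercised with
# planted truth and no external data.
#
# All simulator coordinates are 0-based half-open; only the synthetic hit
# table (an alignment artifact) uses 1-based inclusive coordinates.

#' Define a restriction enzyme
#'
#' @param name enzyme name (used as a fragment end label).
#' @param recognition recognition site over `{A,C,G,T}`, top strand.
#' @param cut_offset cut position measured from the recognition-site start
#'   on the top strand, in `[0, nchar(recognition)]`.
#' @return An `enzyme` list. Non-palindromic recognition sites are accepted
#'   but reported via `message()` (the top-strand-only scan then misses
#'   bottom-strand sites).
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(name) || grepl("\\s", name)) {
    stop("enzyme: name must be non-empty without whitespace")
  }
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition)) {
    stop("enzyme: recognition site must be a non-empty string over {A,C,G,T}")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L ||
      cut_offset > nchar(recognition)) {
    stop("enzyme: cut_offset must lie in [0, ", nchar(recognition), "]")
  }
  if (recognition != revcomp(recognition)) {
    message("enzyme ", name, ": recognition site ", recognition,
            " is not palindromic; only top-strand sites will be cut")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The default ddRAD enzyme pair: EcoRI (G^AATTC) and MspI (C^CGG)
#'
#' @return Named list of two [enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(EcoRI = enzyme("EcoRI", "GAATTC", 1L),
       MspI = enzyme("MspI", "CCGG", 1L))
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with the stated expected GC fraction (C and G equiprobable,
#' likewise A and T). Deterministic for a fixed seed.
#'
#' @param length genome length (>= 1).
#' @param gc_fraction expected GC proportion in \[0,1\] (default 0.5).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param id record id (default "genome").
#' @return A one-row [seq_records()].
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                          id = "genome") {
  if (length < 1 || length != round(length)) {
    stop("random_genome: length must be a positive integer")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("random_genome: gc_fraction must lie in [0,1]")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq_records(id, paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""))
}

# 0-based start positions of all (possibly overlapping) occurrences of
# `pattern` in the character vector `chars`.
find_sites <- function(chars, pattern) {
  k <- nchar(pattern)
  L <- length(chars)
  if (L < k) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  n <- L - k + 1L
  ok <- chars[seq_len(n)] == pc[1]
  for (j in seq_len(k - 1L)) {
    ok <- ok & chars[seq_len(n) + j] == pc[j + 1L]
  }
  which(ok) - 1L
}

#' In-silico restriction digest
#'
#' Finds every top-strand occurrence of each enzyme's recognition site
#' (overlapping occurrences included), cuts at `site_start + cut_offset`,
#' and returns the fragments between consecutive cut positions including
#' both genome termini. Fragment ends are labelled with the cutting
#' enzyme's name, or `"terminus"` at the genome ends. Fragments tile the
#' genome exactly. If two enzymes cut at the same coordinate the label of
#' the enzyme listed first is used (impossible with the default pair).
#'
#' @param genome a one-row [seq_records()] (or any list/data frame with
#'   `id` and `sequence` of length 1).
#' @param enzymes non-empty list of [enzyme()] objects (default
#'   [default_enzymes()]).
#' @return A `rad_fragments` data frame: `source_id`, `start`, `end`
#'   (0-based half-open), `length`, `left_end`, `right_end`, `sequence`.
#' @export
digest <- function(genome, enzymes = default_enzymes()) {
  if (!length(enzymes)) stop("digest: at least one enzyme is required")
  sq <- as.character(genome$sequence[1])
  src <- as.character(genome$id[1])
  chars <- strsplit(sq, "")[[1]]
  L <- length(chars)
  cuts <- integer(0)
  labs <- character(0)
  for (e in enzymes) {
    pos <- find_sites(chars, e$recognition) + e$cut_offset
    cuts <- c(cuts, pos)
    labs <- c(labs, rep(e$name, length(pos)))
  }
  # interior cuts only; a cut at 0 or L yields an empty fragment
  keep <- cuts > 0L & cuts < L
  cuts <- cuts[keep]
  labs <- labs[keep]
  o <- order(cuts)
  cuts <- cuts[o]
  labs <- labs[o]
  first <- !duplicated(cuts)
  cuts <- cuts[first]
  labs <- labs[first]
  bounds <- c(0L, cuts, L)
  blabs <- c("terminus", labs, "terminus")
  n <- length(bounds) - 1L
  start <- bounds[seq_len(n)]
  end <- bounds[seq_len(n) + 1L]
  structure(
    data.frame(
      source_id = src, start = start, end = end, length = end - start,
      left_end = blabs[seq_len(n)], right_end = blabs[seq_len(n) + 1L],
      sequence = substring(sq, start + 1L, end),
      stringsAsFactors = FALSE
    ),
    class = c("rad_fragments", "data.frame")
  )
}

#' ddRAD size selection and end-composition filter
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (inclusive at
#' both ends) and whose two end labels are exactly one of each required
#' enzyme, in either orientation — the fragments that receive both adapters
#' in a standard ddRAD library. Fragments touching a genome terminus never
#' pass.
#'
#' @param fragments a `rad_fragments` data frame ([digest()]).
#' @param min_len,max_len inclusive insert-size window (defaults 200, 300).
#' @param require_ends character vector of the two enzyme names required at
#'   the fragment ends (default `c("EcoRI", "MspI")`).
#' @return The selected subset of `fragments`.
#' @export
ddrad_select <- function(fragments, min_len = 200L, max_len = 300L,
                         require_ends = c("EcoRI", "MspI")) {
  if (length(require_ends) != 2L) {
    stop("ddrad_select: require_ends must name exactly two enzyme ends")
  }
  want <- paste(sort(require_ends), collapse = "/")
  got <- vapply(seq_len(nrow(fragments)), function(i) {
    paste(sort(c(fragments$left_end[i], fragments$right_end[i])),
          collapse = "/")
  }, character(1))
  keep <- fragments$length >= min_len & fragments$length <= max_len &
    got == want &
    fragments$left_end != "terminus" & fragments$right_end != "terminus"
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit single-end reads from selected fragments
#'
#' One read per fragment: the first `min(read_len, fragment length)` bases,
#' with i.i.d. substitutions at `sub_rate` (uniform over the three
#' alternative bases, never to the same base). Deterministic for a fixed
#' seed. Paired-end bookkeeping is deliberately omitted: the pipeline
#' classifies individual sequences.
#'
#' @param fragments a `rad_fragments` data frame with a `sequence` column.
#' @param read_len read length (default 125).
#' @param sub_rate per-base substitution probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @param id_prefix prefix prepended to read ids (e.g. `"sampleA__"`).
#' @return List with `reads` (a [seq_records()]) and `truth` (data frame
#'   `read_id`, `source_id`, `fragment_start`, `mutations`, `read_len`).
#' @export
emit_reads <- function(fragments, read_len = 125L, sub_rate = 0,
                       seed = NULL, id_prefix = "") {
  if (sub_rate < 0 || sub_rate >= 0.5) {
    stop("emit_reads: sub_rate must lie in [0, 0.5)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fragments)
  if (!n) {
    return(list(
      reads = seq_records(),
      truth = data.frame(read_id = character(0), source_id = character(0),
                         fragment_start = integer(0), mutations = integer(0),
                         read_len = integer(0), stringsAsFactors = FALSE)
    ))
  }
  idx <- stats::ave(seq_len(n), fragments$source_id, FUN = seq_along)
  read_id <- sprintf("%s%s_f%03d", id_prefix, fragments$source_id, idx)
  seqs <- character(n)
  muts <- integer(n)
  for (i in seq_len(n)) {
    s <- substr(fragments$sequence[i], 1L,
                min(read_len, fragments$length[i]))
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < sub_rate)
    for (j in hit) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
    muts[i] <- length(hit)
  }
  list(
    reads = seq_records(read_id, seqs),
    truth = data.frame(
      read_id = read_id, source_id = fragments$source_id,
      fragment_start = fragments$start, mutations = muts,
      read_len = nchar(seqs), stringsAsFactors = FALSE
    )
  )
}

#' Build a synthetic 13-column hit table from truth records
#'
#' For each read, one "true" hit against its source reference with
#' `pident = 100 * (1 - mutations / read length)`, plus optional decoy hits
#' at configured identities to exercise the ambiguity-discard rule.
#' Bitscore is monotone in `pident * length` by construction
#' (`2 * length * pident / 100`), so a decoy outranks the true hit only if
#' its identity is higher. Coordinates are 1-based inclusive, per the
#' alignment convention.
#'
#' @param truth truth data frame ([emit_reads()]).
#' @param ref_taxa data frame mapping `source_id` to `taxid`; every truth
#'   source must be present.
#' @param decoys optional data frame with columns `read_id`, `taxid`,
#'   `pident` (one decoy hit per row; `sseqid` defaults to
#'   `decoy_<taxid>`).
#' @return Hit-table data frame with columns [BLAST_COLS].
#' @export
synth_hit_table <- function(truth, ref_taxa, decoys = NULL) {
  i <- match(truth$source_id, ref_taxa$source_id)
  if (anyNA(i)) {
    stop("synth_hit_table: source(s) missing from ref_taxa: ",
         paste(unique(truth$source_id[is.na(i)]), collapse = ", "))
  }
  mk <- function(qseqid, sseqid, len, mismatch, sstart, staxid) {
    pident <- 100 * (1 - mismatch / len)
    bitscore <- round(2 * len * pident / 100, 1)
    data.frame(
      qseqid = qseqid, sseqid = sseqid, pident = pident,
      length = as.integer(len), mismatch = as.integer(mismatch),
      gapopen = 0L, qstart = 1L, qend = as.integer(len),
      sstart = as.integer(sstart), send = as.integer(sstart + len - 1L),
      evalue = 10^(-bitscore / 10), bitscore = bitscore,
      staxid = as.character(staxid), stringsAsFactors = FALSE
    )
  }
  hits <- mk(truth$read_id, truth$source_id, truth$read_len,
             truth$mutations, truth$fragment_start + 1L,
             ref_taxa$taxid[i])
  if (!is.null(decoys) && nrow(decoys)) {
    j <- match(decoys$read_id, truth$read_id)
    if (anyNA(j)) {
      stop("synth_hit_table: decoy read id(s) not in truth: ",
           paste(unique(decoys$read_id[is.na(j)]), collapse = ", "))
    }
    len <- truth$read_len[j]
    mm <- round(len * (1 - decoys$pident / 100))
    sseqid <- if (is.null(decoys$sseqid)) {
      paste0("decoy_", decoys$taxid)
    } else {
      decoys$sseqid
    }
    hits <- rbind(hits, mk(decoys$read_id, sseqid, len, mm, 1L,
                           decoys$taxid))
  }
  if (!nrow(hits)) return(empty_hits())
  hits <- hits[order(hits$qseqid, -hits$bitscore, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Planted taxa of the default simulation
#'
#' One host (Chordata) and three blood-parasite genomes (Platyhelminthes,
#' Nematoda, Apicomplexa) with plausible full lineages. The Apicomplexa
#' kingdom is left unknown, mirroring reference taxonomies that only split
#' eukaryote kingdoms for some groups.
#'
#' @return Data frame with `source_id`, `taxid`, the eight [TAX_RANKS], and
#'   `genome_role` ("host" or "parasite").
#' @export
default_sim_taxa <- function() {
  data.frame(
    source_id = c("host", "flatworm", "roundworm", "apicomplexan"),
    taxid = c("90001", "90002", "90003", "90004"),
    superkingdom = "Eukaryota",
    kingdom = c("Metazoa", "Metazoa", "Metazoa", ""),
    phylum = c("Chordata", "Platyhelminthes", "Nematoda", "Apicomplexa"),
    class = c("Lepidosauria", "Monogenea", "Chromadorea", "Aconoidasida"),
    order = c("Squamata", "Polystomatidea", "Rhabditida", "Haemosporida"),
    family = c("Phrynosomatidae", "Polystomatidae", "Strongyloididae",
               "Plasmodiidae"),
    genus = c("Phrynosoma", "Protopolystoma", "Strongyloides",
              "Plasmodium"),
    species = c("Phrynosoma modestum", "Protopolystoma xenopodis",
                "Strongyloides stercoralis", "Plasmodium mexicanum"),
    genome_role = c("host", "parasite", "parasite", "parasite"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete truth-labelled ddRAD bycatch dataset
#'
#' Generates one host and several parasite genomes, digests them with the
#' enzyme pair, size-selects inserts, assigns parasites to samples, emits
#' mutated reads per sample, and builds the matching hit table, lineage
#' table, across-sample loci and locus-representative hit table. Everything
#' is reproducible bit-for-bit from `seed`.
#'
#' Defaults emulate a small ddRAD experiment: 3 samples, a 300 kb host
#' genome and 100 kb parasite genomes (scaled so the digest yields tens of
#' in-window host fragments and a handful per parasite), GC 0.45, Illumina
#' 125 bp reads at a 1% substitution rate, each parasite infecting a sample
#' with probability 0.8, and each available fragment recovered in a sample
#' with probability 0.9 (allelic dropout).
#'
#' @param n_samples number of host samples (default 3).
#' @param host_length,parasite_length genome lengths in bp.
#' @param gc_fraction expected GC content of all genomes.
#' @param sub_rate per-base read substitution rate in `[0, 0.5)`.
#' @param read_len read length (default 125).
#' @param min_len,max_len inclusive size-selection window (200, 300).
#' @param presence_prob probability a parasite is present in a sample.
#' @param recovery_prob probability a selected fragment of a present genome
#'   is recovered as a read in a sample.
#' @param seed integer seed driving every random choice.
#' @param decoys optional decoy-hit data frame (see [synth_hit_table()]);
#'   decoy `read_id`s must exist in the simulated truth.
#' @param enzymes enzyme list (default [default_enzymes()]).
#' @param taxa planted taxa (default [default_sim_taxa()]); must contain
#'   exactly one `genome_role == "host"` row.
#' @return A `rad_simulation` list: `taxa`, `genomes`, `fragments`
#'   (selected, all sources), `samples`, `reads`, `truth` (read-level, with
#'   sample and lineage), `hits`, `lineage` (a [lineage_store()]), `loci`
#'   (`rad_loci` across samples), `locus_truth`, `locus_hits`, and the
#'   `params` used.
#' @export
simulate_dataset <- function(n_samples = 3L, host_length = 3e5L,
                             parasite_length = 1e5L, gc_fraction = 0.45,
                             sub_rate = 0.01, read_len = 125L,
                             min_len = 200L, max_len = 300L,
                             presence_prob = 0.8, recovery_prob = 0.9,
                             seed = NULL, decoys = NULL,
                             enzymes = default_enzymes(),
                             taxa = default_sim_taxa()) {
  if (sum(taxa$genome_role == "host") != 1L) {
    stop("simulate_dataset: taxa must contain exactly one host row")
  }
  if (!is.null(seed)) set.seed(seed)
  params <- list(
    n_samples = n_samples, host_length = host_length,
    parasite_length = parasite_length, gc_fraction = gc_fraction,
    sub_rate = sub_rate, read_len = read_len, min_len = min_len,
    max_len = max_len, presence_prob = presence_prob,
    recovery_prob = recovery_prob, seed = seed
  )
  glen <- ifelse(taxa$genome_role == "host", host_length, parasite_length)
  genomes <- do.call(rbind, lapply(seq_len(nrow(taxa)), function(i) {
    random_genome(glen[i], gc_fraction, id = taxa$source_id[i])
  }))
  frags <- do.call(rbind, lapply(seq_len(nrow(genomes)), function(i) {
    ddrad_select(digest(genomes[i, , drop = FALSE], enzymes),
                 min_len, max_len, names(enzymes))
  }))
  rownames(frags) <- NULL
  samples <- sprintf("sample%02d", seq_len(n_samples))
  # infection matrix: host always present, parasites Bernoulli
  present <- matrix(
    TRUE, nrow = n_samples, ncol = nrow(taxa),
    dimnames = list(samples, taxa$source_id)
  )
  para <- taxa$genome_role == "parasite"
  present[, para] <- rbinom(n_samples * sum(para), 1L,
                            presence_prob) == 1L
  reads <- NULL
  truth <- NULL
  frag_members <- vector("list", nrow(frags))   # samples carrying fragment
  frag_member_seq <- vector("list", nrow(frags))
  for (s in samples) {
    avail <- which(present[s, frags$source_id])
    recovered <- avail[rbinom(length(avail), 1L, recovery_prob) == 1L]
    if (!length(recovered)) next
    er <- emit_reads(frags[recovered, , drop = FALSE], read_len, sub_rate,
                     id_prefix = paste0(s, "__"))
    er$truth$sample <- s
    reads <- if (is.null(reads)) er$reads else rbind(reads, er$reads)
    truth <- rbind(truth, er$truth)
    for (k in seq_along(recovered)) {
      f <- recovered[k]
      frag_members[[f]] <- c(frag_members[[f]], s)
      frag_member_seq[[f]] <- c(frag_member_seq[[f]], er$reads$sequence[k])
    }
  }
  ti <- match(truth$source_id, taxa$source_id)
  truth$taxid <- taxa$taxid[ti]
  truth$phylum <- taxa$phylum[ti]
  truth$genus <- taxa$genus[ti]
  truth$species <- taxa$species[ti]
  hits <- synth_hit_table(truth, taxa, decoys = decoys)
  lineage <- lineage_store(taxa[, LINEAGE_HEADER])
  # across-sample loci: one per fragment recovered in >= 1 sample,
  # members named by sample id, 0-based locus ids over selected fragments
  got <- which(lengths(frag_members) > 0L)
  loci <- structure(lapply(got, function(f) {
    new_locus(f - 1L, frag_members[[f]], frag_member_seq[[f]])
  }), class = "rad_loci")
  locus_truth <- if (length(got)) {
    first_sample <- vapply(loci, function(l) l$members$sample_id[1],
                           character(1))
    # map each locus back to its representative member's read row
    idx <- mapply(function(f, s) {
      which(truth$sample == s & truth$source_id == frags$source_id[f] &
              truth$fragment_start == frags$start[f])[1]
    }, got, first_sample)
    data.frame(
      read_id = paste0("locus_", vapply(loci, `[[`, integer(1), "locus_id")),
      source_id = truth$source_id[idx],
      fragment_start = truth$fragment_start[idx],
      mutations = truth$mutations[idx],
      read_len = truth$read_len[idx],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(read_id = character(0), source_id = character(0),
               fragment_start = integer(0), mutations = integer(0),
               read_len = integer(0), stringsAsFactors = FALSE)
  }
  locus_hits <- synth_hit_table(locus_truth, taxa)
  structure(
    list(taxa = taxa, genomes = genomes, fragments = frags,
         samples = samples, present = present, reads = reads,
         truth = truth, hits = hits, lineage = lineage, loci = loci,
         locus_truth = locus_truth, locus_hits = locus_hits,
         params = params),
    class = "rad_simulation"
  )
}

#' Write a simulated dataset to a directory
#'
#' Emits every file the CLI pipeline consumes: `reads.fasta`, `refs.fasta`,
#' `hits.tsv`, `locus_hits.tsv`, `lineage.tsv`, `truth.tsv`, `samples.tsv`
#' (read id to sample map), and `loci.loci`.
#'
#' @param sim a `rad_simulation` ([simulate_dataset()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$reads, p("reads.fasta"))
  write_fasta(sim$genomes, p("refs.fasta"))
  write_blast_tab(sim$hits, p("hits.tsv"))
  write_blast_tab(sim$locus_hits, p("locus_hits.tsv"))
  write_lineage_table(sim$lineage, p("lineage.tsv"))
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(
    data.frame(qseqid = sim$truth$read_id, sample = sim$truth$sample),
    p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_loci(sim$loci, p("loci.loci"))
  invisible(dir)
}
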