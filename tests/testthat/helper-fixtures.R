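# Shared fixtures: a toy lineage table spanning the interesting cases
# (host phylum, three parasite phyla, a taxid with no phylum, a bacterial
# taxid for cross-superkingdom conflicts) and a one-row hit constructor.

toy_lineage_df <- function() {
  data.frame(
    taxid = c("9606", "7955", "6183", "6239", "5855", "7777", "8888"),
    superkingdom = c(rep("Eukaryota", 6), "Bacteria"),
    kingdom = c(rep("Metazoa", 4), "", "", ""),
    phylum = c("Chordata", "Chordata", "Platyhelminthes", "Nematoda",
               "Apicomplexa", "", "Proteobacteria"),
    class = "", order = "", family = "",
    genus = c("Homo", "Danio", "Schistosoma", "Caenorhabditis",
              "Plasmodium", "", "Escherichia"),
    species = c("Homo sapiens", "Danio rerio", "Schistosoma mansoni",
                "Caenorhabditis elegans", "Plasmodium vivax", "",
                "Escherichia coli"),
    stringsAsFactors = FALSE
  )
}

toy_store <- function() lineage_store(toy_lineage_df())

make_hit <- function(qseqid, staxid, pident, bitscore = 2 * pident,
                     sseqid = paste0("ref", staxid), evalue = 1e-10,
                     len = 100L, mismatch = NULL) {
  if (!length(qseqid)) return(radbycatch:::empty_hits())
  if (is.null(mismatch)) mismatch <- round(len * (1 - pident / 100))
  data.frame(
    qseqid = qseqid, sseqid = sseqid, pident = pident,
    length = as.integer(len), mismatch = as.integer(mismatch),
    gapopen = 0L, qstart = 1L, qend = as.integer(len), sstart = 1L,
    send = as.integer(len), evalue = evalue, bitscore = bitscore,
    staxid = as.character(staxid), stringsAsFactors = FALSE
  )
}

make_hits <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Randomized hit tables over the toy taxa, used by the property tests and
# the acceptance oracle-equivalence criterion. About 10% of hits carry an
# unknown taxid (classification must stay total).
random_hit_table <- function(n_queries, max_hits, p_unknown_taxid = 0.1) {
  taxids <- c(toy_lineage_df()$taxid, "424242")
  rows <- lapply(seq_len(n_queries), function(q) {
    k <- sample.int(max_hits + 1L, 1L) - 1L   # 0..max_hits
    if (!k) return(NULL)
    tx <- sample(taxids, k, replace = TRUE,
                 prob = c(rep((1 - p_unknown_taxid) / 7, 7),
                          p_unknown_taxid))
    pid <- round(runif(k, 50, 100), 1)
    make_hit(sprintf("q%03d", q), tx, pid,
             bitscore = round(pid * 2 + sample(0:5, k, TRUE), 1),
             sseqid = sprintf("ref%s_%d", tx, sample.int(3, k, TRUE)),
             evalue = signif(10^(-runif(k, 5, 50)), 3))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- make_hit(character(0), character(0), numeric(0))
  rownames(out) <- NULL
  out
}
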