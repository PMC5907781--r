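# simulate: random genomes, restriction digest, size selection, read
# emission, synthetic hit tables and the full dataset generator.

test_that("random_genome is seeded, respects the alphabet and GC target", {
  g1 <- random_genome(500, 0.5, seed = 42)
  g2 <- random_genome(500, 0.5, seed = 42)
  expect_identical(g1$sequence, g2$sequence)

  at_only <- random_genome(300, 0, seed = 1)
  expect_false(grepl("[GC]", at_only$sequence))

  g <- random_genome(1e5, 0.5, seed = 7)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(1e5 * 0.5 * 0.5)
  expect_lt(abs(gc - 5e4), sd3)

  expect_error(random_genome(0), "positive")
  expect_error(random_genome(10, 1.2), "\\[0,1\\]")
})

test_that("enzyme validation and the default EcoRI/MspI pair", {
  ez <- default_enzymes()
  expect_equal(ez$EcoRI$recognition, "GAATTC")
  expect_equal(ez$EcoRI$cut_offset, 1L)
  expect_equal(ez$MspI$recognition, "CCGG")
  expect_equal(ez$MspI$cut_offset, 1L)
  expect_error(enzyme("X", "GAAT", 5), "cut_offset")
  expect_error(enzyme("X", "GANT", 1), "\\{A,C,G,T\\}")
  expect_message(enzyme("FokI", "GGATG", 5), "not palindromic")
})

test_that("digest reproduces the worked EcoRI/MspI example", {
  frags <- digest(seq_records("g", "AAGAATTCAACCGGTT"))
  expect_equal(frags$start, c(0L, 3L, 11L))
  expect_equal(frags$end, c(3L, 11L, 16L))
  expect_equal(frags$left_end, c("terminus", "EcoRI", "MspI"))
  expect_equal(frags$right_end, c("EcoRI", "MspI", "terminus"))
  expect_equal(frags$sequence, c("AAG", "AATTCAAC", "CGGTT"))
})

test_that("digest handles no sites and overlapping occurrences", {
  frags <- digest(seq_records("g", "AAAATTTT"))
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$start, 0L)
  expect_equal(frags$end, 8L)
  expect_equal(frags$left_end, "terminus")
  expect_equal(frags$right_end, "terminus")

  # CCGG occurrences overlapping at CCGGCCGG and CCGCCGG-style runs
  frags <- digest(seq_records("g", "TTCCGGCCGGTT"))
  expect_equal(frags$start, c(0L, 3L, 7L))
  # "CCGGG": sites at 0 only (CCGG once) vs "CCCGG": site at 1
  expect_equal(digest(seq_records("g", "ACCCGGA"))$start, c(0L, 3L))
})

test_that("digest fragments tile randomized genomes exactly", {
  set.seed(55)
  for (rep in 1:5) {
    g <- random_genome(sample(2000:6000, 1), runif(1, 0.3, 0.7),
                       id = "g")
    frags <- digest(g)
    expect_equal(frags$start[1], 0L)
    expect_equal(frags$end[nrow(frags)], nchar(g$sequence))
    if (nrow(frags) > 1) {
      expect_equal(frags$start[-1], frags$end[-nrow(frags)])
      # every internal boundary coincides with a recognition-site cut
      chars <- strsplit(g$sequence, "")[[1]]
      # a cut at 0-based b comes from a site starting at b - cut_offset,
      # i.e. 1-based characters b..b+5 (EcoRI) or b..b+3 (MspI)
      for (b in frags$start[-1]) {
        at_ecori <- b + 5 <= length(chars) &&
          paste(chars[b:(b + 5)], collapse = "") == "GAATTC"
        at_mspi <- b + 3 <= length(chars) &&
          paste(chars[b:(b + 3)], collapse = "") == "CCGG"
        expect_true(isTRUE(at_ecori) || isTRUE(at_mspi))
      }
    }
    expect_equal(paste(frags$sequence, collapse = ""), g$sequence)
  }
})

test_that("ddrad_select applies the inclusive window and the end rule", {
  fr <- data.frame(
    source_id = "g", start = 0L, end = 1L,
    length = c(150L, 250L, 301L, 250L, 250L, 200L, 300L, 199L),
    left_end = c("EcoRI", "EcoRI", "EcoRI", "EcoRI", "terminus", "MspI",
                 "EcoRI", "EcoRI"),
    right_end = c("MspI", "MspI", "MspI", "EcoRI", "MspI", "EcoRI",
                  "MspI", "MspI"),
    sequence = "N", stringsAsFactors = FALSE
  )
  kept <- ddrad_select(fr)
  # 250 EcoRI/MspI, both window bounds inclusive, either orientation;
  # EcoRI/EcoRI, terminus and out-of-window fragments dropped
  expect_equal(kept$length, c(250L, 200L, 300L))
  expect_equal(ddrad_select(fr, 240, 260)$length, 250L)
  expect_error(ddrad_select(fr, require_ends = "EcoRI"), "exactly two")
})

test_that("emit_reads: prefixes, short fragments, planted mutation rate", {
  fr <- digest(random_genome(5000, 0.5, seed = 9, id = "src"))
  er <- emit_reads(fr, read_len = 50, sub_rate = 0)
  expect_equal(er$reads$sequence,
               substr(fr$sequence, 1, pmin(50, fr$length)))
  expect_true(all(er$truth$mutations == 0))
  expect_true(all(grepl("^src_f[0-9]{3}$", er$reads$id)))

  short <- fr[fr$length < 50, , drop = FALSE]
  if (nrow(short)) {
    er2 <- emit_reads(short, read_len = 50, sub_rate = 0)
    expect_equal(nchar(er2$reads$sequence), short$length)
  }

  # realized identity within 3 binomial SD of 1 - sub_rate
  long <- fr[fr$length >= 100, , drop = FALSE]
  er3 <- emit_reads(long, read_len = 100, sub_rate = 0.1, seed = 3)
  n_bases <- sum(er3$truth$read_len)
  p_hat <- sum(er3$truth$mutations) / n_bases
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_bases))
  # reads differ from the fragment prefix at exactly `mutations` positions
  diffs <- mapply(function(read, frag) {
    a <- strsplit(read, "")[[1]]
    b <- strsplit(substr(frag, 1, nchar(read)), "")[[1]]
    sum(a != b)
  }, er3$reads$sequence, long$sequence)
  expect_equal(unname(diffs), er3$truth$mutations)

  expect_error(emit_reads(fr, sub_rate = 0.5), "0.5")
})

test_that("synth_hit_table encodes truth and decoys as specified", {
  truth <- data.frame(
    read_id = c("r1", "r2"), source_id = "host",
    fragment_start = c(0L, 250L), mutations = c(0L, 5L),
    read_len = c(100L, 125L), stringsAsFactors = FALSE
  )
  taxa <- data.frame(source_id = "host", taxid = "90001",
                     stringsAsFactors = FALSE)
  hits <- synth_hit_table(truth, taxa)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$pident[hits$qseqid == "r1"], 100)
  expect_equal(hits$pident[hits$qseqid == "r2"], 100 * (1 - 5 / 125))
  expect_equal(hits$staxid, c("90001", "90001"))
  expect_true(all(hits$qstart == 1L))
  expect_equal(hits$sstart[hits$qseqid == "r2"], 251L)

  decoys <- data.frame(read_id = "r1", taxid = "90002", pident = 85,
                       stringsAsFactors = FALSE)
  hits2 <- synth_hit_table(truth, taxa, decoys = decoys)
  expect_equal(sum(hits2$qseqid == "r1"), 2L)
  d <- hits2[hits2$sseqid == "decoy_90002", ]
  expect_equal(d$pident, 85)
  # bitscore monotone in pident: the true 100%-hit outranks the decoy
  expect_gt(hits2$bitscore[hits2$qseqid == "r1" & hits2$sseqid == "host"],
            d$bitscore)
  expect_error(synth_hit_table(truth, taxa,
                               decoys = data.frame(read_id = "zz",
                                                   taxid = "1",
                                                   pident = 90)),
               "not in truth")
})

test_that("simulate_dataset is reproducible and internally consistent", {
  s1 <- simulate_dataset(n_samples = 2, host_length = 4e4,
                         parasite_length = 2e4, sub_rate = 0.01, seed = 11)
  s2 <- simulate_dataset(n_samples = 2, host_length = 4e4,
                         parasite_length = 2e4, sub_rate = 0.01, seed = 11)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$loci, s2$loci)

  # every read has exactly one truth record and one true hit
  expect_equal(sort(s1$reads$id), sort(s1$truth$read_id))
  expect_equal(anyDuplicated(s1$truth$read_id), 0L)
  expect_true(all(s1$truth$read_id %in% s1$hits$qseqid))

  # all selected fragments respect the window and end rule
  expect_true(all(s1$fragments$length >= 200 &
                    s1$fragments$length <= 300))
  ends <- paste(pmin(s1$fragments$left_end, s1$fragments$right_end),
                pmax(s1$fragments$left_end, s1$fragments$right_end))
  expect_true(all(ends == "EcoRI MspI"))

  # loci member samples are real samples; representatives align to truth
  for (l in s1$loci) {
    expect_true(all(l$members$sample_id %in% s1$samples))
  }
  expect_equal(length(s1$loci), nrow(s1$locus_truth))
  expect_true(all(s1$locus_hits$pident >= 0 & s1$locus_hits$pident <= 100))
})

test_that("write_simulation emits parseable files", {
  sim <- simulate_dataset(n_samples = 2, host_length = 4e4,
                          parasite_length = 2e4, seed = 13)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_equal(nrow(read_fasta(file.path(dir, "reads.fasta"))),
               nrow(sim$reads))
  hits <- read_blast_tab(file.path(dir, "hits.tsv"))
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_equal(hits$qseqid, sim$hits$qseqid)
  store <- read_lineage_table(file.path(dir, "lineage.tsv"))
  expect_equal(resolve(store, "90002")$phylum, "Platyhelminthes")
  loci <- read_loci(file.path(dir, "loci.loci"))
  expect_equal(length(loci), length(sim$loci))
  expect_equal(loci[[1]]$members$sample_id, sim$loci[[1]]$members$sample_id)
})
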