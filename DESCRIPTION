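Package: radbycatch
Title: Mining Metagenomic Bycatch from Reduced-Representation (ddRAD)
    Sequencing Data
Version: 1.0.0
Authors@R:
    person("Avery", "Whitaker", email = "avery.whitaker@example.org",
           role = c("aut", "cre"))
Description: Tools to recover non-target ("bycatch") metagenomic sequences
    from host-targeted double-digest RADseq libraries. Reads clustered
    RADseq outputs (FASTA, pyRAD-style *.edit and *.loci files), classifies
    locus sequences taxonomically from BLAST tabular hit tables under
    percent-identity thresholds and a kingdom/phylum ambiguity-discard rule,
    and summarises results as per-sample phylum count tables, cross-host
    presence/absence matrices, genus-level community matrices and exact
    hypergeometric rarefaction curves. Includes an in-silico ddRAD simulator
    (restriction digest, size selection, mutated reads, truth-labelled hit
    tables) so the whole pipeline can be exercised offline, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
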