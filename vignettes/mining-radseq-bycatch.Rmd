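---
title: "Mining metagenomic bycatch from ddRAD data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenomic bycatch from ddRAD data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbycatch)
```

## The problem

Double-digest RADseq (ddRAD) libraries are built from total DNA extracted
from host tissue. Restriction digestion and size selection sample a
reproducible subset of *whatever genomes are present in the extract* —
overwhelmingly the host, but also blood parasites, gut microbes and other
organisms whose DNA circulates in or adheres to the tissue. This package
treats a clustered RADseq dataset as a crude shotgun metagenome: each
clustered sequence is aligned against a reference nucleotide database
(externally, with a cross-species-tolerant mode such as discontiguous
megablast), and the resulting tabular hits are classified, filtered and
summarised here.

The pipeline stages are: representative extraction from across-sample
loci → per-query taxonomic classification under an identity threshold and
an ambiguity-discard rule → per-sample count tables, cross-host
presence/absence matrices and genus-level community matrices → rarefaction
curves assessing sampling depth.

## The classification model

Each query *q* has a (possibly empty) set of hits; each hit carries a
percent identity and a subject taxon resolved to a ranked lineage through
an **offline lineage table** (live taxonomy lookups are deliberately out of
scope: the lineage TSV is the contract, which makes runs reproducible and
network-free). The decision chain, applied in order:

1. **no_hit** — the hit set is empty.
2. **ambiguous** — the hits with identity *strictly* greater than the
   ambiguity floor (default 80%) span more than one phylum, or more than
   one superkingdom, or more than one kingdom. Such a query resembles
   conserved sequence that cannot be attributed to a lineage and is
   discarded from counting.
3. **below_threshold** — the best hit's identity is below the working
   threshold *t* (comparison is inclusive: identity ≥ *t* passes).
4. **unresolvable** — the best hit resolves to no phylum (sentinel
   `UNKNOWN` lineage). Kept distinct from `no_hit` for auditability.
5. **classified** — phylum, genus and species are copied from the single
   best hit (no consensus across hits): the hit maximising bitscore, then
   identity, then smallest e-value, with deterministic tie-breaks on
   subject id and taxon id so output is platform-independent.

Design choices worth spelling out:

- **"Kingdom" is checked at both superkingdom and kingdom ranks.**
  Reference taxonomies split Bacteria/Archaea/Eukaryota at superkingdom
  while eukaryote kingdoms (Metazoa, Fungi, …) sit one rank lower. The
  discard rule's intent is conservative removal of cross-kingdom
  conflicts, so a conflict at either rank discards the query.
- **The floor is strict (> 80), the threshold inclusive (≥ t).** A hit at
  exactly 80% identity does not trigger the discard rule, while a best hit
  at exactly *t* does count as identified at *t*. The two parameters are
  decoupled: the
  ambiguous set does not move during a threshold sweep, which the sweep
  implementation exploits (classify once at t = 0, then re-label
  classified/unresolvable queries whose best identity falls under each t).
- **Sentinel labels never create ambiguity.** A hit whose taxon resolves
  to no label at the checked rank is excluded from the label set (and
  logged): unknown is not evidence of conflict.
- **Unknown taxids resolve to an all-sentinel lineage with a warning**
  rather than an error. Classification is total; unidentifiable queries
  are reported, not dropped.

The five statuses partition the query universe at every threshold — a
bookkeeping identity asserted by the tests — and per-phylum classified
counts are non-increasing in *t*, the testable form of the qualitative
claim that raising the similarity threshold shrinks every phylum's count
without usually zeroing it.

## Community summaries

- **Phylum count table** (per sample): classified counts for the four
  phyla of interest (Chordata, Platyhelminthes, Nematoda, Apicomplexa, at
  the 97% headline threshold by default) plus a `Total` column counting
  every query, classified or not. Totals are the denominator for "how much
  of the library is identifiable at all".
- **Shared presence/absence matrix**: across-sample loci are the only
  structure tying one sequence to multiple hosts, so "distinct,
  identifiable metagenomic sequences" are operationalised as loci whose
  representative classified to a non-host phylum. The default filter keeps
  loci present in ≥ 2 samples; because "two or more representatives" can
  also be read as two member sequences, both filters are exposed
  (`min_samples`, `min_members`), with `min_samples = 2` the default.
- **Genus community matrix** (at the 90% community threshold): one lumped
  host column plus one column per parasite genus. Parasite queries whose
  genus is unknown pool into `<phylum>_unassigned` rather than being
  dropped, so parasite column sums equal parasite-classified query counts
  exactly — rarefaction totals then match classification totals.

## Rarefaction

Expected richness under subsampling without replacement is the
hypergeometric expectation

$$E[S_n] = \sum_i \left[ 1 - \binom{N - N_i}{n} \Big/ \binom{N}{n} \right],
\qquad N = \sum_i N_i,$$

the documented individual-based method of the standard vegetation-ecology
implementations, adopted here as the definition. Binomial ratios are
evaluated as `exp(lchoose(...) - lchoose(...))`: log-gamma arithmetic
keeps the computation exact to machine precision at totals of 10^6 reads
and beyond (naive factorials overflow). `lchoose(k, n)` is `-Inf` for
`n > k`, so taxa that cannot be missed contribute exactly 1 without a
special case. Non-integer counts are rejected — inputs are read counts.
Depth grids default to 20 evenly spaced depths from 1 to the sample total.

Two analytic subtleties surfaced while testing:

- Duplicating every count **lowers** (weakly) expected richness at a fixed
  depth: {1,1} at n = 2 gives richness 2, while {2,2} at n = 2 gives 5/3.
  The intuition that scale cannot matter is wrong because a smaller pool
  is exhausted faster without replacement. The property suite asserts this
  true direction.
- Monte-Carlo validation ("within 3 SE") breaks down where a taxon's miss
  probability drops below 1/replicates: every replicate then observes full
  richness, the replicate standard deviation is 0, and the exact value
  differs from the integer by that tiny probability. The tests add a
  4/replicates allowance — the Poisson 98% upper limit for an event
  observed zero times — which keeps the check honest in the zero-variance
  regime without loosening it anywhere variance exists.

## The simulator: a stated world

The generator emulates the wet-lab protocol at desk scale so planted truth
can be recovered exactly:

| parameter | default | why |
|---|---|---|
| enzymes | EcoRI `G^AATTC`, MspI `C^CGG` | the protocol's pair |
| insert window | 200–300 bp, inclusive | the protocol's size selection |
| read length | 125 bp, single-end | the protocol's sequencing; pairing adds no tested math |
| genomes | host 3×10⁵ bp, parasites 10⁵ bp, GC 0.45 | scaled so the digest yields tens of host inserts and a handful per parasite; GC in the vertebrate/parasite range |
| substitution rate | 0.01 | typical Illumina + divergence-from-reference noise; 0 and 0.05 are used where stated by specific checks |
| samples | 3; parasite presence 0.8; fragment recovery 0.9 | parasites in "most but not all" samples, mild allelic dropout — the qualitative structure of real shared-locus matrices |

Digestion finds every (possibly overlapping) top-strand site occurrence —
both defaults are palindromic so this covers both strands — cuts at
`site_start + cut_offset`, and the resulting fragments provably tile the
genome. Size selection additionally requires **one end per enzyme**
(either orientation): only such fragments receive both adapters in real
ddRAD chemistry; terminus fragments never pass. Substitutions are uniform
over the three alternative bases with no indel model, so the synthetic hit
table's identity is exactly `100 × (1 − mutations/length)` and bitscore is
monotone in identity — decoy hits planted at chosen identities therefore
interact with the ambiguity rule in a fully controlled way.

What the simulator does **not** model: sequencing-quality profiles, PCR
duplicates, adapters/barcodes, indels, real genome composition
(repeats, GC heterogeneity), or database incompleteness. A green
end-to-end test establishes that the *bookkeeping and decision rules* are
correct under planted truth — not that any particular real library will
yield similar counts.

## Numerical and interface conventions

- Alignment coordinates (hit tables) are 1-based inclusive; simulator
  coordinates are 0-based half-open. The boundary is the hit table itself.
- Parsers are strict with line-numbered errors (13-column hit TSV,
  mandatory lineage header); duplicate lineage taxids keep the last row
  with a warning; `;`-separated `staxids` cells split into one hit each.
- `*.loci` separators are recognised by the `//` prefix alone; a trailing
  `|N|` tag supplies the locus id, otherwise the 0-based block index does.
  Alignment gaps are stripped on read because classification operates on
  ungapped queries. `*.edit` files are plain FASTA to this package.
- Equal-coordinate cuts by two enzymes take the first enzyme's label —
  deterministic, and impossible with the default pair.
- All randomness flows from a single integer seed; identical config + seed
  reproduces every output byte-for-byte (asserted by the determinism
  test). Config files are flat `key = value` (no YAML dependency in the
  supported R stack).

## Known limitations

- Classification trusts the hit table; no e-value filtering beyond the
  tie-break and no lowest-common-ancestor consensus (the best-hit rule is
  the contract).
- The ambiguity rule inspects *all* provided hits; if an upstream tool
  capped hits per query, the effective rule is capped likewise.
- Rarefaction is individual-based; incidence-based rarefaction,
  extrapolation and confidence intervals are out of scope.
- The published real-data counts are not reproducible offline (they
  depend on the original reads and on the reference database's state at
  query time) and are deliberately not acceptance targets; the acceptance
  suite is property-based instead.
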