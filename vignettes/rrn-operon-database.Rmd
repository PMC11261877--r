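---
title: "Building and analysing rRNA operon reference databases with rrndb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing rRNA operon reference databases with rrndb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rrndb` builds non-redundant reference databases of full-length
16S-ITS-23S rRNA operon (*rrn*) sequences from annotated genome
assemblies, and implements the analytics used to characterise such
databases: intragenomic diversity of operon copies and in-silico PCR
evaluation of degenerate primer panels. This vignette is the package's
account of its methods: the model behind each stage, the parameters that
matter, the numerical conventions, and the limits of what the bundled
simulator can demonstrate.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open intervals, so lengths are
always `end - start` and adjacent features never share a position. GFF3
input and output is converted at the boundary (1-based inclusive on disk).
Sequences are uppercased on read; `N` and the other IUPAC ambiguity codes
are preserved, because primer matching and distance computation give them
specific semantics (below). Duplicate contig identifiers are an error
rather than being deduplicated silently, because operon identifiers embed
the contig identifier.

## Operon extraction

An annotated rRNA feature is classified as 16S, 23S or 5S from its
`product`/`Name` attributes. A gene's *coverage* is its annotated length
divided by a canonical gene length — defaults 1534 nt (16S) and 2924 nt
(23S), the mean gene lengths observed across large genome collections —
and genes with coverage below 0.80, or annotated as partial upstream, are
flagged partial and excluded from linking. Partial genes are usually
contig-edge fragments; linking them would fabricate truncated operons.

Linking then pairs, within each contig and strand, every 16S gene with the
nearest unused 23S gene downstream of it in transcription order (greater
coordinates on `+`, lesser on `-`), scanning 16S genes in coordinate
order. "Nearest downstream" matches the biology of the *rrn* operon, where
the 23S follows the 16S after a spacer, and makes the pairing
deterministic; each 23S is consumed at most once. When annotations of a
pair overlap (a negative spacer), the pair is rejected with a warning — a
negative spacer is biologically implausible and breaks interval
arithmetic. The inter-gene gap is the ITS; it may be empty.

Two filters follow:

* **unlinked** — operons whose ITS exceeds `max_its` (default 1500 nt) are
  removed. The threshold is strict: an ITS of exactly 1500 nt is kept.
  Such "unlinked" 16S/23S pairs are real features of some phyla
  (Deinococcus-Thermus, Planctomycetes) but do not form a contiguous
  amplifiable unit.
* **boundary** — operons not fully contained in `[0, contig length)` are
  removed. Containment is checked linearly even for circular replicons:
  origin-wrapping operons are discarded rather than re-stitched.

Surviving operons are sliced from their contig, reverse-complemented when
on the minus strand so every stored sequence reads 16S→ITS→23S, and named
`genome|contig|start-end|strand`.

## Dereplication

### Identity

Pairwise identity is computed from an ends-free (overlap) global
alignment: a Needleman-Wunsch dynamic programme with free terminal gaps,
linear gap penalties, and scores match = +2, mismatch = −3, gap = −5.
Identity is `100 × matching columns / alignment columns`, with
terminal-gap columns excluded — the convention of the common dereplication
tools, under which a sequence contained in a longer one at full identity
scores 100 %. The exact formula is stated here because published pipelines
often name only the tool, not its identity definition; fixing the formula
makes results reproducible.

The implementation (in C++) is banded: cells are restricted to the
corridor between the end diagonals plus a margin (default
`max(64, length difference + 64)` for sequences above 512 nt, exact
otherwise). At a 99.9 % threshold two ~5 kb sequences can differ by only a
few edits, so high-identity alignments never leave the band; `band = Inf`
forces the exact programme. Tie-breaks (diagonal over vertical over
horizontal moves, end cells scanned from the corner) are fixed so results
are deterministic. The test suite checks the aligner against an
independent full-matrix dynamic-programming oracle on all random pairs up
to 12 nt.

### Greedy clustering

Sequences are sorted by decreasing length (ties broken by identifier) and
scanned once. Each sequence joins the *best-scoring* existing centroid
with identity at or above the threshold (default 99.9 %), else founds a
new cluster. Because of the sort, every representative is its cluster's
longest member. Best-scoring assignment, rather than first-qualifying, is
deliberately order-robust and may differ from any particular external
tool's accept heuristic; the difference is documented rather than hidden.

A k-mer containment prescreen (k = 12) skips alignments against centroids
that share too few k-mers to possibly reach the threshold. The cutoff is
derived from the threshold (`1 − 2k(1 − t/100) − 0.05`) with a factor-two
margin for edits falling as indels, and disables itself below ~95 %
thresholds where the bound becomes vacuous. The prescreen is an
accelerator only: a pair at or above the threshold always passes it.

### Two phases, representatives, consensus

Database construction is two-phase: operons from complete assemblies are
clustered first; operons from incomplete assemblies are appended to the
phase-1 representatives and re-clustered, so an incomplete-assembly
sequence is retained only if it is below the threshold to every retained
centroid — it must expand on the diversity already captured by complete
genomes. Phase-1 members are re-attached to the final cluster of their
representative, and identities to the final representative are reused
where the reference is unchanged and recomputed otherwise.

Each cluster is exported two ways: the representative sequence (*nrRep*)
and a column-majority consensus (*nrCon*). The consensus comes from a star
alignment of members to the representative, not a full multiple-sequence
alignment: per column the most frequent symbol wins, columns with a gap
majority are dropped, and base ties resolve in the fixed order
A < C < G < T. A star alignment is deterministic and cheap, and is exact
for single-member and identical-member clusters — the large majority in
practice, where roughly four out of five non-redundant clusters hold a
single sequence. Insertion columns relative to the representative are
keyed to the representative position they follow; members lacking an
insertion vote gap there.

## Taxonomy

Lineages use the seven-rank prefixed form
`k__;p__;c__;o__;f__;g__;s__`. A lineage may be truncated (deeper ranks
empty) but never gapped: an empty rank above a named one is an error.

Three cluster-level systems are computed:

* `taxRep` — the source-genome lineage of the representative.
* `taxLCA` — the deepest rank at which all members agree, with an
  identical path above; disagreement at kingdom yields an empty lineage.
* `taxMaj` — scanning from species upward, the first rank at which some
  full lineage prefix is carried by *strictly more than half* of the
  members. Exact ties carry no majority and fall to the next rank up.
  Votes are pooled over full prefixes, never bare names at a rank, so a
  homonymous genus under two families cannot assemble a chimeric lineage.
  Members count once per operon sequence, even when several come from one
  genome.

The classic illustration: a cluster of 97 *Escherichia coli* and 3
*Shigella flexneri* operons is `s__Escherichia coli` under `taxMaj` but
only `f__Enterobacteriaceae` under `taxLCA`. Both behaviours are useful;
`taxRep` is the pragmatic default.

## Intragenomic diversity

For every genome with at least two surviving operons, the package compares
all operon pairs for the whole operon and for each constituent region
(16S, ITS, 23S), sliced from the transcription-oriented sequence. The
distance unit is SNVs per 100 comparable nucleotides:
`100 × mismatching columns / columns where both sequences carry an
unambiguous base`. Gap columns and columns containing `N` are excluded
from numerator and denominator alike — the gap treatment of distance
tools is rarely documented, so the choice is pinned here and exercised by
tests. Identity is `100 − distance`, and an approximate SNV count for a
peak identity is `round(length × (100 − identity) / 100)`.

Pairs are aligned with the same ends-free aligner used for clustering,
i.e. pairwise alignments rather than one multiple alignment per genome.
This removes an external alignment-heuristic dependence and is exact for
substitution-only differences, which is also what the simulator plants;
for indel-rich copies the pairwise and MSA column spaces can differ
slightly.

Summary statistics (mean, median, SD, CV of identities) are pooled over
all pairs across genomes, not averaged per genome, and
`fraction_genomes_diverse` is the share of multi-copy genomes with any
pair below 100 % identity. Cross-region Pearson correlations match pairs
by (genome, operon pair) key; correlations over fewer than three pairs or
with zero variance are reported missing. The interquartile-range outlier
rule offered by the plotting method trims the *plot only* — statistics are
never computed on trimmed data.

## In-silico PCR

Primer matching is IUPAC-aware and positional: a primer code matches a
template base when the base lies in the code's expansion set (R = A/G,
and so on). Degenerate positions are never expanded combinatorially; the
test is per-position set membership, so long degenerate primers cost
nothing extra. A template `N` (or any template ambiguity code) matches
nothing — conservative, so runs of `N` cannot fabricate binding sites.
The default mismatch allowance is zero, matching the behaviour of the
commonly used in-silico PCR scripts; it is configurable.

Reverse primers are given 5'→3' on the antisense strand (the standard
convention for published primer tables); the tool reverse-complements them
before scanning the sense strand. Each forward site pairs with the nearest
downstream reverse site, the product spanning forward-site start to
reverse-site end; the template's reverse complement is scanned
symmetrically and reported in template coordinates. Products above
`max_len` (default 10 kb, comfortably above the ~4.9 kb full-length
amplicon) are dropped to bound runaway pairings on concatenated input.

The bundled panel holds the three full-operon pairs in common use — 27F
with 2241R, 27F with 2428R, and 519F with 2428R. Panel evaluation reports
per-pair coverage (share of sequences with at least one product), the
amplicon length distribution, and the phylum composition of sequences
with no product.

## The synthetic-genome simulator

`generate_fixture()` exists so that every pipeline stage is testable
without downloading genomes. Its defaults emulate the broad shape of real
genome collections: around five operon copies per genome (a Poisson option
mirrors the observed mean of ~5.3), ITS lengths drawn around 440 nt with
wide spread, most intragenomic variation in the ITS, and an even strand
mix. Lineage founder operons diverge from fixed synthetic gene templates
at 5 % per base — far outside any dereplication radius — while copies
within a genome differ by small Poisson-distributed substitution counts.
The ITS is lineage-level, so within-lineage cohesion and between-lineage
divergence are both controlled. Planted anomalies (truncated 16S genes,
oversized spacers, origin-crossing annotations) are recorded in a truth
table together with each operon's coordinates, strand and per-region
substitution counts, and whether it should survive extraction.

Substitutions never silently restore the original base, so planted
Hamming distances are exact and the diversity module can be checked
against the truth table to the digit. Mutation is substitution-only by
default — that is what makes distance arithmetic exactly checkable — and
the gene templates are synthetic random sequences of canonical length
(1534/2924 nt) carrying intact motifs for the bundled primers, not real
gene sequences. Primer sites are protected from mutation by default,
mirroring the conservation of real primer binding regions.

What passing tests therefore do *not* show: performance on real rRNA
secondary-structure-constrained sequence variation, indel-rich ITS
evolution, chimeric assemblies, or annotation errors beyond the planted
anomaly classes. The simulator validates the machinery, not the biology.

## Problem sizes and determinism

The test suite runs the full pipeline — simulate, build, diversity, PCR —
on a 50-genome fixture (~250 operons of ~5 kb), a size chosen so the whole
suite completes in a few minutes while still exercising two-phase
clustering, anomaly filtering and the primer panel at realistic sequence
lengths. Unit fixtures are far smaller. Every stage is deterministic given
(inputs, configuration, seed): fixture generation is seeded, clustering is
order-deterministic, and all tie-breaks are fixed. Re-running any stage on
identical input produces byte-identical output, which the tests assert.

## Known limitations

* The greedy clusterer is quadratic in the number of clusters per lineage
  neighbourhood; it is designed for desk-scale and moderate collections,
  not for hundreds of thousands of genomes in one pass.
* Identity and distance definitions are principled choices among several
  defensible readings of the tools they emulate; absolute numbers can
  differ slightly from other software even when rankings agree.
* Assembly level (complete/incomplete) is caller-supplied metadata, as is
  the lineage table; the package neither downloads accessions nor
  converts taxon identifiers.
* 5S genes are classified but never incorporated into operons, and
  operons spanning multiple contigs are out of scope by construction.
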