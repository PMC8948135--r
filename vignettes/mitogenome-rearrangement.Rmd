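---
title: "Mitogenome annotation statistics and the TD(N\\R)L + RC rearrangement model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome annotation statistics and the TD(N\R)L + RC rearrangement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearrange)
```

## The problem

Bilaterian mitochondrial genomes are small circular molecules — typically 13
protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs, and one AT-rich control
region (CR) — whose *gene order* evolves by rearrangement: segments are
duplicated and copies lost, inverted, or shuffled by recombination.  Because
rearrangements are rare and essentially irreversible, shared arrangements
are strong phylogenetic characters.  This package models the gene order of
the millipede *Polydesmus* sp. GZCS-2019, whose 15,036 bp mitogenome has
every gene — including both rRNAs and the control region — on one strand, an
arrangement that none of the three classical mechanisms (tandem
duplication–random loss, duplication–non-random loss, recombination) explains
alone.

## Objects and conventions

An **annotation table** (`mito_annotation`) holds 1-based, fully closed
coordinate intervals on the circular genome, the convention of GenBank
feature tables; converters to other conventions belong at I/O boundaries,
and origin-wrapping features are rejected (none occur here).  A **signed
gene order** (`gene_order`) is the circular sequence of (label, orientation)
pairs; the control region participates as an orientable element because the
rearrangement model tracks it.  Since strand labels on a circular molecule
are conventions, two orders are *equal* iff they agree up to rotation and
reflection (reverse the sequence, flip every orientation); `canonicalize()`
fixes rotation at an anchor (*cox1* by default) and resolves reflection by
forcing the anchor to `+`.  Adjacencies are unordered pairs of oriented gene
extremities (each gene has a 5′ tail and 3′ head), so the breakpoint
distance is orientation-aware: inverting a single gene in place creates two
breakpoints.

## Annotation statistics

The signed gap between consecutive features is
`downstream start − upstream end − 1`: positive values are intergenic
spacers, negative overlaps.  The circular closing pair (last feature → first
across the origin, 1 bp here) is emitted as a flagged record but excluded
from the scalar summaries, because printed annotation tables — whose
intergenic column the summaries must reproduce — carry no closing entry.
With that convention the shipped table yields exactly the published
accounting: 351 bp of spacer in 19 regions (1–174 bp), 27 bp of overlap in
5 locations with two 7 bp maxima (*nad4L*/*nad4* and *trnH*/*nad5* — the
source text names *trnL1*/*rrnL*, but its own coordinates put a 15 bp spacer
there, so the coordinate-derived answer is used).  A useful internal check:
the signed gaps (closing gap included) plus the feature lengths always sum
to the genome length.

Strand asymmetry uses the standard skews `(A − T)/(A + T)` and
`(G − C)/(G + C)`.  `skew_from_percentages()` applies the formula to printed
percentages without re-normalising, which is the honest way to compare
against a published table; note that rounding in such tables can shift the
third decimal of a recomputed skew by one unit.

RSCU is the observed codon count divided by its family-uniform expectation.
Families follow the invertebrate mitochondrial genetic code (NCBI table 5)
*split by codon box*: Leu into UUR/CUN and Ser into UCN/AGN.  This matches
the separate tRNA isoacceptors (trnL1/trnL2, trnS1/trnS2) and the way
mitogenome codon-usage tables are conventionally reported; under plain
amino-acid grouping Leu would form a single 6-codon family and Ser (with AGR
coding Ser in this code) an 8-codon one.  Stop codons form their own family
and are excluded from the RSCU figure.  Truncated terminal stops (`TA`,
`T`) are stored verbatim and trimmed before codon counting; their completion
to `TAA` by polyadenylation is biology, not computation.

## The TD(N\\R)L + RC model

The model composes five operators:

1. **Whole-genome tandem duplication** — the circular genome becomes a
   head-to-tail dimer of two tagged monomer copies.  The dimer is
   linearised at the origin of the input order; the shipped ancestral order
   starts at *trnI*, so the monomer boundary falls at the CR–*trnI*
   junction, the layout of the inferred intermediate.
2. **Polarity-determined (non-random) loss** — from one monomer all genes of
   one transcriptional polarity are deleted, from the other all genes of the
   opposite polarity, so each gene survives exactly once and each monomer is
   single-polarity.
3. **3′–3′ recombination join** — the 3′ end of monomer 1 (3′ taken with
   respect to each monomer's majority polarity) is ligated to the 3′ end of
   monomer 2: monomer 2's gene sequence is reversed and each of its genes'
   polarities flipped.  This is the step that makes the product
   single-stranded, and it holds for *any* input with mixed polarities — a
   property the suite verifies on 1000 random orders.
4. **TDRL translocation** — a circular segment is duplicated in tandem and
   one copy of each duplicated gene deleted.  TDRL can move genes but never
   flips an orientation.  The *trnT* event duplicates the span
   *trnT* … *nad4* (14 genes) and keeps *trnT* from the second copy,
   producing … *nad4L*, *nad4*, *trnT*, *trnH* …  The source text locates
   the event "between *nad4L* and *trnP*", which names the landing
   neighbourhood; the duplicated span necessarily also covers the genes
   *trnT* crosses.
5. **Segment reversal** — `invert_segment()` reverses a segment and flips
   its orientations, the signature of a replication-mediated inversion.
   The final *trnC–trnQ* event cannot be such an inversion: a strict
   inversion of the post-join segment (*trnC*, *trnQ*) yields
   (−*trnQ*, −*trnC*) and would break the observed all-(+) arrangement,
   because a position swap with polarity preserved is mathematically a
   transposition.  The event is attributed to the recombination model, so
   the shipped scenario encodes it as a *polarity-preserving* reversal
   (`inversion` event with `polarity = "preserve"`, `invert_segment(...,
   flip = FALSE)`): an excision and re-insertion in which each gene keeps
   its transcriptional polarity.  This is the package's design resolution of
   a genuine ambiguity in the verbal model description.

Replaying the shipped scenario from the ancestral arthropod ground pattern
(the *Limulus* arrangement) reproduces the observed gene order exactly, with
strand homogeneity 1.0 from the join step onward:

```{r replay}
res <- replay(polydesmus_scenario())
tidy(res)
glance(res)
```

The published intermediate gene lists carry typographic anomalies — *nad4L*
printed where *nad1* must stand, and *trnY* missing from the second monomer
list — which are preserved verbatim in flagged fixture files
(`monomer1_printed.order`, `monomer2_printed.order`, `final_printed.order`,
readable with `strict = FALSE`); the executable scenario takes *trnY* as
surviving on monomer 2, and replay verification targets the
coordinate-derived order, not the printed list.  `diff_orders()` documents
the printed list's anomalies directly.

## Single-event search

`enumerate_tdrl()` and `enumerate_inversions()` are deliberate brute force:
every (segment, loss-pattern) pair within a span bound, every contiguous
segment.  Candidates are deduplicated by resulting canonical order because
many loss patterns give one biologically indistinguishable product.  The
TDRL candidate space grows as `n · Σ 2^s`, hence the default span bound of
6 genes; exhaustive runs should stay at toy sizes.  Property tests plant a
random single event in a random order and verify the enumerators recover
it (500 seeded trials).

## Synthetic data: the stated world

`polydesmus_genome_spec(seed)` mirrors the shipped annotation — lengths,
strands, codons, and the exact signed gap plan — with per-partition target
compositions from the published composition table (mitogenome A 25.3 / T
40.9 / G 24.2 / C 9.7, and the PCG, tRNA, rRNA, CR rows likewise).  Printed
rows round to one decimal and so sum to 100 ± a few tenths; the generator
accepts that and renormalises internally.  Composition is realised by exact
count allocation (largest-remainder rounding, then a seeded shuffle), so a
partition's realised composition deviates from target only through rounding
and the codon overwrites — comfortably within the documented ±1% for
partitions of 1 kb and more.  Seeds are mandatory everywhere; there is no
wall-clock default, so fixtures are reproducible by construction.

What the generator does *not* emulate: codon structure beyond the start/stop
codons (synthetic PCGs contain internal stops), tRNA/rRNA secondary
structure, control-region motifs, and any real substitution process.  A
green test on synthetic data therefore establishes the *statistical and
combinatorial* contracts (accounting identities, skew formulas, RSCU
definition, operator algebra, replay determinism) — not agreement with the
real MZ677220 sequence, whose per-partition percentages and codon counts
are deliberately out of scope.

`evolve_order()` draws inversion/TDRL/TDNL+RC events with stated
probabilities, records every drawn parameter explicitly in the emitted
history, and guarantees that replaying the history reproduces the final
order — the suite checks this over 100 random specifications.

## Numerical and degenerate-input choices

Skews with a zero denominator are reported `NA`, not 0.  Ambiguous bases
(N) are excluded from composition denominators.  An empty monomer is legal
and joins to a plain circularisation of its partner.  Loss patterns must
keep exactly one copy per duplicated gene; keeping zero or two is an error,
as is a polarity rule that is not a bijection of strands onto monomer
copies.  `nad1`'s length is derived from its coordinates (925 bp); the
conflicting printed alternative is ignored.  rRNA sizes follow the
coordinates (rrnS 808 bp, rrnL 1054 bp), not the prose that swaps them.
The PCG partition length is the coordinate sum (10,997 bp); the prose
figures "9882 bp" and "5012 codons" are irreconcilable with the table and
are not used.

## Limitations

The scenario machinery verifies a *given* event list; it does not infer
minimal scenarios (the search space is exponential — only single-event
enumeration is provided).  Breakpoint distance is the only gene-order
metric; inversion/DCJ distances and common intervals are out of scope, as
are phylogenetic inference and divergence dating.
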