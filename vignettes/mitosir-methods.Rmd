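---
title: "Methods: repeat landscapes and gene-order evolution in small circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscapes and gene-order evolution in small circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosir)
```

# Scope and model

mitosir analyses the architecture of small circular genomes — designed
around placozoan-style mitochondrial DNA, whose 23–44 kb chromosomes are
inflated by proliferating hairpin-forming repeats. The package covers
five connected procedures: maximal inverted-repeat (SIR) detection and
family classification, tandem-repeat detection by wraparound-alignment
scoring, sliding-window GC / dotplot / p-distance profiles, partitioning
into coding and intergenic regions, and signed circular gene-order
comparison with conserved-section merging and tree-edge change mapping.
A synthetic-genome generator with planted truth closes the loop so that
every stage can be validated end to end.

# Inverted-repeat detection

## Definition

A hit is a pair of equal-length arms (the *stem*) around a spacer (the
*loop*): arm one at `[i, i+L)`, arm two at `[i+L+g, i+2L+g)`, where the
second arm is the reverse complement of the first with at most
`max_mismatch` mismatched base pairs. Pairing is Watson–Crick only
(A–T, C–G); `N` never pairs. Defaults: `min_stem = 6`, `max_stem = 100`,
`max_loop = 10`, `max_mismatch = 1` — the classic settings for hairpin
scans of animal mitogenomes. The published parameter "maximum length 100"
is interpreted as the maximum *arm* length, matching the semantics of the
classic palindrome-scanning tools this reproduces. Downstream selection
keeps hits with `stem > loop` (strict), classifies each kept hit by the
six loop-adjacent bases of the left arm, and calls a hexamer family a
"repeat" type at ≥ 10 occurrences in a single genome, applied in that
order (selection first, then classification and thresholding).

## Maximality and tie-breaking

Counting all palindromes under a mismatch budget is ill-posed unless
"maximal" is pinned down. A hit is reported iff it cannot be extended:

* **outward** — growing both arms away from the loop by one base — while
  keeping mismatches ≤ `max_mismatch`, `L ≤ max_stem`, staying inside the
  sequence (and, on circles, inside one genome circumference);
* **inward** — growing both arms into the loop (loop shrinks by two,
  requires `g ≥ 2`) under the same constraints.

When an extension is possible only by spending a mismatch, the longer hit
is the one reported. One hit is emitted per distinct maximal span;
overlapping hits at different centres are all reported (no greedy
masking). All pairs of a candidate lie on one anti-diagonal of the
sequence-versus-complement matrix, so the compiled scan walks each
anti-diagonal once, growing arms greedily outward from each admissible
innermost pair; a hit is suppressed exactly when its inward extension is
admissible, because the extended hit is generated from the same diagonal.
The test suite checks this against an independent brute-force enumerator
over every (loop position, loop length, stem length) triple.

Two consequences worth knowing. First, under a mismatch budget a
*perfect* hairpin is usually not maximal — the scanner legitimately
extends it by spending the unused budget on a flanking non-pairing pair.
Second, a hairpin is (up to its mismatched pairs) its own reverse
complement, so at `max_mismatch = 0` the family multiset is invariant
under scanning the opposite strand; the scan therefore runs on the
deposited strand only. The left-arm classification convention is a
declared choice: the published family tables list both `AAAAAA` and
`TTTTTT` as distinct classes, which proves the classification is arm- and
strand-specific, but not which arm was used; we fix the left (5′) arm on
the deposited strand.

## Circular scanning

Circular genomes are scanned on an unrolled extension of the circle long
enough to hold any admissible span plus one outward-extension probe; hits
are de-duplicated by keeping left-arm starts in a single fundamental
window. Spans are capped at one circumference. Coordinates of
origin-crossing hits are reported on the unrolled circle (positions past
the genome length wrap), keeping intervals half-open and arithmetic
unambiguous.

# Tandem repeats

The detector is deliberately a *simplified* scanner sharing the published
scoring weights (match +2, mismatch −7, indel −7, minimum score 50,
maximum period 500, 80 %/10 % match/indel probabilities), not a
re-implementation of the classic probabilistic tool — whose heuristics
are version-dependent. Candidate periods are seeded by exact 8-mer
recurrence at distance ≤ 500; arrays grow by period-consistency with a
maximal-prefix-score cut (+1 per consistent base, −3 per inconsistent);
the consensus is a per-phase majority vote; the reported period is the
smallest divisor of the seeded period whose cyclic consensus explains the
array at ≥ 80 % identity *and* still clears the score gate; the score is
a wraparound dynamic-programming alignment (free starting phase, cyclic
column wrap via a two-pass sweep) of everything beyond the first copy, so
a perfect array of span *s* and period *p* scores `2(s − p)` — e.g.
20 copies of `ACGT` score 152 and 7 copies score 48, below the gate.
Arrays need ≥ 1.9 copies. Overlapping reports of one array are merged to
the highest-scoring period. Because the growth cut maximises a running
score, mutated bases at the extreme edge of an imperfect array can be
trimmed from the reported span; recovery checks therefore ask for ≥ 90 %
span coverage with bounded overhang rather than byte-equal boundaries.

# Profiles and distances

GC content is computed as (G+C)/(non-N) in 100-bp windows anchored at
0, 10, 20, … On circular genomes windows wrap, giving `ceiling(n/10)`
windows; anchoring at position 0 of the deposited sequence is a declared
convention. All-N windows are missing values. Dotplots mark window pairs
scoring ≥ 100 under +5/−4 over 50-bp words — the standard DNA scoring of
the classic dotplot tools, which publish only window and threshold.
p-distances use pairwise deletion: a site contributes to a pair only when
both sequences carry an unambiguous base, and the per-pair compared-site
count is reported alongside the proportion of differences; the
implementation is cross-checked in the tests against `ape`'s raw
distance with pairwise deletion.

# Region accounting

Coding is the union of exonic spans of protein genes, rRNA fragments,
tRNAs and annotated ORFs of unknown function (ORFs are gene-like in the
annotations even though they are dropped from gene orders). Group I/II
intron spans are reported as their own classes but counted inside the
intergenic total: published per-genome tables show coding + intergenic
equal to the whole-genome size while listing introns separately, and this
accounting reproduces that identity structurally (coding + intergenic =
genome length is asserted on every fixture). Overlaps resolve with
precedence coding > intron > intergenic. Repeats are assigned to a region
by full containment; boundary-spanning elements are tallied to the class
holding their midpoint, which keeps two-way splits additive. Because the
split between coding and intergenic depends on annotation conventions
(whether ORFs and tRNAs count as coding), per-accession coding/intergenic
totals are treated as convention-dependent and are not replicated
numerically.

# Gene orders and sections

A gene order is the signed circular sequence of annotated gene fragments
(each annotated fragment — e.g. the two rRNA pieces `16Sa`, `16Sb` — is
its own unit), omitting ORFs of unknown function and introns. Two units
link when, in *every* genome containing both, they are adjacent with the
same relative orientation; `−b,−a` in one genome matches `+a,+b` in
another (signed-reversal equivalence), because orientation changes are
tracked as real events. A unit private to a single genome is a singleton
section by definition. Connected components of the link relation are the
conserved sections; a fully conserved circle collapses to one section
with a deterministic declared break. Sections are labelled `A`, `B`, …
by position in the first input genome. The breakpoint distance between
two orders is the number of signed circular adjacencies of one absent
from the other after restricting to shared units — a semimetric that is
zero exactly on rotation/reflection-equivalent orders.

Change mapping onto a tree is descriptive, not ancestral reconstruction
(deliberately: ancestral gene orders are left unresolved): for each edge,
an adjacency present in every descendant tip and no other tip is reported
as gained below that edge, and conversely as lost. At the root of a
rooted binary tree the two child edges describe complementary
bipartitions, so a single change below one of them appears mirrored on
both — readers should interpret those two edges jointly. Changes at
polytomies are reported on the polytomy's edges and flagged.

# The synthetic generator

`generate_genome()` emulates the statistical structure of a
placozoan-like mitogenome: a circular chromosome (default 36 kb, the
cohort-average size; background GC 0.41, the cohort mean) carrying 12
protein-coding genes (cox1 and nad5 fragmented by group I/II introns), a
fragmented large rRNA, 12S, 24 tRNAs and one ORF, with intergenic gaps
sized by a random allocation of the slack. Planted elements:

* **Hairpins** — default plan: `GGCGCC` ×12, `GGATCC` ×10 (GC-rich
  stems), `AAAAAA` ×10 (AT-rich), stems 6–10 bp, loops 0–3 bp, one
  mismatched pair each, placed in intergenic gaps ≥ 150 bp apart (150 bp
  is a fixture constraint preventing hit interaction, not a detector
  assumption). Each plant carries *exactly* the scan's mismatch budget
  and non-pairing guard bases at its flanks and loop ends; this is what
  makes exact-coordinate recovery well-posed — a planted perfect hairpin
  would be legitimately extended by a budget-spending scan, so plants
  with fewer mismatches than the budget are recoverable only up to
  boundary slack.
* **Tandem arrays** — default periods 12/30/90 bp with 8/5/3 copies at
  identity 1/1/0.97, with period-breaking guard bases at both flanks.
* **Rearrangements** — `evolve_along_tree()` applies inversions and
  translocations of whole gene-unit spans along each root-to-tip path of
  a given Newick tree; sequence, annotations and planted-element truth
  move (and flip) together, and a symbolic gene order is maintained
  independently of coordinates as per-tip truth. Events are
  content-preserving: genome length and gene complement are invariants.

What the generator does **not** emulate: codon or dinucleotide structure
(background is i.i.d. per base), substitution-model sequence evolution,
selection, intron splicing, or the mosaic GC heterogeneity of real
intergenic spacers. Passing recovery tests therefore demonstrates the
correctness of the detectors' geometry, scoring and bookkeeping — not
their behaviour on the full complexity of real mitogenomes, where
annotation conventions and nested repeat structure add ambiguity.

# Summary statistics

Cohort tables report per-column means and **population** standard
deviations (divisor *n*): the published intergenic-size spread is
reproduced by divisor-*n* on the printed sizes, not divisor-(n−1), so the
convention is adopted and documented. Group comparisons are one-tailed
Welch's *t* (Welch–Satterthwaite degrees of freedom; both-groups-constant
with equal means returns p = 0.5 by convention) and a one-tailed
Mann–Whitney U with exact enumeration of all `choose(n, n_a)` assignments
for combined n ≤ 12 (ties handled exactly) and the tie-corrected,
continuity-corrected normal approximation otherwise. The printed summary
of the 14 placozoan mitogenomes ships as a plain-text table
(`placozoan_summary()`) so these statistics are reproducible offline.

# Numerical choices and problem sizes

* Coordinates are 0-based half-open internally (BED-compatible); GenBank
  I/O converts from 1-based inclusive, resolves `join`/`complement`
  locations into multi-part stranded features ordered along transcription,
  and represents origin-wrapping features as two parts of one feature.
* Hits sort by left-arm start, then stem length descending; section and
  roster orderings are deterministic, and `run_cohort()` output is
  byte-identical across reruns on identical inputs.
* Validation sizes were chosen to exercise every code path at desk scale:
  oracle equivalence on 104 random sequences of 150–2,000 bp; 512 planted
  hairpins and 48 planted arrays across 16 seeded 36-kb genomes; a
  simulated 14-tip cohort with six planted events; 30 random signed
  circular permutations for breakpoint checks.

# Known limitations

* The tandem detector shares the published scoring weights but not the
  original tool's probabilistic model; its counts are not comparable to
  published tandem-repeat tallies and are excluded from replication.
* Exact-coordinate hairpin recovery presumes budget-consuming plants (see
  above); real hairpins bordered by chance-pairing bases are reported
  with extended, still-maximal spans.
* Whether published scans were run on one or both strands is not
  documented; the single-strand default is justified by the strand
  symmetry of hairpins but may differ for mismatch-carrying hits.
* Section merging assumes each unit has at most two conserved neighbours;
  conflicting adjacency data demote the affected units to singletons with
  a message rather than producing non-linear sections.
* The edge-change report is a presence/absence description; it does not
  infer ancestral arrangements or event counts.
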