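---
title: "Reconstructing recombining plant mitochondrial genomes as terminus graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing recombining plant mitochondrial genomes as terminus graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitograph)
```

## The model

Plant mitochondrial genomes carry repeated sequences in two copies whose
recombination generates alternative genome arrangements. An assembly of
such a genome is therefore not a sequence but a *graph*: unique contigs,
repeat contigs present once but traversed twice, and junctions where
contig ends overlap exactly (k−1 bp for a De Bruijn assembler with k-mer
size k).

`mitograph` models this as an undirected **terminus graph**. Every contig
contributes two vertices — its head (5′ end of the stored strand) and
tail — joined by a contig edge; an exact end overlap between two contigs
is an overlap edge between the touching termini. The graph itself carries
no direction: orientation exists only in *walks*, as (contig, orientation)
pairs, and reverse complementing is a view, never a sequence mutation.
Coordinates are 0-based half-open internally; the tabular alignment
boundary converts from 1-based inclusive, with `s_start > s_end` encoding
a minus-strand hit.

### Strand rule

An end-to-end hit joins termini according to its strand: a plus-strand hit
joins opposite sides (tail–head or head–tail, by which ends the hit
touches), a minus-strand hit joins equal sides (tail–tail or head–head).
This is the only assignment under which emitting a walk across the
junction reproduces the underlying sequence, which is how the package's
round-trip tests pin it down.

## Graph construction

`detect_end_overlaps()` is a built-in exact matcher: De Bruijn contigs
overlap neighbours exactly, so identity is 100 % and the maximal shared
end block suffices. External aligner output (12-column tabular) is
accepted for noisy data with a configurable identity floor.
`filter_end_to_end()` keeps hits of at least `min_overlap` (default
**49 bp**) whose aligned interval lies within `end_window` (default
**300 bp**, 600 bp for assemblers padding contig ends) of a contig end on
*both* contigs. Hits spanning an entire contig are containments: they are
excluded from adjacency (a contained contig is not an end-to-end
neighbour) but kept for curation, which removes contained fragments
shorter than twice the assembly k-mer.

Graph growth starts only from **high-confidence contigs** — length
strictly over 1 kb and coverage strictly over 3000× (or recovery by all
other assemblers at 90 % of bases under e-value 1e−40, in consensus
mode) — and proceeds breadth-first until no overlap reaches a new contig.
Low-confidence contigs thus enter only when connected to the
high-confidence backbone; unconnected contamination never does.

A self overlap (suffix of a contig equal to its own prefix) is stored and
flagged as a circular candidate rather than rejected: it is exactly what a
single-contig circular genome produces.

## Curation

Every curation step is an explicit, logged action, so a curated graph is
reproducible by replaying the log: plastid-flagged contigs adjacent to the
non-plastid subgraph are removed (disconnecting the plastid component);
contained fragments below 2·k and contigs below a coverage floor are
pruned; scripted `remove_edge` / `remove_contig` / `split_contig` /
`trim_contig` actions handle misassemblies. Two defaults are the package's
own, documented choices where the method description is qualitative: a
contig is called plastidial when ≥ 0.8 of its bases are covered by
plastid-reference hits, and the low-coverage floor defaults to 10 % of the
median graph-contig coverage. Automatic re-inspection of raw reads is
deliberately out of scope — sequence corrections are explicit script
actions.

## Repeats: double forks and CRC variants

A repeat contig's termini each touch at least two alternative **termini**
of non-repeat contigs — a *double fork*. Counting termini rather than
contigs matters: with an inverted repeat flanked by a single unique contig
on one side, both alternatives are the two ends of the same contig, and
the fork is still real. Contigs forked on one side only are reported
separately; they are not repeat pairs but may force a second traversal
during reconstruction.

The four head × tail combinations of a 2×2 fork are the CRC
(contig-repeat-contig) variants. The canonical CRC key is the
lexicographically smaller of `left,repeat,right` and its reversal, so a
junction and its reverse complement count as one — direct and inverted
junction readings aggregate identically in stoichiometry.

Repeat role is assigned *structurally*; `scan_repeats()` (maximal exact
repeated blocks ≥ 50 bp on both strands, seed-and-extend) is the
genome-wide cross-check, and `classify_repeat_sizes()` labels repeat
lengths SSR < ISR < LSR by 1-D k-means with three centres. k-means uses 25
restarts under the caller's seed because 1-D k-means on a handful of
points is initialization-sensitive; tests verify the result against an
exhaustive contiguous-partition optimum (optimal 1-D clusters are
contiguous in sorted order). Fewer than k distinct values is a documented
error, not a silent merge.

## Stoichiometry

Contig chains — maximal runs of non-repeat contigs between repeat pairs —
anchor spanning reads whose insert exceeds individual contig lengths. A
chain of a single contig immediately bracketed by repeats is flagged: it
offers less anchoring sequence, deflating that repeat's counts (visible as
a low mate-pair usage factor).

**Mate pairs.** A pair supports a CRC variant when its two mates (on
different contigs) lie in the chains attached to the variant's head- and
tail-side fork termini. Two refinements beyond chain membership were
needed, and are this package's documented design choices. First, each fork
branch is anchored to a specific chain *end*: with an inverted repeat both
head-side branches fall into the same chain, and only the end
distinguishes them. Second, the implied molecule span (distance of mate 1
from the branch end + repeat length + distance of mate 2) must not exceed
`max_span` (default 6500 bp, matching a 5 kb insert library); this rejects
pairs that merely span a junction in the chain's interior. A pair matching
more than one variant of a repeat is dropped as ambiguous for that repeat;
whether it may support two different repeats simultaneously is not
constrained (it brackets each independently).

**Long reads.** Per-read alignment hits are sorted by read start, floored
on hit length (> 100 bp; 170/180 bp dialects serve cross-mapping
diagnostics), collapsed over consecutive identical contig ids, and
retained only for reads aligning almost fully (covered fraction ≥ 0.99 —
the numeric reading of "fully aligns", configurable), at ≥ 95 % identity,
and ≥ 5 kb long; sub-threshold alignment is classified nuclear-like. A
chain supports a variant when the variant's id triple occurs as a
contiguous subsequence in either direction.

**Summary.** Shares are integer-rounded percentages of the repeat's read
sum; the usage factor is the read sum divided by the smallest read sum
among evaluated junction candidates, rounded to one decimal **half away
from zero** — with a read sum of 31 715 over a divisor of 21 865 this
yields 1.5, which banker's rounding would miss. The divisor can be
overridden because dismissed false-positive candidates may define a
smaller minimum than the tabulated repeats. A repeat is *dominant* when
its top two shares are ≥ 25 % each and its bottom two ≤ 15 % each (a
threshold that fits every row of the shipped count fixture), else
*balanced*.

## Traversal

A closed oriented walk is one circular genome configuration; its length is
the step lengths minus the junction overlaps (the closing junction
included). The **master configuration** visits every contig with each
repeat traversed at least twice. When no such walk exists at base budgets
(repeat ×2, others ×1), budgets escalate — first non-repeat contigs to
two traversals, then repeats to three — and the walk with the fewest total
steps is chosen, so the set of contigs exceeding base budget is minimal
and is reported. This staged-uniform escalation replaces a per-element
iterative deepening: it is simpler, deterministic, and the fewest-steps
selection yields the same observable outcome on one-sided-fork and
thrice-traversed-repeat cases.

**Enumeration** of all sub-genomes is exhaustive backtracking under
budgets (repeat ≤ 2, others ≤ 1) with the start rule that a walk begins
and ends at the same vertex through *different edges* — read as: the first
and last traversed edges are distinct physical edges, which excludes only
the single-step self-loop closure (master reconstruction, whose rule has
no such clause, allows it). Walks are deduplicated by canonical form: the
lexicographic minimum over all rotations of the oriented step sequence and
of its reversed-complement. Neighbours are explored in lexicographic
terminus order; there is no randomness anywhere in traversal. Enumeration
beyond `max_walks` (default 10 000) is an explicit error, never silent
truncation.

Classification follows the configuration definitions: *master* — all
repeats twice and every other contig once; *small sub-circle* — no repeat
twice and some, but not all, other contigs once; *intermediate
sub-circle* — every repeat at least once and some, but not all, other
contigs once. A walk satisfying both of the last two reads as small (it
lacks a second repeat traversal).

Recombination operates on walks: at a direct repeat (both mates traversed
in the same orientation) the walk splits into two flank-exchanged
sub-circles with total length conserved; at an inverted repeat the
inter-mate segment is reversed and complemented in place. Requesting the
wrong mode for the mates' orientations is an error explaining why.

## The synthetic generator

`plant_genome()` emulates the study conditions the method targets: a
circular genome of 50–450 kb (the published organelle is ≈ 400 kb), unique
segments of ≥ 1500 bp (so unique contigs clear the high-confidence length
bar at the mitochondrial coverage tier), repeats planted twice with
lengths drawn from the LSR (825–1625 bp), ISR (239–479 bp) and SSR
(150–200 bp) ranges observed in that genus, arranged so every repeat's
flanks differ (a proper double fork). `fragment_to_contigs()` reproduces
De Bruijn fragmentation: unique contigs carry k−1 bp of the preceding
element at their head and of a following repeat at their tail, each repeat
is one forward-strand contig, and every junction shares exactly k−1 bp.
Coverage tiers default to 5000× mitochondrial, 500× plastid, 30× nuclear.

`simulate_spanning_reads()` draws molecules proportional to abundance ×
admissible start positions (so junction counts recover abundances without
length bias), with Normal(5000, 300) mate-pair inserts, 150 bp mates, and
log-normal long-read lengths (meanlog log 8000, sdlog 0.25, putting a few
percent under the 5 kb filter so the retention boundary is exercised).
Placements are exact truth placements; what the generator deliberately
does **not** emulate is mapping noise, chimeric reads, heteroplasmy
gradients, or sequencing error beyond a uniform identity stamp — so
passing tests show the algorithms are correct on clean signals, not that a
particular mapper's artefacts are handled.

One consequence of real recombination appears directly in testing: once a
genome carries an inverted pair or several repeat pairs, multiple master
configurations of identical length coexist, and reconstruction returns the
canonical one. Round-trip tests therefore assert that the *planted*
arrangement is among the enumerated masters and emits the planted sequence
exactly — the graph cannot, and should not, prefer one arrangement without
read evidence (which the stoichiometry module supplies separately, and
which is intentionally never merged into enumeration).

## Problem sizes and numerical choices

The test suite and the acceptance script run planted genomes of 50–450 kb
with 1–4 repeat pairs (≤ 14 contigs), 100-seed enumeration-oracle
sweeps on graphs of ≤ 8 contigs, and read simulations of 10⁴ mate pairs
and 2×10³ long reads — sizes at which exhaustive oracles (naive DFS over
closed walks, contiguous-partition k-means, brute-force window scans)
remain feasible, which is what makes the checks independent. Degenerate
inputs are handled explicitly: zero-read repeats are flagged rather than
divided by; equal-length repeat sets refuse k-means; duplicate overlap
edges keep the longest hit deterministically (hits processed in
lexicographic order); an all-plastid graph warns and empties.

## Limitations

- Linear genome forms, lariats and branched intermediates are out of
  scope: enumeration is over closed walks only.
- Exact-match repeat scanning does not reproduce the scoring subtleties of
  dedicated repeat finders; diverged repeat copies below 100 % identity
  are found only via external aligner input.
- Published full-genome endpoints (curated contig counts 21/38/45, the
  70 = 44 + 6 + 20 configuration census, master sizes 408 744 / 424 132 /
  449 216 bp) require the deposited assemblies and replayed manual
  curation; `external_validation_targets()` documents them, and nothing in
  the default suite claims to compute them.
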