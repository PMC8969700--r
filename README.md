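# mitograph

Graph-based reconstruction of recombining plant mitochondrial genomes.

## The problem

Plant mitochondrial genomes (PMGs) are structurally fluid: repeated
sequences present in two copies mediate homologous recombination, so a
single "master circle" coexists with sub-genomic circles carrying
alternative arrangements. Short-read assemblies of such genomes fragment at
the repeats, and conventional assemblers either pick one arrangement or
refuse to circularize at all. `mitograph` treats the assembly as what it
is — a graph — and makes the heterogeneity explicit:

1. **Terminus graph construction.** Each contig contributes two vertices
   (head/tail termini) joined by a contig edge; exact end overlaps between
   contigs (k−1 bp for a k-mer assembler) become undirected overlap edges.
   All-vs-all hits are filtered to significant end-to-end hits (≥ 49 bp,
   within 300 bp of a contig end on both sides), and the graph is grown
   breadth-first from high-confidence contigs (HCCs: length > 1 kb and
   coverage > 3000×), so low-confidence contigs enter only when connected.
2. **Double forks and CRC variants.** A recombinogenic repeat pair (RRP)
   collapses into one contig whose both termini each touch ≥ 2 alternative
   termini — a *double fork*. Its four head × tail combinations are the
   contig-repeat-contig (CRC) junction variants. Repeat lengths are
   classified SSR < ISR < LSR by 1-D k-means (k = 3).
3. **Stoichiometry.** Large-insert mate pairs and long reads that bracket a
   repeat are counted per CRC variant, using *contig chains* (maximal runs
   of non-repeat contigs between RRPs) to anchor mates. Per repeat this
   yields counts, integer percentage shares, a read sum, and a **usage
   factor** (read sum / smallest read sum across evaluated junction
   candidates), plus a balanced/dominant classification.
4. **Traversal.** The master configuration is a closed walk visiting every
   contig with each repeat traversed twice; all sub-genome configurations
   are enumerated by budgeted backtracking (repeat ≤ 2, others ≤ 1; start
   and end at the same vertex through different edges) and classified as
   master configuration, small sub-circle, or intermediate sub-circle.
   Direct recombination splits a walk into two flank-exchanged sub-circles;
   inverted recombination flips the inter-mate segment. Walk sequences are
   emitted with each junction overlap trimmed once.
5. **Synthetic truth.** A generator plants circular genomes (50–450 kb)
   with direct/inverted repeat pairs, fragments them into contigs with
   exactly k−1 bp end overlaps and tiered coverage
   (mitochondrial ≫ plastid ≫ nuclear), and simulates mate pairs (5 kb
   inserts) and long reads, with exact truth placements — every stage is
   testable offline.

## Worked example

```r
library(mitograph)

g <- plant_genome(n_unique = 4,
                  repeat_specs = list(repeat_spec(length = 1000,
                                                  mode = "direct")),
                  seed = 42, total_length = 60000)
contigs <- fragment_to_contigs(g)
flt     <- filter_end_to_end(detect_end_overlaps(contigs), contigs)
graph   <- build_graph(contigs, flt$adjacency, select_hccs(contigs))
forks   <- detect_double_forks(graph)
master  <- reconstruct_master(forks$graph)
master
#> mito_walk (master_configuration): r1+ u01+ u02+ r1+ u03+ u04+ | 60000 bp
same_circular_sequence(emit_sequence(forks$graph, master), g$sequence)
#> [1] TRUE
walks <- enumerate_subgenomes(forks$graph)
table(vapply(walks, `[[`, character(1), "kind"))
#> master_configuration      small_subcircle
#>                    1                    2
```

The planted 60 kb circle with one direct repeat pair is recovered exactly:
one master configuration (repeat traversed twice, every unique contig once)
plus the two small sub-circles a direct recombination event would excise.

For stoichiometry, the shipped junction-count fixture
(`inst/extdata/oelata_crc_counts.tsv`, an *Oenothera elata* 5-repeat count
matrix for a mate-pair and a long-read dataset) summarizes to usage factors
1.5, 2.8, 2.7, 2.8, 2.2 (mate-pair, divisor 21 865) and 2.2, 2.8, 2.8,
2.7, 1.7 (long-read, divisor 665), every repeat classified *dominant* —
two of the four junction variants carry nearly all spanning reads.

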