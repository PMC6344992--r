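# DendriteLoc

Sub-cellular RNA localization analysis for paired soma/dendrite RNA
sequencing of single neurons.

Neurons transport specific mRNAs into their dendrites for local
translation, a prerequisite of long-lasting synaptic potentiation. When
the soma and the dendrites of the *same* neuron are harvested and
sequenced separately, each cell yields a paired sub-cellular
transcriptome, and dendritically localized RNAs can be identified as
those consistently enriched or present in the dendritic compartment
across cells. Because many genes express alternative 3′UTR isoforms — and
3′UTRs carry the cis-elements that direct transport — localization must
be resolved at the isoform level as well. `DendriteLoc` implements this
analysis end to end for anyone working with paired-compartment
single-cell data (16 cells, 32 samples in the reference design):

- **Feature construction** — union 3′UTRs per gene for gene-level
  quantification, and non-overlapping "last 500 nt" terminal windows per
  3′ isoform (3′ ends closer than 500 nt are merged), built on
  GenomicRanges from GTF/GFF3 or BED12 annotations; isoform pairs are
  classified **ALE** (alternative last exons, disjoint UTRs) or
  **tandem** (alternative polyadenylation, overlapping/abutting UTRs).
- **Quantification** — strand-specific read counting into these features,
  median-of-ratios size factors, and detection filters.
- **Localization calling** — three complementary gene sets:
  - **deDend**: genes with higher dendritic than somatic expression under
    a paired exact Wilcoxon signed-rank test with Benjamini–Hochberg
    correction (q ≤ 0.05);
  - **consDend**: genes detected (≥ 1 read) in ≥ 90% of dendrite samples
    (15 of 16), constitutively present rather than concentration-enriched;
  - **isoDend**: genes whose distal fraction
    DF = distal/(distal + proximal) shifts consistently between
    compartments across cells — the per-cell statistic is
    ΔDF = DF_dendrite − DF_soma, tested with an exact signed-rank test at
    p < 0.1 over ≥ 5 valid soma–dendrite pairs (≥ 10 combined reads per
    member).
- **Variability analysis** — the dendritic read fraction f = d/(d+s) per
  cell, its cross-cell variance, and a binomial read-downsampling control
  (n = 10 reads, 1000 replicates) that separates biological localization
  variability from expression-level effects.
- **Motif and structure scanning** — G-quadruplex detection with the
  regex `([gG]{3,}\w{1,7}){3,}[gG]{3,}`, PWM scanning with per-motif
  log-odds thresholds scaled by the number of informative positions, and
  single-exemplar covariance models of the murine B1/B2 SINE hairpins
  (CYK dynamic programming in C++; bitscore cutoffs 50 and 35) — all
  tested for enrichment against **length-matched non-localized
  backgrounds** (first pool gene within 100 nt of the foreground 3′UTR
  length, one match counted per gene, Fisher's exact test).
- **Master-list integration** — cross-study observation tables of
  dendritic gene lists.
- **Synthetic data** — a generator for paired-compartment count matrices,
  annotations, and sequences with planted deDend/consDend/isoDend classes,
  negative-binomial noise, and dropout, so the whole pipeline is testable
  against known ground truth.

## Worked example

```r
library(DendriteLoc)

sc   <- simScenario(nGenes = 300, seed = 42)   # 16 cells, planted classes
sim  <- simulateCounts(sc)
sim$counts
#> PairedCountMatrix: 654 features x 32 samples ( 16 cells )
#>  compartments: dendrite 16, soma 16

gene <- estimateSizeFactors(aggregateToGene(sim$counts))
de   <- callDE(gene, genes = filterExpressed(gene))
table(de$set)
#> deDend deSoma     ns
#>     30    179     91

ips <- isoformRecords(sim$counts)
ips
#> IsoformPairSet: 227 multi-isoform genes; 220 tested; 43 isoDend

pref <- preferenceSummary(ips)
pref$table
#>         distal proximal
#> isoDend     24       19
#> rest        86       91
```

The 30 deDend calls recover the 30 planted dendrite-enriched genes (10×
concentration ratio); 43 of the 220 testable multi-isoform genes show a
consistent ΔDF shift and are called isoDend, and `preferenceSummary`
tabulates whether the dendrite-preferred member of each pair is the
distal or the proximal isoform (planted 50/50 here, hence an odds ratio
near 1).

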