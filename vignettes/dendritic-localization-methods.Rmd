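---
title: "Methods: calling dendritically localized RNAs and isoforms from paired sub-cellular sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling dendritically localized RNAs and isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DendriteLoc)
```

# The experimental design this package models

The unit of observation is a single neuron whose soma and dendrites were
harvested separately and sequenced as two libraries. With $n$ cells the
experiment yields $2n$ samples in $n$ matched pairs (the reference design
has $n = 16$). Pairing is what gives the analysis its power: the soma of
the same cell is the natural control for its dendrites, so per-cell
contrasts cancel the (large) cell-to-cell variation in absolute
expression. Poly(A)-selected amplification concentrates reads near
transcript 3′ ends, which is why all quantification features here are
3′UTR-anchored.

# Quantification features

**Gene level.** Each gene's feature is the interval union of all of its
transcripts' 3′UTRs (`buildUnionUtr`). Unioning avoids double counting
where isoform UTRs overlap and keeps one row per gene.

**Isoform level.** Each distinct transcript 3′ end is represented by the
terminal `window` nucleotides upstream of it in transcript orientation
(`buildIsoformWindows`, default 500 nt — matching both the 3′ coverage
bias and the need to normalize length differences between isoforms). 3′
ends closer than `mergeDist` (default 500 nt) along the genome are
chain-merged into one feature, because reads cannot be attributed
unambiguously between ends closer than the window itself. Three design
points were genuinely open and resolved as follows:

- *Merged-feature extent*: the union of the member ends' individual
  windows. This preserves "last 500 nt" semantics for every member end.
- *Overlap resolution*: after construction, the upstream (more 5′)
  feature is truncated at the downstream feature's boundary, which
  guarantees the final per-gene feature set is non-overlapping.
- *End-to-end distance*: measured along the genome on the annotated
  strand, ignoring introns — the simplest reproducible rule. Windows
  themselves, by contrast, are walked in spliced (transcript) coordinates
  so a window crossing an exon junction is split correctly; distances
  could be defined transcript-wise too, and the builder operates per
  `GeneModel` so either convention can be fed in.

Internally all intervals are `GRanges`/`IRanges` (1-based, closed), the
Bioconductor convention; GTF/BED conversions are delegated to
`rtracklayer`, and BED output remains 0-based through `rtracklayer::export`.

A pair of alternative 3′ ends is classified **tandem** when the two
full-length 3′UTRs overlap or directly abut (alternative cleavage and
polyadenylation within a terminal exon) and **ALE** otherwise
(alternative last exons; `classifyPair`).

# Counting and normalization

A read counts toward a feature when it overlaps it by at least one base
on the same strand. Reads touching features of more than one gene are
discarded as ambiguous; within a gene a read goes to the single feature
with the larger base overlap, ties resolved toward the more 3′ feature
(consistent with the 3′-biased chemistry). Library sizes are normalized
with median-of-ratios size factors (`medianOfRatios`): $s_j =
\mathrm{median}_i \, K_{ij} / (\prod_j K_{ij})^{1/2n}$ over features with
all-positive counts, falling back to total-count ratios (with a warning)
when no feature is positive everywhere.

# The three localization calls

**deDend.** Genes passing the detection filter (≥ 1 read in ≥ 16 of 32
samples) are tested with a paired exact Wilcoxon signed-rank test on
size-factor-normalized counts across the 16 (dendrite, soma) pairs, then
Benjamini–Hochberg corrected over the tested set. deDend = q ≤ 0.05 and
positive median paired difference; deSoma symmetric. A nonparametric
paired test was chosen as the built-in engine because it is
distribution-free, exact at n = 16, and self-contained; the result table
(`callDE`) exposes a standardized statistic so externally computed
negative-binomial GLM results can be substituted upstream of
`buildPool`/`matchBackground` if preferred. The signed-rank null is
enumerated exactly for up to 25 non-zero differences (midranked ties,
zeros dropped; doubled ranks make the convolution integral), with a
continuity-corrected normal approximation beyond.

**consDend.** Genes with ≥ 1 read in at least
$\lceil 0.9 \, n_\mathrm{dendrite} \rceil$ dendrite samples (15 of 16).
This catches constitutively present RNAs whose dendritic *concentration*
is not elevated — in single cells, bursting transcription and variable
transport make concentration a noisy signal of function.

**isoDend.** For each gene with ≥ 2 expressed isoform features, the top
two isoforms are chosen by summing per-sample read fractions across
samples with ≥ 10 gene reads (equal weight per sample, unreliable samples
skipped; ties by raw reads, then the more 3′ feature). The more 5′ of
the two is *proximal*, the more 3′ *distal*. Per sample,
$\mathrm{DF} = \text{distal}/(\text{distal}+\text{proximal})$, defined
only at ≥ 10 combined reads; per cell
$\Delta\mathrm{DF} = \mathrm{DF}_\mathrm{dendrite} -
\mathrm{DF}_\mathrm{soma}$ where both members are defined. Genes with
≥ 5 valid pairs are tested two-sided (exact signed-rank); isoDend =
p < 0.1. The threshold is deliberately permissive: the call asks for
*consistency of direction* across cells, not a large shift. The
preferred isoform is read off the median ΔDF sign (mean as tie-break —
the sign convention was open and this rule is symmetric and robust).

Two cohort-level contrasts accompany the isoDend call, and their
comparison sets were chosen so that the published cross-product odds
ratios are reproduced arithmetically from the printed cohort sizes
(both constructions are plain 2×2 Fisher tables and other comparison
sets can be formed from the same records):

- *Distal preference* (`preferenceSummary`): distal- vs
  proximal-preferred genes, isoDend set vs the **complement** of the
  tested set, non-isoDend preference taken as the sign of the mean ΔDF.
- *DF variability* (`dfVarianceComparison`): genes whose DF is more
  variable across soma samples than dendrite samples, isoDend set vs the
  **full** tested set. Because somas carry several-fold more reads, the
  soma DF is also re-estimated per sample from a Binomial(10, DF) draw,
  1000 times, to show the comparison is not a read-depth artifact.

# Localization variability and the downsampling control

Per cell, the dendritic read fraction $f = d/(d+s)$ (defined at ≥ 10
total reads); per gene, its cross-cell sample variance. Because the
sampling variance of $f$ scales with $1/(d+s)$, highly expressed genes
look artificially stable. `downsampledVariance` therefore re-draws each
cell at a common total of `nDown = 10` reads — $d^\ast \sim
\mathrm{Binomial}(10, f)$, i.e. sampling reads from either compartment
in proportion to their original frequencies — and reports the mean and a
nonparametric 2.5/97.5 percentile interval of the recomputed variance
over 1000 replicates. The percentile interval was chosen because it is
assumption-free at this replicate count. Cells with fewer than `nDown`
reads are excluded rather than sampled without replacement, keeping the
binomial model exact. All-or-nothing profiles ($f \in \{0,1\}$) are
fixed points of this procedure, a property the tests assert.

# Length-matched backgrounds and enrichment

Motif frequency scales with sequence length, so enrichment in localized
3′UTRs is always measured against a **length-matched** non-localized
background: the pool is the soma-enriched DE set minus all localized and
known-dendritic genes, ordered by descending somatic specificity
(|standardized DE statistic|); for each foreground gene the first pool
gene within 100 nt of its 3′UTR length is taken (without replacement),
falling back to the closest remaining length, earlier pool position
winning ties. Enrichment counts **one match per gene** and reports the
hit-fraction fold, the cross-product odds ratio (`Inf` with a zero
off-diagonal cell), and the two-sided Fisher exact p (`fisherEnrichment`).

# Sequence and structure motifs

**G-quadruplexes** are matched with the literal pattern
`([gG]{3,}\w{1,7}){3,}[gG]{3,}` under standard greedy, non-overlapping
regex semantics (PCRE); the tests pin these semantics against an
independent grammar-reachability oracle.

**PWMs** (CISBP-RNA-style probability matrices) are scanned by
sliding-window log-odds in bits against the background distribution; `N`
scores 0 and T≡U. Per-motif thresholds scale with specificity:
`c` bits (default 1) per informative position, a position being
informative at ≥ `icCut` bits of information content (default 0.5).
The exact rule was open; this one preserves the required monotonicity —
longer, more specific motifs demand higher scores — and both constants
are arguments.

**B1/B2 SINE hairpins** are detected with single-exemplar covariance
models: the dot-bracket structure defines a guide tree (one pair node per
base pair, one left/right node per unpaired base, bifurcations only at
true multiloops), emissions are pseudocount-smoothed log-odds centered on
the exemplar's bases and pairs (pseudocount 0.05; +0.5-bit pair bonus;
1-bit extra mismatch penalty on pairs), and indels cost affine
`gapOpen`/`gapExtend` = 4/1 bits (pair-node deletion 5). Alignment is
CYK-style inside-max (Rcpp), global to the model with free end insertions
at the root, so scanning reports the best-scoring subsequence of each
window. Absolute bitscores of any re-parameterized model cannot match a
published CM suite's, so the defaults are instead **calibrated to the
published decision boundary**: with shipped parameters the B1 exemplar
self-scores ≥ 50 bits and B2 ≥ 35 bits, while ≥ 99% of
dinucleotide-preserving shuffles of each exemplar score below its cutoff
(asserted by the test suite at 1000 shuffles, and recomputed by the
acceptance script). Scanning tiles 250-nt windows with a 75-nt slide —
windows must hold a full ~90–175 nt element, which is why the window
exceeds the tree-building window used for de novo discovery tools; only
the annotated strand is scanned, and sequences shorter than half the
model length yield no windows. The `scoreWindow` span precondition is
enforced as this lower bound only: with free root end-insertions an
upper bound on window length has no effect.

# The synthetic-data generator

`simScenario`/`simulateCounts` emulate the study design, not any
particular dataset: 16 cells, lognormal baselines (median 150 reads,
sdlog 1), per-sample lognormal library factors (sdlog 0.3) with dendrite
libraries scaled to 0.4× soma depth, NB dispersion 0.3, Bernoulli
gene-sample dropout (soma 5%; dendrite 25%, but 2% for
deDend/consDend-class genes, encoding constitutive presence), 1–4
isoforms per gene (probabilities .3/.4/.2/.1), and planted classes:
deDend at a 10× dendrite/soma concentration ratio, isoDend at a ΔDF
shift of 0.3 with the preferred isoform drawn 50/50, nonlocalized genes
with a lognormal(0, 0.4) per-gene compartment ratio so that a genuine
soma-enriched pool exists for background matching. The shift and ratio
match the planted-recovery conditions stated for the method; the noise
levels are one-time choices of what is realistic for deeply sequenced
single-cell compartments. `simulateAnnotation` plants ALE vs tandem
geometry at 85/15 (the observed ALE share among tested multi-UTR genes)
and puts 20% of adjacent 3′ ends closer than 500 nt to exercise merging;
`simulateSequences` plants G4/PWM/SINE instances at configurable
foreground/background rates.

What passing tests on these data do show: the callers recover planted
effects of the stated size at the stated sample sizes, control their
nominal error rates under the null, and every interval/counting/scoring
operation agrees with brute-force oracles. What they do not show:
robustness to features of real data the generator omits — amplification
jackpots, gene-correlated dropout, mappability artifacts, annotation
errors, isoform-specific degradation.

# Problem sizes and determinism

Default verification sizes: 1000-gene scenarios for caller
calibration/power, 1000 dinucleotide shuffles per structure model
(500 in the acceptance script), 200–400-sequence motif panels. Every
stochastic stage takes a seed and is bit-reproducible under it; the
acceptance script derives all sub-seeds from its `--seed` argument.

# Known limitations

- The DE engine is a rank test on normalized counts, not an NB GLM;
  exact replication of counts published from an NB-GLM analysis is out
  of scope by design.
- Master-list integration normalizes symbol case only; no alias or
  cross-species ortholog mapping is attempted, so the same gene under
  different symbols counts twice.
- CM bitscores are calibrated to the published cutoffs' decision
  boundary, not to any external scoring scheme; scores are comparable
  within this package only.
- The G-quadruplex scanner is a sequence-pattern search; it does not
  fold RNA or score quadruplex stability.
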