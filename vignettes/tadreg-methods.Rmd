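---
title: "tadreg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadreg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`tadreg` implements an integrative chromatin analysis for a
transcriptional regulator that binds molecularly distinct classes of
chromatin sites. Starting from ChIP-seq peaks, coverage tracks for the
factor and its candidate co-factors (e.g. TRIM28, SUMO2/3, ADNP),
chromatin accessibility and histone-mark signal, the pipeline:

1. builds a windowed multi-track **signal matrix** around peak centres
   and partitions the peaks into k classes by k-means;
2. characterises each class by **genomic feature** (promoter/TTS/
   exonic/intronic/distal), **retrotransposon composition** (LTR, SINE,
   LINE classes; ERV1/ERVL/Alu/MIR families) and **consensus motif
   frequency** against a random background;
3. integrates differential expression (DE) after factor depletion:
   directional set overlaps between depletion conditions,
   **distance-bracket hypergeometric association** of peaks with
   up/down gene sets against random-gene controls, and
4. asks whether regulation is **regional rather than peak-to-gene**:
   within topologically associating domains (TADs), it compares up/down
   proportions of genes sharing a TAD with each peak class, tests
   co-localization against a permutation null, measures peak-to-boundary
   distances against uniform controls, and runs an adjacent-TAD
   distance-mirror control;
5. filters RIME-style proteomics spectral-count tables into a ranked
   interactor list.

A seeded synthetic-data generator produces a complete bundle (genome
FASTA, genes, TADs, repeats, peaks, bedGraph tracks, DE and
spectral-count tables) with planted structure for every one of these
stages, so the full pipeline is testable without any external download.

# Core statistics

**Mutual-overlap rule.** Two intervals overlap only if the shared span
is at least 30% of *each* interval's length. This symmetric rule is
stricter than one-sided fractional overlap and is used for all
peak-set comparisons (`mutual_overlap`, `overlap_peak_sets`).

**Hypergeometric association.** For a gene set of size $n$ drawn from a
universe of $N$ testable genes of which $K$ lie within distance $d$ of
a peak centre, the enrichment p-value is the upper tail
$P(X \ge k) = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$.
Brackets are cumulative (nested windows $0..d$) by default because the
quantity of interest is "genes within the indicated distance"; a
disjoint-ring mode is available (`mode = "rings"`). The universe is the
set of genes present in the DE table — enrichment must condition on
testability, not on annotation. K and k are non-decreasing in $d$; the
p-value is *not* required to be monotone and is reported per bracket
without multiplicity correction (the raw per-bracket hypergeometric is
the quantity of interest; callers can apply `p.adjust`).

**Directional overlaps.** Up/down gene-set overlaps between two
depletion conditions use the two-sided Fisher exact test on the 2x2
membership table over the common universe; the hypergeometric upper
tail is returned alongside.

**Permutation null for co-localization.** The observed statistic is the
fraction of up-regulated (TAD-assigned) genes whose TAD contains at
least one peak of the class of interest. The null permutes *gene
labels* across all assigned genes, preserving the genes-per-TAD
structure — this conditions on the TAD architecture and gene content,
which peak shuffling would destroy. The estimator
$p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$ never returns 0.

**Boundary distances.** A peak's distance to its TAD boundary is
$\min(c - s, e - c)$ for centre $c$ in TAD $[s, e)$; it is bounded by
half the TAD length. Controls are uniform *points* within TAD
territory (distances are measured from peak centres, so interval-shaped
controls would add an arbitrary width convention). For a TAD of length
$L$, a uniform position has expected boundary distance $L/4$ and
standard deviation $L/\sqrt{48}$; across a mixed-length TAD set the
expectation is the length-weighted $\sum L_i^2 / (4 \sum L_i)$. The
comparison uses Welch's two-sided t-test per (class, control set).

**Adjacent-TAD mirror control.** For every (peak, up-gene) pair sharing
a TAD at distance $d$, the mirror position at distance $d' \in
[(1\pm0.25)d]$ on the *opposite* side of the peak is searched for gene
TSSs residing in a different TAD. If deregulation simply spread with
distance, these mirror genes would be up-regulated as often as the
same-TAD genes; counting qualifying peaks, unique candidate genes, and
up-regulated candidates quantifies that. "Adjacent" is read as any TAD
other than the peak's own (the geometry almost always lands in a
neighbour); `mode = "flanking"` restricts to the immediately
neighbouring TAD.

**RIME filter.** Proteins are removed if found in more than 50% of
contaminant-catalogue (CRAPome) runs, flagged ribosomal, or zero in any
experiment; survivors are kept when the mean spectral count across
experiments is strictly greater than 4 ("average of more than 4" is
read literally as strict). The ribosomal flag comes from a
caller-supplied id list, never from name-pattern matching. The filter
is monotone in both thresholds.

# Signal matrices and clustering

Windows are 10 kb (default) centred on the **peak centre**
$\lfloor (start+end)/2 \rfloor$; summits are used only where the
analysis is summit-anchored (feature classification, motif windows).
Each of the 100 bins per track holds the mean per-base coverage;
half-open bins, zero signal beyond chromosome ends.

Before clustering, each track's columns are scaled by that track's
global 95th-percentile bin value, so one deep track cannot dominate the
Euclidean metric; profiles and downstream summaries always use the raw
matrix (`scaling = "raw"` disables this). Clustering is Lloyd's
k-means, k = 3 by default, best of 25 seeded restarts by total
within-cluster sum of squares. A single master seed spawns the restart
seeds, so identical inputs and seed give identical labels.

Raw k-means labels are arbitrary, but the class numbering is semantic:
cluster 1 should be the repressive class. Labels are therefore
reassigned deterministically — cluster 1 is the class richest in the
designated repressive track (e.g. TRIM28); among the remaining classes,
cluster 2 is the richest in the designated active track (e.g. ADNP).
The secondary key exists because the two non-repressive classes are
both repressive-low and, in balanced designs, equal-sized, so neither
the repressive mean nor the size fallback can order them reliably.
Without designated tracks the fallback is descending cluster size with
ties broken by the previous label.

`superimpose_track` computes per-class profiles of a track that was not
part of the clustering while keeping the assignment fixed — the
overlay operation used when a new co-factor's signal is mapped onto an
existing peak classification.

# Feature classification

The genome is divided into five mutually exclusive categories with
strand-aware windows: promoter (TSS $-1$ kb to $+0.1$ kb), TTS
($-0.1$ kb to $+1$ kb), exonic and intronic (within the gene body from
TSS $+0.1$ kb to TTS $-0.1$ kb), and distal intergenic. A peak is
linked to a category when its *summit* falls inside the window, with
precedence promoter > TTS > exonic > intronic across all genes. Genes
without exon lists are treated as single-exon, which keeps the gene
table minimal; supplying an `exons` column refines the exon/intron
split. The genome-wide baseline is the fraction of genome base pairs
per category under the same windows and precedence (a bp-fraction
baseline, not a random-region baseline — the choice is declared, since
either reading is defensible).

Repeat "containment" is at least 1 bp of overlap between the element
and the peak interval; the threshold is exposed (`min_overlap_bp`)
because "containing" admits stricter readings. Family-level
composition is restricted to one parent class and normalised to sum
to 1 per cluster over per-peak family memberships.

Motif scanning is exact IUPAC-compatible matching (both strands) in a
101-bp window centred on the summit, via `Biostrings` fixed-free
matching; the background is a caller-supplied control set or 10x
width-matched uniform random regions on the same chromosomes.

# Coordinates

Externally, all BED-family formats are 0-based half-open (the BED
convention) and the gene table may declare 1-based closed coordinates
with a `#coordinates=1-based` first line. Internally the package uses
`GenomicRanges` (1-based closed) — the standard container in this
ecosystem — and converts at the I/O boundary, so write-then-read round
trips reproduce coordinates exactly. TAD containment is half-open by
peak centre and gene TSS: a position at a TAD start belongs to that
TAD, a position at its (exclusive) end does not. Chromosome names are
matched exactly, with a loud warning when two inputs share no
chromosome names; silent `chr`-prefix coercion hides real errors.

# The synthetic generator

The generator's defaults define the desk-scale study conditions: two
10-Mb chromosomes tiled by 200-500 kb TADs with occasional 10-50 kb
gaps (~55 TADs), 1200 strand-aware genes of 2-20 kb, and three peak
archetypes of 200 peaks each (95% placed inside TAD territory), mapped
over six tracks:

| archetype | planted signature |
|---|---|
| 1 | ZMYM2 + TRIM28 + SUMO high; ATAC/H3K18ac low (repressive class) |
| 2 | ZMYM2 + ADNP + ATAC + H3K18ac high (active class) |
| 3 | ZMYM2 only (bare class) |

Coverage bumps are Gaussian (sd 400 bp) with negative-binomial heights
(dispersion `size = 20`) over a constant background of 0.5. The
dispersion was fixed at design time by the generator's defining
property: the planted archetypes must be recoverable from the default
bundle (at `size = 5` the shared-high ZMYM2 track's height noise
dominates the cross-track contrasts and recovery fails, which
contradicts what the default bundle is for; noisier regimes remain
available through the config). Repeat placement is conditioned on the
archetype — LTR/ERV1 elements in 80% of archetype-1 peaks, SINE
(Alu + MIR) in 70% of archetype-2 peaks, LTR/ERVL in 75% of
archetype-3 peaks — over 400 background elements of mixed classes.

The DE table plants two kinds of structure: a baseline 10% of genes
genuinely regulated (half up, half down, log2 shift 1.5), and the
regional effect — 50% of the remaining genes in TADs containing an
archetype-1 peak shifted up by 1.5. Observed log2 fold changes add
Normal(0, 0.25) noise; p-values come from the z-score against the
known noise sd with Benjamini-Hochberg adjustment. There is no
count-level RNA-seq simulation: the pipeline consumes DE statistics
tables, so the generator produces coherent statistics directly.

A concrete instantiation of the IUPAC consensus `CGCCCYCTNSTG` is
planted at the summit of 15% of archetype-2 peaks (random strand) in
the otherwise uniform-random genome sequence. The spectral-count table
contains four planted protein categories (true interactors,
CRAPome-frequent contaminants, ribosomal, single-experiment dropouts)
exercising every filter rule.

All randomness flows from one master seed through named sub-streams,
so a config and seed identify a byte-identical bundle.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: mappability and GC biases, read-level
noise and duplicate structure, correlated replicate variability,
realistic gene/repeat density heterogeneity, nested or cell-type
variable TADs, LD-like spatial autocorrelation of DE genes beyond the
planted regional effect, and motif background composition (the random
genome makes chance 12-mer matches rarer than in real sequence).
Recovery results demonstrate internal consistency of the pipeline, not
field performance.

# Problem sizes used in the checks

The default bundle (600 peaks, 1200 genes, ~55 TADs over 20 Mb) is
within 2x of the motivating analysis' peak-set scale and is used for
clustering recovery, repeat composition, motif frequency and
determinism checks. The regional (TAD direction) recovery and null
calibration use a sparser variant — 30 peaks per archetype, 1500
genes, baseline DE 15% — because at the default density essentially
every TAD contains peaks of every class and the no-peak reference
category would be empty; the sparser density keeps every Fisher cell
expectation above ~20, mirroring the genome-wide sparsity of a real
peak set relative to ~3000 TADs. These sizes are fixed in the test and
acceptance code and were chosen once, before the checks were run, as
the package's own study conditions.

# Numerical and degenerate-input choices

* k-means restarts that produce an empty cluster are skipped; at least
  one successful restart is required. Ties in best inertia resolve to
  the earliest restart; relabelling ties resolve to the previous label
  order.
* Nearest-distance ties resolve to the first target in sorted genomic
  order (the distance is unchanged either way).
* Peaks without summits fall back to their centre, with a message.
* A cluster with fewer than two assigned peaks yields `NA` in the
  boundary t-test; a category with no up/down genes yields `NA`
  proportions; a chromosome with no targets yields `NA` distances —
  sentinels, never silent zeros.
* `call_de` refuses tables without an adjusted-p column rather than
  falling back to raw p. Default thresholds are adjusted p < 0.01 and
  fold change > 1.6; an alpha of 0.05 is honoured via the argument —
  both variants occur in practice and neither is hard-coded.
* Track values written to bedGraph omit zero runs; reading the file
  back reproduces the coverage exactly up to the final nonzero run.

# Limitations

* TADs are inputs; no Hi-C processing or TAD calling, and no causal
  claim about chromatin topology — the module computes association
  statistics only.
* Gene-level counting in the TAD direction analysis pseudoreplicates
  genes within a TAD; the per-TAD alternative (counting TADs) is noted
  but not implemented, matching the analysis being reproduced.
* The motif background here is random sequence; the empirical
  background frequency in real genomes is substantially higher, so
  motif fractions are comparable only within a bundle.
* No read alignment, peak calling, count-model DE fitting, de novo
  motif discovery or GO enrichment: those stages belong to the
  established tools whose outputs this package consumes.
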