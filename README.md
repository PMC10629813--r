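# tadreg

Integrative chromatin analysis for transcriptional regulators that act
through molecularly distinct binding-site classes. `tadreg` takes
ChIP-seq peaks, multi-track coverage (the factor itself, co-factors
such as TRIM28/SUMO/ADNP, accessibility and histone marks), gene and
TAD annotations, RepeatMasker-style repeat tables and differential
expression (DE) statistics, and answers:

* which signal classes do the peaks fall into (k-means on windowed
  tag-density matrices), and how do the classes differ in genomic
  features, retrotransposon content (LTR/ERV1, LTR/ERVL, SINE Alu/MIR)
  and consensus motif frequency;
* are DE genes associated with peaks as a function of distance
  (cumulative distance brackets, hypergeometric upper-tail
  $P(X \ge k)$ for $k$ of $K$ eligible genes in a set of $n$ from a
  universe of $N$, against random-gene controls);
* is regulation *regional*: within topologically associating domains
  (TADs), are up-regulated genes over-represented in domains carrying
  a given peak class (Fisher exact vs peak-free TADs), do peaks
  co-localize with regulated genes beyond a gene-label permutation
  null, do peaks sit near TAD boundaries relative to uniform controls
  (E[distance] = L/4 for a TAD of length L), and does deregulation
  fail an adjacent-TAD distance-mirror control (genes at a mirrored
  distance ±25% across the TAD border);
* which proteins survive RIME spectral-count filtering (CRAPome > 50%
  removal, ribosomal removal, zero-count removal, mean count > 4).

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_bundle()`) produces an internally consistent bundle — genome
FASTA, genes, TADs, repeats, narrowPeak peaks with three planted signal
archetypes, bedGraph tracks, DE and spectral-count tables plus truth
labels — so every stage is verifiable end to end without external data.

## Worked example

```r
library(tadreg)
library(GenomicRanges)

cfg <- sim_config(seed = 7)
b <- simulate_bundle(cfg, components = c("tads", "genes", "peaks",
                                         "repeats", "tracks", "de"))

mat <- compute_signal_matrix(b$peaks, b$tracks, window = 10000, n_bins = 100)
asg <- cluster_peaks(mat, k = 3, seed = 7,
                     repressive_track = "TRIM28", active_track = "ADNP")
asg
#> ClusterAssignment: k = 3, sizes = 196/200/204, inertia = 2.683e+04

mclust::adjustedRandIndex(asg$labels, b$truth_archetype[mat$peak_ids])
#> [1] 0.96

lab <- asg$labels[mcols(b$peaks)$name]
subset(repeat_composition(b$peaks, unname(lab), b$repeats, "class"),
       class %in% c("LTR", "SINE"))
#>  cluster class    fraction n_peaks
#>        1   LTR 0.811224490     196
#>        1  SINE 0.000000000     196
#>        2   LTR 0.010000000     200
#>        2  SINE 0.515000000     200
#>        3   LTR 0.720588235     204
#>        3  SINE 0.009803922     204

de <- call_de(b$de)          # adjusted p < 0.01, fold change > 1.6
attr(de, "counts")
#>        up      down unchanged
#>       563        60       577
```

The three peak classes are recovered almost perfectly from the signal
alone (adjusted Rand index 0.96 against the planted archetypes), the
repressive class (cluster 1) is LTR-rich and SINE-free while the
active class (cluster 2) is SINE-rich — the planted repeat
conditioning — and the DE table shows the planted excess of
up-regulated genes driven by the regional effect in cluster-1 TADs.
`run_pipeline()` chains all stages from file inputs and writes
per-stage TSVs plus a JSON manifest; `inst/scripts/tadreg.R` is a thin
command-line wrapper (`simulate`, `run`).

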