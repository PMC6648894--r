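# degronCTS

Differential CTCF occupancy, motif clustering and loop quantification
for acute-depletion (auxin degron) experiments.

## What this package is for

Acute depletion of an architectural protein such as CTCF produces a
characteristic bundle of genomics data: Cut&Run occupancy profiles from
clonal replicates with and without auxin, CTCF motif maps, Capture-C
viewpoint tracks at a promoter of interest, and an RNA-seq
differential-expression table, plus externally derived gene sets
(loop-disrupted genes from Hi-C, enhancer-docking genes).  `degronCTS`
implements the downstream analysis that connects them, for analysts of
degron time-course experiments:

* **Peak consensus** — the dual-confidence reproducibility rule (a region
  is kept when one clone calls it at high confidence, FDR ≤ 0.05, and
  every other clone supports it at high or low confidence, FDR ≤ 0.5),
  union merging across conditions, blacklist removal, whole-fragment
  overlap counting, and FPKM:

  FPKM = count / ((length / 10³) × (library / 10⁶)),
  log₂FC = log₂((FPKM̄₊ + ε) / (FPKM̄₋ + ε)), ε = 0.5.

* **CTS classes** — single-linkage clustering of CTCF motifs at an
  inter-motif gap ≤ 40 bp into 1X/2X/3X CTCF target sites (isolated,
  paired, ≥ 3 clustered motifs); occupancy classification by fold
  change (reduced ≤ −1 < retained ≤ 1 < gained); two-sided Wilcoxon
  rank-sum comparisons between classes (exact enumeration for small
  groups, tie-corrected normal approximation otherwise).

* **Annotation** — feature assignment with the standard priority
  promoter > UTR > exon > intron > downstream > distal intergenic, with
  promoter distance bins at 1/2/3 kb of the nearest TSS, and per-class
  distribution summaries.

* **Capture-C** — probe normalisation (every track divided by the
  base-pair-weighted signal mass over the capture probe, so the probe
  mass becomes 1) and relative interaction frequency over loop windows,
  with two-tailed t-tests across replicates.

* **Integration** — DEG filtering (|log₂FC| ≥ 1, adjusted P ≤ 0.05,
  FPKM ≥ 1), exact gene-set overlaps, enhancer-docking cohort analysis
  at an expression cutoff, signature concordance, and Spearman
  transcriptome correlation.

* **Synthetic data** — a generator (`sim_config()`, `sim_experiment()`)
  producing every input above with planted ground truth (CTS orders,
  occupancy effects, loop multipliers, DEG membership), so the whole
  pipeline is testable without deposited sequencing data.  All standard
  formats are written and read: narrowPeak, BED6/BED12, BEDPE, bedGraph,
  chrom.sizes, TSV, JSON.

## Worked example

A small synthetic experiment, end to end:

```r
library(degronCTS)

cfg <- sim_config(n_sites = 300, depth = 1e5,
                  chrom_sizes = c(chr1 = 1e6, chr2 = 1e6), n_genes = 60)
genome <- sim_genome(cfg)
motifs <- sim_motifs(genome, cfg)
occ    <- sim_occupancy(motifs, cfg)

repro     <- lapply(occ$peak_calls, filter_reproducible)
consensus <- merge_and_blacklist(repro$minus, repro$plus)
peaks <- quantify_fpkm(consensus, sim_fragments(occ, cfg),
                       occ$samples$condition)
peaks <- assign_peak_cts(peaks, cluster_motifs(motif_granges(motifs)))
peaks <- classify_occupancy(peaks)
table(peaks$occupancy_class)
#>  reduced retained   gained
#>      118      142        3
```

263 consensus regions survive the reproducibility rule at this depth,
and the fold-change partition recovers the planted class mix (about
48% reduced, 51% retained, 1% gained).  Loop quantification against the
planted Capture-C multiplier of 0.25:

```r
cc   <- sim_capturec(cfg)
norm <- lapply(cc$tracks, function(reps)
  lapply(reps, probe_normalize, probe = cc$probe))
relative_interaction(norm, cc$windows)
#> Relative interaction frequencies (probe-normalised)
#>   Loop1: -IAA 0.7492, +IAA 0.1916, ratio 0.256, P = 0.0038
#>   Loop2: -IAA 0.4831, +IAA 0.1264, ratio 0.262, P = 0.00208
```

The ratio is the +IAA/−IAA contact frequency — here the ~4-fold loop
loss is recovered, with the replicate t-test confirming it.  Expression
integration against the planted gene sets:

```r
ex  <- sim_expression(cfg)
deg <- filter_degs(ex$expression)
overlap_sets(deg$gene_id, ex$loop_genes)
#> Gene-set overlap: |A| = 330, |B| = 664, intersection = 10
signature_concordance(ex$targets, ex$expression)
#> Signature concordance: 92/100 targets decreased (94 evaluable, 0 unresolved)
```

330 genes pass the DEG thresholds, exactly 10 of them intersect the
664-gene loop-disrupted list, and 92 of the 100 signature targets
decrease (6 are excluded below the FPKM floor) — the planted structure,
recovered by computation.

The methods vignette (`vignettes/degron-cts-analysis.Rmd`) documents the
model, the parameter choices and their rationale, and the limitations of
the synthetic data.

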