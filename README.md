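# seasight

Cross-platform integration of deep-sequencing and microarray expression
data in R.

## The problem

Bulk transcriptome studies routinely mix measurement technologies: the
same tissues hybridized to microarrays *and* sequenced on several lanes.
The two platforms produce fundamentally different raw data — probe-level
fluorescence intensities on one side, genomic coordinates of mapped reads
on the other — yet downstream analysis (differential expression,
clustering, visualization) wants a single features × experiments matrix
in which a given numeric value means the same expression strength in
every column.

`seasight` builds that matrix.  It provides:

- **Import** of mapped reads (SAM, BAM, generic tabular with a column
  map), raw probe tables (generic delimited exports, 1- or 2-channel,
  with optional background columns), and locus annotations (GFF3, NCBI
  PTT, generic tabular).
- **A locus algebra** to reconcile coordinate sets from different
  sources: `merge_union`, `merge_pairwise`, `merge_greedy`,
  `merge_minmax`, plus `filter_loci` (max-distance / min-overlap) and
  `edit_loci` (shift, resize, strand edits, renaming).  Internally all
  coordinates are 0-based half-open; parsers and exporters convert.
- **Quantification** of reads per locus: naive counts
  (overlap/start-in/contained rules), mean per-base coverage,
  RPKM = 10⁹·c/(N·L) (c reads in the feature, N total mapped reads, L
  feature length in bp), and DCPM (mean depth per base per million
  mapped reads), plus a basic coverage-threshold peak finder
  (`derive_loci`).
- **A normalization catalog**: background subtraction and normexp
  correction (observed X = S + B with S ~ Exp(α), B ~ N(μ, σ²);
  correction returns E[S | X = x]), quantile and reference-quantile
  normalization, average/percentile scaling, loess and printtip-loess
  MA normalization for two-channel arrays, Tukey median-polish /
  mean / median probeset summarization, log₂, logarithmic interval
  mapping, MA transform, dye swap and identifier mapping.
- **A state-typed transformation matrix**: experiments are rows,
  processing steps are columns, each cell holds at most one
  transformation instance.  Every transformation declares which data
  states (entity, channels, linear/log scale, measure, processing
  flags) it accepts and which state it produces, so whole pipelines are
  validated — and final data properties predicted — *before any value
  is computed* (`add_instance`, `predict_states`, `execute`,
  `save_config`/`load_config`).
- **A seeded synthetic-study generator** (`synth_study`) emulating a
  two-condition, two-platform design with technical replicates and
  machine-readable ground truth, used throughout the test suite.
- **A CLI**: `exec/seasight` with subcommands `run`, `states`,
  `merge-loci`, `quantify`, `synth`.

## Worked example

Merge two stranded locus sets, then run the reference cross-platform
pipeline on a small synthetic study:

```r
library(seasight)

a <- locus_set(chrom = "chr1", start = c(100, 480), end = c(400, 900), strand = "+")
b <- locus_set(chrom = "chr1", start = 350, end = 520, strand = "+")
merge_greedy(list(a, b), min_overlap = 1)
#> LocusSet with 1 loci on 1 chromosome(s)
#>   species chrom start end strand   id
#> 1 unknown  chr1   100 900      + <NA>

dir <- file.path(tempdir(), "demo")
design <- study_design(genes = 50, depth = 2e4, probes_per_gene = 5,
                       genome_length = 5e5, seed = 42)
synth_study(design, dir)               # SAM + array tables + GFF3 + config
tm <- load_config(file.path(dir, "config.json"))
tm
#> TransformationMatrix: 8 experiment(s) x 5 column(s), 8 instance(s)
#>   col 1: normexp (array_c1r1, array_c1r2, array_c2r1, array_c2r2)
#>   col 1: count (seq_c1r1, seq_c1r2, seq_c2r1, seq_c2r2)
#>   col 2: quantile (array_c1r1, array_c1r2, array_c2r1, array_c2r2)
#>   col 2: rpkm (seq_c1r1, seq_c1r2, seq_c2r1, seq_c2r2)
#>   col 3: log2 (array_c1r1, array_c1r2, array_c2r1, array_c2r2)
#>   col 3: interval_map_log (seq_c1r1, seq_c1r2, seq_c2r1, seq_c2r2)
#>   col 4: summarize (array_c1r1, array_c1r2, array_c2r1, array_c2r2)
#>   col 5: quantile (array_c1r1, ..., seq_c2r2)

predict_states(tm)[["seq_c1r1"]][[6]]  # predicted final state, no data touched
#> DataState: locus[1] log expression norm loci n=50

ds <- execute(tm)
ds
#> SeasightDataset: 50 features x 8 experiments (0 missing values)
round(ds$values[1:4, c(1, 2, 5, 6)], 2)
#>           array_c1r1 array_c1r2 array_c2r1 array_c2r2
#> gene_0001       6.78       5.95       7.25       7.01
#> gene_0002       9.78       9.58       9.58       9.58
#> gene_0003       7.89       8.14       8.22       8.22
#> gene_0004       3.50       2.86       2.86       2.86
```

The values are log-scale expression after the closing quantile step, so
all eight columns share one distribution and are directly comparable.
Ranking genes by the absolute between-condition difference of mean
log expression puts the simulated differentially expressed genes on top:

```r
truth <- read.delim(file.path(dir, "truth.tsv"))
g1 <- grepl("_c1", colnames(ds$values)); g2 <- grepl("_c2", colnames(ds$values))
delta <- abs(rowMeans(ds$values[, g2]) - rowMeans(ds$values[, g1]))
round(sort(delta, decreasing = TRUE)[1:5], 2)
#> gene_0017 gene_0024 gene_0032 gene_0036 gene_0007
#>      3.38      3.01      2.76      2.55      1.99
truth$gene[truth$is_de]
#> [1] "gene_0007" "gene_0017" "gene_0024" "gene_0032" "gene_0036"
```

All five true DE genes (fold change 4 → 2 log₂ units) are the top five.

## Command line

```sh
exec/seasight synth --out study --seed 1
exec/seasight run --config study/config.json --out dataset.tsv
exec/seasight states --config study/config.json        # dry run: states only
exec/seasight merge-loci --method minmax --min 100 --max 2000 a.gff b.gff --out merged.gff
exec/seasight quantify --reads lane1.sam --loci genes.gff --mode rpkm --out expr.tsv
```

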