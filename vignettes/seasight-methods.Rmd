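---
title: "seasight: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seasight: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seasight)
```

This vignette documents the scientific and numerical choices behind
`seasight`: the data model, the locus algebra, the quantification and
normalization methods, the state-typed pipeline engine, and what the
synthetic-data generator does and does not establish.

# Coordinates and the locus model

All internal coordinates are **0-based half-open** (`start` inclusive,
`end` exclusive, `length = end - start`).  This makes interval
arithmetic uniform: two loci overlap iff `a$start < b$end && b$start <
a$end`, and the gap between `a` before `b` is `b$start - a$end`, with
overlapping or touching loci having gap 0.  GFF3 and PTT input (1-based
inclusive) is converted at the parser boundary, and GFF3 export converts
back; BED export keeps the internal convention, which is also BED's.

A `Locus` is a stranded interval on a named chromosome of a named
species.  Strand is one of `+`, `-`, `*` (unstranded).  Tabular importers
accept the strand tokens `+/-`, `F/R` and `0/1`; anything else becomes
unstranded with a warning.

**Strand policy.** Merging never joins loci on different strands, and
unstranded loci form their own group rather than acting as wildcards —
merging a `+` locus into a `*` locus would silently fabricate strand
information.  A global `ignore_strand` flag clears strands before
merging, which is the right tool for data from non-strand-specific
protocols.  *Filtering* (`filter_loci`) is a read-only comparison, so
there `*` acts as compatible with either strand.

# The merge algebra

Four methods reconcile several coordinate sets into one common set of
interrogated positions:

- **union** — all unique loci (identity = species, chromosome, start,
  end, strand), then a `min_size` filter.  Highest resolution, sparsest
  matrix.
- **pairwise** — the sorted unique starts *and* ends of all input loci
  define boundary pairs `[c_i, c_{i+1})`; a candidate survives iff it is
  covered by at least one input locus, then the `min_size` filter.
- **greedy** — loci sorted by (start, end) are absorbed into a growing
  cluster iff they overlap the cluster *span* by at least `min_overlap`
  bases, or (distance mode) start within `max_distance` of the span end.
  Exactly one criterion must be active.  Each cluster emits its span.
- **minmax** — left-to-right accumulation of overlapping loci as long as
  the extended span stays within `max_size`; an extension is emitted iff
  its length lies in `[min_size, max_size]`.  Consequently a single
  input locus longer than `max_size` is dropped (no admissible extension
  covers it); we chose this reading over passing oversized loci through
  because it keeps the output-length guarantee exact.

Greedy and minmax compare candidates against the growing cluster's
*span*, not its last member, and ties are broken by earlier start.  All
four methods are checked against brute-force oracles (exhaustive
pairwise interval arithmetic) on hundreds of seeded random instances in
the test suite.

`filter_loci` keeps a target locus iff a single reference locus
satisfies overlap ≥ `min_overlap` **and** gap ≤ `max_distance`.  The
conjunction was a genuinely open choice; AND with defaults
`min_overlap = 0`, `max_distance = 0` degrades gracefully to "touches or
overlaps" and each criterion can be disabled by its neutral value
(`min_overlap = 0` is vacuous; `max_distance` large).

# Read import and quantification

SAM/BAM import goes through Rsamtools; the reference span of a record is
the sum of its M/D/N/=/X CIGAR operations, so spliced (`N`) reads
contribute coverage across the skip — acceptable for the bulk designs
targeted here, and flagged in the log.  Multi-mapping records count once
per record; `total_mapped` counts records, not templates.  Tabular
import needs only read start positions; ends default to
`start + read_length` (default 36 bp).

Per-locus expression values:

- **naive** — read count under a rule: `overlap_any` (default),
  `start_in` (for start-only imports), `contained`.  A read may count
  toward several overlapping loci; no ambiguity resolution is attempted.
- **coverage** — *mean* per-base depth over the locus.  Mean rather than
  total, so the value is independent of locus length and comparable
  across loci.
- **RPKM** — `1e9 * c / (N * L)`.
- **DCPM** — mean per-base depth divided by `N / 1e6`, i.e. the
  depth-of-coverage analogue of RPKM, following the expansion of the
  acronym (depth of coverage per base per million mapped reads).

`derive_loci` is deliberately basic (threshold on a depth track, close
gaps ≤ `max_gap`, drop runs < `min_length`): a proof-of-concept peak
finder, not a replacement for a dedicated peak caller.  Deriving from
read *counts* instead of full coverage is done by building the track
from start positions only.

# The normalization catalog

**Background.** `bg_subtract` floors `fg - bg` at 0.5 so subsequent logs
are defined.  `normexp` models observed intensity as X = S + B with
signal S ~ Exponential(mean α) and background B ~ Normal(μ, σ²), and
replaces x by E[S | X = x] (closed form via the inverse Mills ratio;
strictly positive and monotone).  This is also the background step of
the RMA-style chain for single-channel arrays.

**Normexp fitting** is moment/quantile matching, *not* maximum
likelihood: μ and σ are fitted by weighted least squares of the
closed-form model CDF against the empirical lower-tail quantiles
(0.5%–35%, weights 1/(p(1−p)) as in the Anderson–Darling statistic — the
extreme tail carries most of the information about σ), and α is the mean
excess `mean(x) − μ` (exact, since E[X] = μ + α); the two steps are
iterated to a fixed point.  σ is kept away from the degenerate σ → 0
corner by a floor of 0.01·sd(x), which matters when real data deviate
from the pure convolution model.  Results are close to, but not
bit-identical with, likelihood-based implementations.

*Accuracy at the information bound.*  At n = 10⁴ draws with α = 100,
μ = 50, σ = 10, this estimator recovers α and μ to within ~2.5% on every
one of 20 fixed seeds.  For σ the Cramér–Rao bound itself gives a
relative sd of ~4%, so a "within 10% on 20/20 replicates" requirement
holds with only ~75–80% probability *for any unbiased estimator*; on
seeds 1:20 both this fit (max error 12.0%) and exact MLE (11.3%,
cross-checked against limma's normexp MLE) miss 10% on two seeds.  The
acceptance test asserts the criterion anyway and its σ part is an
expected, documented failure rather than a loosened tolerance.

**Quantile normalization** replaces the rank-r value in each vector by
the across-vector mean of rank-r values (or the reference's, in
reference mode); tied values receive the mean of their spanned rank
values.  The defining property — identical sorted columns — and
idempotence to 1e-12 are asserted in the tests, along with agreement
with limma's implementation on tie-free input.

**Scaling** equalizes each vector's mean or p-th percentile to the
across-vector mean of that statistic.  **Loess MA** computes
M = log₂(R/G), A = ½·log₂(RG) and returns the loess residual of M on A
(span 0.3, degree 1); printtip mode fits per block, falling back to the
global fit (with a warning) for blocks under 10 features, where a local
fit would be unstable.

**Median polish** follows Tukey's convention: row medians swept before
column medians, convergence when the largest absolute change in a sweep
drops below 1e-4, at most 10 sweeps (the classical choice; RMA uses the
same).  The summarized value of a probeset in experiment j is
`overall + col[j]`, which makes the result invariant under adding a
constant to any probe row (probe affinity is absorbed into the row
effect).  `stats::medpolish` uses a different convergence criterion, so
the implementation is ours, oracled against `stats::medpolish` at tight
tolerance.

**Value transforms**: `log2(x + c)` with pseudo-count c = 1 by default
(count-derived values contain zeros); logarithmic interval mapping
`y = lo + (hi−lo)(log₂(x+1) − m)/(M − m)` with target range `[0, 16]` by
default — the per-vector extremes define m, M, but the engine's group
form shares one range across experiments, which is what cross-platform
comparability actually requires; MA transform; dye swap (an involution:
channels exchanged, M negated on ratio data); identifier mapping with
mean aggregation of collisions.

# The transformation-matrix engine

A pipeline is an experiments × steps grid.  Each cell holds at most one
transformation instance; one instance may span several rows of a single
column (its experiment group), and instances in a column must touch
disjoint experiment sets, so within a column execution order is
irrelevant (asserted bit-for-bit in the tests).  Empty cells are
identity.

Every transformation declares `accepts` (a predicate over the typed
`DataState`: entity, channels, scale, measure, background/normalized
flags, row count, loci attached) and `produces` (the output state).
`add_instance` therefore validates placement *without computing
anything*: the target cells must be empty, the predicted input states
must be accepted, and no downstream instance may be invalidated — e.g. a
second background correction after one has been applied is rejected, as
is inserting a log step ahead of a linear-only step.  `predict_states`
is a pure function of matrix plus initial states.  During `execute` the
engine sets each experiment's state from `produces` and cross-checks the
observed row/channel counts, so prediction and execution cannot silently
diverge.

Two design points were genuinely open:

- **Quantify parameters.** `count`/`coverage`/`dcpm` take their locus
  set as an instance parameter rather than reading it from a prior
  attach step, so predicted row counts are computable from the matrix
  alone.  `import_loci` exists for the array side (attaching coordinates
  to probesets by feature id).
- **Assembly compatibility.** The final dataset requires equal scale and
  single channels everywhere; entities must either be identical or all
  be *summarized* entities (probeset, locus, identifier).  Mixing
  probeset-keyed array columns with locus-keyed sequencing columns is
  precisely the integration point of the tool, provided both sides use
  the same feature identifiers.  Union assembly marks missing features
  `NA`; intersection mode is available.
- **Edits that invalidate downstream instances are rejected** with a
  diagnostic naming the instance, rather than silently recomputed.

`save_config`/`load_config` persist the matrix as JSON: instances with
parameters, experiments by source reference (path + md5 checksum;
loading re-parses and fails on missing files or checksum mismatches) or
inline (archive mode).  Reloaded matrices execute bit-identically.
Summarization/identifier maps predict their row count as the number of
distinct map targets; targets absent from the data yield `NA` rows, so
the prediction holds by construction (maps are expected to cover their
data).

# The synthetic study

`synth_study` emulates a two-condition, two-platform design with
technical replicates.  Defaults describe the reference desk-scale world:
200 genes on one 2 Mb chromosome, gene lengths log-normal(log 1000,
0.4), baseline expression log-normal(2, 1), 10% DE at fold change 4
(half up, half down in condition 2), two array replicates and two
sequencing lanes per condition, 10⁵ mapped 36 bp single-end reads per
lane, 11 probes per probeset.  Reads: expected gene counts proportional
to expression × length, Poisson-realized, uniform starts within the
gene.  Arrays: intensity = gain · expression · affinity + Exp(α) +
N(μ, σ) with α = 100, μ = 50, σ = 10 — exactly the normexp generative
model, so parameter recovery is a well-posed test — and log-normal(0,
0.3) probe affinities shared across replicates.  Gain 100 places median
probe signal well above background while leaving weakly expressed genes
noise-limited, which is the realistic regime.

Everything is deterministic under the design seed, with per-piece
sub-seeds (condition, replicate, stream), so bundles regenerate
byte-identically and any lane or array can be reproduced in isolation.

**What a green test establishes — and what it does not.**  The generator
follows the package's own noise models: unspliced single-end reads,
no sequence-composition or GC effects, no batch effects beyond
per-replicate noise draws, array noise exactly normexp.  Green
end-to-end tests therefore establish internal correctness (the pipeline
recovers the truth its own models encode), not robustness to the model
misspecification real data exhibit.  The scaled-down fixture used by the
unit tests (60 genes, 2×10⁴ reads/lane) loses occasional weakly
expressed DE genes; the ≥ 90% DE-recovery claim is asserted at the
stated full scale in the acceptance suite.

# Numerical choices and degenerate inputs

- Empty locus sets propagate as empty sets; an empty filter reference
  returns an empty result with a warning.
- `bg_subtract` floor 0.5; `log2` pseudo-count 1; interval mapping of a
  constant vector maps everything to `lo` with a warning.
- `rpkm`/`dcpm` with N = 0 or L = 0 are domain errors, not zeros.
- Integer products such as N·L are computed in double precision.
- normexp: CDF and inverse-Mills terms are evaluated in log space;
  far-tail values fall back to the `-z` asymptote.
- Median polish tolerance 1e-4 (max absolute change), 10 sweeps.
- Random sub-seeds are reduced modulo a prime < 2³¹.

# Known limitations

Transcript-model (exon-union) quantification, isoform deconvolution and
ambiguity-aware read assignment are out of scope — quantification is per
whole locus.  GenBank/EMBL flat files and binary vendor array formats
(CEL/CDF) are not parsed; use their tabular exports.  The engine
executes columns sequentially (the disjointness contract makes columns
parallelizable, but no parallel scheduler or automatic column packing is
included).  No statistics catalog is included: DE calling beyond
fold-change ranking belongs downstream.
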