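#' Synthetic study design
#'
#' Describes a two-condition, two-platform expression study with technical
#' replicates, the structure used throughout the test suite.  All
#' generators are fully deterministic under `seed`; replicate-specific
#' randomness is driven by sub-seeds derived from `seed`, condition and
#' replicate index, so regenerating any piece reproduces it exactly.
#'
#' Defaults describe the reference desk-scale study: 200 genes on one
#' 2 Mb chromosome, gene lengths log-normal around 1 kb, 10% of genes
#' differentially expressed at fold change 4 (half up, half down in
#' condition 2), 100,000 mapped single-end 36 bp reads per sequencing
#' lane, 11 probes per probeset, and array noise drawn from the normexp
#' convolution model (exponential signal mean 100 on top of Gaussian
#' background mean 50, sd 10).
#'
#' @param genes number of genes G.
#' @param conditions number of conditions (2).
#' @param reps_array,reps_seq technical replicates per condition per
#'   platform.
#' @param de_fraction fraction of genes differentially expressed, in
#'   `[0, 1)`.
#' @param fold_change fold change of DE genes in condition 2.
#' @param genome_length chromosome length in bases.
#' @param read_length read length in bases.
#' @param depth mapped reads per sequencing lane (the N of RPKM).
#' @param probes_per_gene probes per probeset.
#' @param alpha,mu,sigma normexp noise parameters of the array model.
#' @param gain linear scaling from expression units to intensity units.
#' @param expr_meanlog,expr_sdlog log-normal parameters of baseline gene
#'   expression.
#' @param len_meanlog,len_sdlog log-normal parameters of gene length.
#' @param affinity_sdlog log-normal sd of per-probe affinities (shared
#'   across replicates).
#' @param seed master seed.
#' @return a `StudyDesign` list.
#' @export
study_design <- function(genes = 200L, conditions = 2L, reps_array = 2L,
                         reps_seq = 2L, de_fraction = 0.1, fold_change = 4,
                         genome_length = 2e6, read_length = 36L,
                         depth = 1e5, probes_per_gene = 11L, alpha = 100,
                         mu = 50, sigma = 10, gain = 100,
                         expr_meanlog = 2, expr_sdlog = 1,
                         len_meanlog = log(1000), len_sdlog = 0.4,
                         affinity_sdlog = 0.3, seed = 1L) {
  stopifnot(genes > 0, conditions > 0, reps_array > 0, reps_seq > 0,
            de_fraction >= 0, de_fraction < 1, fold_change > 0,
            depth > 0, probes_per_gene > 0)
  structure(as.list(environment()), class = "StudyDesign")
}

## Deterministic sub-seed below 2^31: mixes the master seed with a stream
## id so every generated piece has its own reproducible stream.
sub_seed <- function(design, stream) {
  (design$seed %% 83492791L) * 17L + stream
}

#' Synthetic gene loci
#'
#' Places `genes` non-overlapping stranded loci with log-normal lengths on
#' one chromosome, separated by random intergenic gaps.
#'
#' @param design a [study_design()].
#' @return a `LocusSet` with ids `gene_0001 ...`.
#' @export
synth_loci <- function(design) {
  set.seed(sub_seed(design, 1L))
  G <- design$genes
  lens <- pmax(round(stats::rlnorm(G, design$len_meanlog, design$len_sdlog)),
               3L * design$read_length)
  gaps <- sample(100:2000, G, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-G]))
  ends <- starts + lens
  if (ends[G] > design$genome_length) {
    stop(sprintf("infeasible packing: %d genes need %d bases but the genome has only %g",
                 G, ends[G], design$genome_length))
  }
  strand <- sample(c("+", "-"), G, replace = TRUE)
  locus_set(species = "synthia", chrom = "chr1", start = starts, end = ends,
            strand = strand, id = sprintf("gene_%04d", seq_len(G)))
}

#' Ground-truth expression table
#'
#' Baseline expression is log-normal; a `de_fraction` subset of genes is
#' multiplied (up) or divided (down) by `fold_change` in condition 2 (and
#' beyond).
#'
#' @param design a [study_design()].
#' @return data.frame with `gene`, `length`, `strand`, one `expr_c<k>`
#'   column per condition, `is_de`, `direction`.
#' @export
synth_truth <- function(design) {
  loci <- synth_loci(design)
  set.seed(sub_seed(design, 2L))
  G <- design$genes
  base <- stats::rlnorm(G, design$expr_meanlog, design$expr_sdlog)
  n_de <- round(design$de_fraction * G)
  de_idx <- sort(sample.int(G, n_de))
  direction <- rep(0L, G)
  if (n_de > 0) {
    direction[de_idx] <- rep_len(c(1L, -1L), n_de)
  }
  out <- data.frame(gene = loci$id, length = locus_lengths(loci),
                    strand = loci$strand, stringsAsFactors = FALSE)
  for (k in seq_len(design$conditions)) {
    fc <- if (k == 1) rep(1, G) else design$fold_change^direction
    out[[paste0("expr_c", k)]] <- base * fc
  }
  out$is_de <- direction != 0L
  out$direction <- direction
  out
}

## Core read simulator: expected per-gene counts proportional to
## expression * length, realized counts Poisson, uniform start positions.
simulate_reads <- function(loci, expr, depth, read_length, seed) {
  set.seed(seed)
  w <- expr * (loci$end - loci$start)
  lambda <- if (sum(w) > 0) depth * w / sum(w) else rep(0, length(w))
  counts <- stats::rpois(length(lambda), lambda)
  idx <- rep.int(seq_along(counts), counts)
  max_start <- loci$end[idx] - read_length
  starts <- loci$start[idx] +
    floor(stats::runif(length(idx)) * (max_start - loci$start[idx] + 1L))
  df <- data.frame(chrom = loci$chrom[idx], start = as.integer(starts),
                   end = as.integer(starts + read_length),
                   strand = loci$strand[idx], stringsAsFactors = FALSE)
  list(reads = read_collection(df, species = loci$species[1]),
       counts = stats::setNames(counts, loci$id))
}

#' Simulate one sequencing lane
#'
#' @param design a [study_design()].
#' @param condition condition index.
#' @param replicate technical replicate index (drives the noise stream).
#' @return list with `reads` (a `ReadCollection`) and `counts` (the
#'   ground-truth per-gene read counts).
#' @export
synth_reads <- function(design, condition = 1L, replicate = 1L) {
  loci <- synth_loci(design)
  truth <- synth_truth(design)
  simulate_reads(loci, truth[[paste0("expr_c", condition)]], design$depth,
                 design$read_length,
                 seed = sub_seed(design, 100L + 10L * condition + replicate))
}

#' Simulate one microarray replicate
#'
#' Probe intensity = `gain * expression * affinity + Exponential(alpha) +
#' Normal(mu, sigma)`: a deterministic probe-affinity signal on top of
#' noise drawn from the normexp convolution model.  Probe affinities are
#' log-normal and shared across replicates and conditions.
#'
#' @inheritParams synth_reads
#' @return list with `table` (a `ProbeTable`), `map` (a `ProbesetMap`) and
#'   `truth` (true per-gene expression in this condition).
#' @export
synth_array <- function(design, condition = 1L, replicate = 1L) {
  truth <- synth_truth(design)
  G <- design$genes
  P <- design$probes_per_gene
  probes <- sprintf("%s_p%02d", rep(truth$gene, each = P),
                    rep(seq_len(P), G))
  set.seed(sub_seed(design, 3L))  # affinities: one shared stream
  affinity <- stats::rlnorm(G * P, 0, design$affinity_sdlog)
  expr <- rep(truth[[paste0("expr_c", condition)]], each = P)
  set.seed(sub_seed(design, 200L + 10L * condition + replicate))
  noise <- stats::rexp(G * P, rate = 1 / design$alpha) +
    stats::rnorm(G * P, design$mu, design$sigma)
  intensity <- pmax(design$gain * expr * affinity + noise, 0)
  list(table = probe_table(probes, matrix(intensity, ncol = 1)),
       map = probeset_map(probes, rep(truth$gene, each = P)),
       truth = stats::setNames(truth[[paste0("expr_c", condition)]],
                               truth$gene))
}

write_sam <- function(reads, genome_length, path) {
  df <- reads$reads
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", unique(df$chrom),
                     as.integer(genome_length)))
  if (nrow(df) > 0) {
    flag <- ifelse(df$strand == "-", 16L, 0L)
    lines <- c(lines,
               sprintf("read_%07d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(df)), flag, df$chrom, df$start + 1L,
                       df$end - df$start))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete synthetic study on disk
#'
#' Writes everything a pipeline run needs: per-lane SAM files (plus
#' tabular twins), per-replicate array tables, the probe-to-gene map, gene
#' loci as GFF3, a machine-readable ground-truth table, and a ready-made
#' pipeline configuration (`config.json`) implementing the reference
#' cross-platform pipeline: arrays normexp -> quantile -> log2 ->
#' median-polish summarization; reads count -> RPKM -> logarithmic
#' interval mapping to [0, 16]; closing group quantile normalization over
#' all experiments.  Regenerating with the same design yields
#' byte-identical files.
#'
#' @param design a [study_design()].
#' @param dir target directory (created if needed).
#' @return invisibly, a manifest list with file paths and the config path.
#' @export
synth_study <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- synth_loci(design)
  truth <- synth_truth(design)
  loci_path <- file.path(dir, "loci.gff")
  write_loci(loci, loci_path, format = "gff3")
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  map <- NULL
  files <- list(loci = loci_path, truth = file.path(dir, "truth.tsv"),
                arrays = character(), reads_sam = character(),
                reads_tab = character())
  exps <- list()
  array_names <- character(); seq_names <- character()
  for (cond in seq_len(design$conditions)) {
    for (r in seq_len(design$reps_array)) {
      arr <- synth_array(design, cond, r)
      if (is.null(map)) {
        map <- arr$map
        write_probeset_map(map, file.path(dir, "probeset_map.tsv"))
        files$map <- file.path(dir, "probeset_map.tsv")
      }
      nm <- sprintf("array_c%dr%d", cond, r)
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(
        data.frame(probe = arr$table$probes,
                   intensity = format(arr$table$fg[, 1], digits = 10,
                                      trim = TRUE, scientific = FALSE)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      files$arrays <- c(files$arrays, p)
      e <- experiment_from_array_file(nm, p,
        column_map = list(probe_id = "probe", fg = "intensity"),
        dialect = list(header = TRUE))
      e$provenance$path <- basename(p)
      exps <- c(exps, list(e))
      array_names <- c(array_names, nm)
    }
    for (r in seq_len(design$reps_seq)) {
      lane <- synth_reads(design, cond, r)
      nm <- sprintf("seq_c%dr%d", cond, r)
      sam <- file.path(dir, paste0(nm, ".sam"))
      write_sam(lane$reads, design$genome_length, sam)
      tab <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(lane$reads$reads, tab, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files$reads_sam <- c(files$reads_sam, sam)
      files$reads_tab <- c(files$reads_tab, tab)
      e <- experiment_from_reads_file(nm, sam, format = "sam")
      e$provenance$path <- basename(sam)
      exps <- c(exps, list(e))
      seq_names <- c(seq_names, nm)
    }
  }
  tm <- transformation_matrix(exps)
  tm <- add_instance(tm, 1L, array_names, "normexp")
  tm <- add_instance(tm, 1L, seq_names, "count",
                     list(loci = loci_path, rule = "overlap_any"))
  tm <- add_instance(tm, 2L, array_names, "quantile")
  tm <- add_instance(tm, 2L, seq_names, "rpkm")
  tm <- add_instance(tm, 3L, array_names, "log2")
  tm <- add_instance(tm, 3L, seq_names, "interval_map_log",
                     list(lo = 0, hi = 16))
  tm <- add_instance(tm, 4L, array_names, "summarize",
                     list(method = "median_polish",
                          map = file.path(dir, "probeset_map.tsv")))
  tm <- add_instance(tm, 5L, c(array_names, seq_names), "quantile")
  # make source references relative so the bundle is relocatable
  for (k in seq_along(tm$instances)) {
    pr <- tm$instances[[k]]$params
    if (!is.null(pr$loci_source)) {
      tm$instances[[k]]$params$loci_source <- basename(pr$loci_source)
    }
    if (!is.null(pr$map_source)) {
      tm$instances[[k]]$params$map_source <- basename(pr$map_source)
    }
  }
  config_path <- file.path(dir, "config.json")
  save_config(tm, config_path)
  files$config <- config_path
  invisible(files)
}
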