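#' Count reads per locus
#'
#' Produces naive per-locus read counts.  A read may count toward several
#' overlapping loci.  Counting rules: `overlap_any` (any overlap between
#' read and locus, the default), `start_in` (read start position falls
#' inside the locus; useful when only start positions were imported),
#' `contained` (read lies entirely within the locus).
#'
#' @param reads a `ReadCollection`.
#' @param loci a `LocusSet`; loci need unique `id`s (auto-assigned when
#'   missing).
#' @param rule counting rule, see above.
#' @param stranded if `TRUE`, only reads on the locus strand count
#'   (unstranded loci accept both strands).
#' @return A `LocusExpression`: list with `loci`, named numeric `values`
#'   (by locus id), `mode = "naive"`, `N` (total mapped reads).
#' @export
count_reads <- function(reads, loci, rule = c("overlap_any", "start_in",
                                              "contained"),
                        stranded = FALSE) {
  rule <- match.arg(rule)
  loci <- ensure_locus_ids(loci)
  df <- reads$reads
  if (stranded && nrow(df) > 0 && all(df$strand == "*")) {
    stop("stranded counting requested but all reads are unstranded")
  }
  counts <- stats::setNames(numeric(nrow(loci)), loci$id)
  if (nrow(df) > 0 && nrow(loci) > 0) {
    rd_ir <- switch(rule,
      overlap_any = ,
      contained = IRanges::IRanges(start = df$start + 1L, end = df$end),
      start_in = IRanges::IRanges(start = df$start + 1L, width = 1L))
    lc_ir <- IRanges::IRanges(start = loci$start + 1L, end = loci$end)
    type <- if (rule == "overlap_any") "any" else "within"
    hits <- IRanges::findOverlaps(rd_ir, lc_ir, type = type)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ok <- df$chrom[q] == loci$chrom[s]
    if (stranded) {
      ok <- ok & (loci$strand[s] == "*" | df$strand[q] == loci$strand[s])
    }
    tab <- table(factor(s[ok], levels = seq_len(nrow(loci))))
    counts[] <- as.numeric(tab)
  }
  locus_expression(loci, counts, mode = "naive", N = reads$total_mapped)
}

locus_expression <- function(loci, values, mode, N) {
  structure(list(loci = loci, values = values, mode = mode, N = N),
            class = "LocusExpression")
}

#' @export
print.LocusExpression <- function(x, ...) {
  cat(sprintf("LocusExpression (%s): %d loci, N = %s\n", x$mode,
              length(x$values), format(x$N, big.mark = ",")))
  invisible(x)
}

ensure_locus_ids <- function(loci) {
  if (nrow(loci) == 0) return(loci)
  miss <- is.na(loci$id)
  if (any(miss)) {
    loci$id[miss] <- sprintf("locus_%s_%d_%d", loci$chrom[miss],
                             loci$start[miss], loci$end[miss])
  }
  if (anyDuplicated(loci$id)) {
    loci$id <- make.unique(loci$id, sep = "#")
  }
  loci
}

#' Mean per-base coverage per locus
#'
#' The coverage expression value of a locus is its mean per-base read
#' depth, `sum(depth over locus) / length(locus)`, which is independent of
#' locus length.
#'
#' @param track a `CoverageTrack` from [build_coverage()].
#' @param loci a `LocusSet`.
#' @param N total mapped reads (kept for downstream DCPM; default `NA`).
#' @return a `LocusExpression` with `mode = "coverage"`.
#' @export
coverage_value <- function(track, loci, N = NA_integer_) {
  loci <- ensure_locus_ids(loci)
  vals <- vapply(seq_len(nrow(loci)), function(i) {
    sum(coverage_window(track, loci$chrom[i], loci$start[i], loci$end[i])) /
      (loci$end[i] - loci$start[i])
  }, numeric(1))
  locus_expression(loci, stats::setNames(vals, loci$id), mode = "coverage",
                   N = N)
}

#' RPKM: reads per kilobase of feature per million mapped reads
#'
#' `rpkm = 1e9 * count / (N * L)` where `count` is the number of reads in
#' the feature, `N` the total number of mapped reads in the experiment and
#' `L` the feature length in bases.
#'
#' @param count read count(s) in the feature (vectorized).
#' @param N total mapped reads; must be > 0.
#' @param L feature length(s) in bases; must be > 0.
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(100, 1e6, 1000)  # 100
#' @export
rpkm <- function(count, N, L) {
  if (any(N <= 0)) stop("domain error: RPKM requires N > 0 mapped reads")
  if (any(L <= 0)) stop("domain error: RPKM requires feature length L > 0")
  1e9 * count / (as.numeric(N) * as.numeric(L))  # avoid integer overflow
}

#' DCPM: depth of coverage per base per million mapped reads
#'
#' The mean per-base depth over the locus divided by the number of mapped
#' reads in millions: `dcpm = (sum(depth)/L) / (N/1e6)`.
#'
#' @param track a `CoverageTrack`.
#' @param loci a `LocusSet`.
#' @param N total mapped reads; must be > 0.
#' @return a `LocusExpression` with `mode = "dcpm"`.
#' @export
dcpm <- function(track, loci, N) {
  if (length(N) != 1 || N <= 0) stop("domain error: DCPM requires N > 0 mapped reads")
  cov <- coverage_value(track, loci, N = N)
  locus_expression(cov$loci, cov$values / (N / 1e6), mode = "dcpm", N = N)
}

#' Derive loci from a coverage track
#'
#' A basic peak finder: maximal runs of positions with depth >=
#' `min_depth`, allowing internal gaps of up to `max_gap` bases, become
#' loci; runs shorter than `min_length` are dropped.  To derive loci from
#' read counts rather than full coverage, build the track from
#' start-position coverage (see [build_coverage()]).
#'
#' @param track a `CoverageTrack`.
#' @param min_depth minimal per-base depth (> 0).
#' @param min_length minimal locus length in bases.
#' @param max_gap maximal internal below-threshold gap in bases.
#' @param species species name for the derived loci.
#' @return a `LocusSet` of unstranded loci.
#' @export
derive_loci <- function(track, min_depth = 1, min_length = 1, max_gap = 0,
                        species = "unknown") {
  if (min_depth <= 0) stop("parameter error: min_depth must be > 0")
  per_chrom <- lapply(names(track), function(chrom) {
    r <- unclass(track)[[chrom]]
    ir <- IRanges::reduce(
      methods::as(IRanges::slice(r, lower = min_depth), "IRanges"),
      min.gapwidth = max_gap + 1L)
    ir <- ir[IRanges::width(ir) >= min_length]
    n <- length(ir)
    data.frame(species = rep_len(species, n), chrom = rep_len(chrom, n),
               start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir), strand = rep_len("*", n),
               id = rep_len(NA_character_, n), stringsAsFactors = FALSE)
  })
  as_locus_set(do.call(rbind, per_chrom))
}

#' Export a LocusExpression as a table
#' @param x a `LocusExpression`.
#' @param path output TSV path.
#' @export
write_locus_expression <- function(x, path) {
  df <- data.frame(feature = x$loci$id, chrom = x$loci$chrom,
                   start = x$loci$start, end = x$loci$end,
                   strand = x$loci$strand, value = unname(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
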