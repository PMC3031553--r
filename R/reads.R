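#' Import mapped sequencing reads
#'
#' Reads mapped-read files into a `ReadCollection`: reads grouped per
#' chromosome with 0-based half-open coordinates, plus the total number of
#' mapped reads (the `N` used by RPKM/DCPM normalization).  SAM/BAM `POS`
#' fields are 1-based and converted on import; the reference span of a SAM
#' record is the sum of its M/D/N/=/X CIGAR lengths.  Unmapped records are
#' skipped (but reported); multi-mapping records count once per record.
#'
#' For tabular files at least a start-position column must be mapped; when
#' no end or length column is available, read ends default to
#' `start + read_length`.
#'
#' @param path input file path.
#' @param format one of `"sam"`, `"bam"`, `"tabular"`.
#' @param column_map for tabular input, named list/vector mapping fields
#'   (`start`, and optionally `end`, `length`, `strand`, `chrom`,
#'   `species`) to column positions or header names.
#' @param defaults list of fall-backs: `species`, `chrom`, `read_length`
#'   (default 36), `strand` (default `"*"`).
#' @param dialect tabular dialect, see [parse_loci()].
#' @param coordinates tabular coordinate convention, `"0-based"` (default)
#'   or `"1-based"`.
#' @return A `ReadCollection`: list with elements `reads` (data.frame with
#'   `chrom`, `start`, `end`, `strand`), `total_mapped`, `unmapped_skipped`,
#'   `species`.
#' @export
parse_reads <- function(path, format = c("sam", "bam", "tabular"),
                        column_map = NULL, defaults = list(), dialect = list(),
                        coordinates = c("0-based", "1-based")) {
  format <- match.arg(format)
  coordinates <- match.arg(coordinates)
  defaults <- utils::modifyList(
    list(species = "unknown", chrom = NA_character_, read_length = 36L,
         strand = "*"), defaults)
  if (format == "tabular") {
    parse_reads_tabular(path, column_map, defaults, dialect, coordinates)
  } else {
    parse_reads_sambam(path, format, defaults)
  }
}

read_collection <- function(df, total_mapped = nrow(df), unmapped = 0L,
                            species = "unknown") {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(reads = df, total_mapped = as.integer(total_mapped),
                 unmapped_skipped = as.integer(unmapped), species = species),
            class = "ReadCollection")
}

#' @export
print.ReadCollection <- function(x, ...) {
  cat(sprintf("ReadCollection: %d mapped reads on %d chromosome(s) (%d unmapped skipped)\n",
              x$total_mapped, length(unique(x$reads$chrom)),
              x$unmapped_skipped))
  invisible(x)
}

## Reference-space width of a CIGAR string: sum of M/D/N/=/X op lengths
## (spliced N regions contribute coverage across the skip).
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar,
                                                   N.regions.removed = FALSE)
}

parse_reads_sambam <- function(path, format, defaults) {
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  what <- c("rname", "pos", "cigar", "strand", "flag")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  mapped <- !bitwAnd(res$flag, 4L) & !is.na(res$pos)
  n_unmapped <- sum(!mapped)
  width <- cigar_ref_width(res$cigar[mapped])
  if (any(grepl("N", res$cigar[mapped], fixed = TRUE))) {
    message("note: spliced (N) CIGAR reads contribute coverage across the skipped region")
  }
  st <- as.character(res$strand[mapped])
  st[!st %in% c("+", "-")] <- "*"
  df <- data.frame(chrom = as.character(res$rname[mapped]),
                   start = res$pos[mapped] - 1L,   # SAM 1-based -> 0-based
                   end = res$pos[mapped] - 1L + as.integer(width),
                   strand = st, stringsAsFactors = FALSE)
  read_collection(df, total_mapped = sum(mapped), unmapped = n_unmapped,
                  species = defaults$species)
}

parse_reads_tabular <- function(path, column_map, defaults, dialect,
                                coordinates) {
  tab <- read_dialect_table(path, dialect)
  if (is.null(column_map) || is.null(as.list(column_map)$start)) {
    stop("configuration error: at least read start positions are required; map a 'start' column")
  }
  cm <- resolve_columns(column_map, names(tab), "start", "reads")
  if (nrow(tab) == 0) {
    return(read_collection(data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character(),
                                      stringsAsFactors = FALSE),
                           species = defaults$species))
  }
  start <- numeric_column(tab[[cm$start]], "start")
  if (coordinates == "1-based") start <- start - 1
  end <- if (!is.null(cm$end)) {
    e <- numeric_column(tab[[cm$end]], "end")
    if (coordinates == "1-based") e else e  # 1-based incl == 0-based excl
  } else if (!is.null(cm$length)) {
    start + numeric_column(tab[[cm$length]], "length")
  } else {
    start + defaults$read_length
  }
  strand <- if (!is.null(cm$strand)) {
    normalize_strand_tokens(tab[[cm$strand]])
  } else rep(defaults$strand, nrow(tab))
  chrom <- if (!is.null(cm$chrom)) tab[[cm$chrom]] else {
    if (is.na(defaults$chrom)) {
      stop("configuration error: no chromosome column mapped and no default chromosome given")
    }
    rep(defaults$chrom, nrow(tab))
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) {
    stop(sprintf("parse error at data row %d: read end <= start",
                 which(df$end <= df$start)[1]))
  }
  read_collection(df, species = defaults$species)
}

#' Per-base read coverage
#'
#' Builds a sparse per-base depth track from a read collection: depth at
#' position `p` is the number of reads `r` with `r$start <= p < r$end`.
#' The track is stored run-length encoded per chromosome, so memory is
#' proportional to the number of depth changes, not to genome size.
#'
#' @param reads a `ReadCollection`.
#' @param strand optional strand filter (`"+"` or `"-"`).
#' @return A `CoverageTrack`: named list of [IRanges::Rle] depth vectors,
#'   one per chromosome, each covering positions `0 .. max(end)-1`.
#' @export
build_coverage <- function(reads, strand = NULL) {
  df <- reads$reads
  if (!is.null(strand)) df <- df[df$strand == strand, , drop = FALSE]
  track <- lapply(split(df, df$chrom), function(g) {
    IRanges::coverage(IRanges::IRanges(start = g$start + 1L, end = g$end))
  })
  structure(track, class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack over %d chromosome(s); total depth %s\n",
              length(x), format(coverage_total(x), big.mark = ",")))
  invisible(x)
}

coverage_total <- function(track) {
  sum(vapply(unclass(track), function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                               S4Vectors::runLength(r)),
             numeric(1)))
}

## Depth vector over [start, end) of one chromosome (0-based half-open).
coverage_window <- function(track, chrom, start, end) {
  r <- unclass(track)[[chrom]]
  if (is.null(r)) return(numeric(end - start))
  n <- length(r)
  lo <- start + 1L; hi <- end  # 1-based inclusive window into the Rle
  if (lo > n) return(numeric(end - start))
  head_part <- as.numeric(S4Vectors::window(r, lo, min(hi, n)))
  c(head_part, numeric(max(0L, hi - n)))
}
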