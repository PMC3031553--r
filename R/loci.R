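#' Construct a set of genomic loci
#'
#' A `LocusSet` is the unit of cross-platform comparison: a collection of
#' stranded intervals on named chromosomes of a named species.  Coordinates
#' are 0-based half-open internally (`start` inclusive, `end` exclusive), so
#' `length = end - start`.  External 1-based inclusive formats (GFF3, PTT)
#' are converted on import and export.
#'
#' @param species character vector of species names (recycled).
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, 0-based exclusive end positions.
#' @param strand character vector in `c("+", "-", "*")`; `"*"` means
#'   unstranded.  Recycled.
#' @param id optional feature identifiers (recycled; `NA` allowed).
#' @return An object of class `LocusSet`: a data.frame with columns
#'   `species`, `chrom`, `start`, `end`, `strand`, `id`.
#' @examples
#' locus_set(chrom = "chr1", start = c(0, 100), end = c(50, 200))
#' @export
locus_set <- function(species = "unknown", chrom, start, end, strand = "*",
                      id = NA_character_) {
  n <- max(length(chrom), length(start), length(end), 0L)
  if (n == 0L) {
    df <- data.frame(species = character(), chrom = character(),
                     start = integer(), end = integer(),
                     strand = character(), id = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("LocusSet", "data.frame")
    return(df)
  }
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  bad_strand <- !strand %in% c("+", "-", "*")
  if (any(bad_strand)) {
    stop("invalid strand value(s): ",
         paste(unique(strand[bad_strand]), collapse = ", "))
  }
  df <- data.frame(species = rep_len(as.character(species), n),
                   chrom = rep_len(as.character(chrom), n),
                   start = rep_len(start, n),
                   end = rep_len(end, n),
                   strand = rep_len(strand, n),
                   id = rep_len(as.character(id), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("locus start positions must be >= 0")
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(sprintf("locus %d has end (%d) <= start (%d); empty loci are not allowed",
                 i, df$end[i], df$start[i]))
  }
  rownames(df) <- NULL
  class(df) <- c("LocusSet", "data.frame")
  df
}

#' @export
print.LocusSet <- function(x, ...) {
  cat(sprintf("LocusSet with %d loci on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' @export
`[.LocusSet` <- function(x, i, j, ...) {
  df <- as.data.frame(x)
  if (missing(j)) {                    # row subset: keep the class
    out <- df[i, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("LocusSet", "data.frame")
    return(out)
  }
  if (missing(i)) df[, j, ...] else df[i, j, ...]
}

#' Locus lengths in bases
#' @param x a `LocusSet`.
#' @return integer vector of `end - start`.
#' @export
locus_lengths <- function(x) x$end - x$start

## Sort loci by (species, chrom, strand?, start, end); stable.
sort_loci <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(x$species, x$chrom, x$start, x$end, x$strand), ]
}

## Grouping key for stranded locus algebra: loci on different strands are
## never merged, and "*" forms its own group.
locus_group_key <- function(x, ignore_strand = FALSE) {
  st <- if (ignore_strand) "*" else x$strand
  paste(x$species, x$chrom, st, sep = "\r")
}

#' Parse locus annotations
#'
#' Reads locus annotations from GFF3, NCBI PTT, or generic delimited text.
#' GFF and PTT coordinates are 1-based inclusive and converted to the
#' internal 0-based half-open convention.  Comment lines are skipped.
#'
#' @param path file path (or connection for `format = "tabular"`).
#' @param format one of `"gff"`, `"ptt"`, `"tabular"`.
#' @param column_map for tabular input, a named list/vector assigning fields
#'   to column positions (1-based) or column names; must cover at least
#'   `start` and either `end` or `length`.  Recognized fields: `species`,
#'   `chrom`, `start`, `end`, `length`, `strand`, `id`.
#' @param defaults named list of fill-in values (`species`, `chrom`,
#'   `strand`) for attributes absent from the file.
#' @param dialect for tabular input, a list with elements `sep` (default
#'   `"\t"`), `quote` (default `"\""`), `comment` (default `"#"`),
#'   `header` (default `FALSE`).
#' @param coordinates origin convention of tabular input: `"1-based"`
#'   (inclusive, default) or `"0-based"` (half-open).
#' @return A [locus_set()].
#' @export
parse_loci <- function(path, format = c("gff", "ptt", "tabular"),
                       column_map = NULL, defaults = list(),
                       dialect = list(), coordinates = c("1-based", "0-based")) {
  format <- match.arg(format)
  coordinates <- match.arg(coordinates)
  defaults <- utils::modifyList(
    list(species = "unknown", chrom = NA_character_, strand = "*"), defaults)
  switch(format,
         gff = parse_loci_gff(path, defaults),
         ptt = parse_loci_ptt(path, defaults),
         tabular = parse_loci_tabular(path, column_map, defaults, dialect,
                                      coordinates))
}

parse_loci_gff <- function(path, defaults) {
  gr <- rtracklayer::import(path, format = "gff")
  if (length(gr) == 0) return(locus_set(chrom = character(), start = integer(),
                                        end = integer()))
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "."] <- "*"
  ids <- as.character(if (!is.null(gr$ID)) gr$ID
                      else if (!is.null(gr$Name)) gr$Name else NA)
  locus_set(species = defaults$species,
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = BiocGenerics::start(gr) - 1L,  # 1-based incl -> 0-based
            end = BiocGenerics::end(gr),
            strand = st, id = ids)
}

parse_loci_ptt <- function(path, defaults) {
  lines <- readLines(path)
  # PTT: description line, "NNN proteins" line, header line, then records.
  hdr <- grep("^Location\t", lines)
  if (length(hdr) == 0) stop("not a PTT file: no 'Location' header line found")
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(locus_set(chrom = character(),
                                          start = integer(), end = integer()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  loc <- vapply(fields, `[`, character(1), 1L)
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("PTT parse error at record %d: malformed location '%s'",
                 which(bad)[1], loc[which(bad)[1]]))
  }
  s1 <- as.integer(vapply(m, `[`, character(1), 2L))
  e1 <- as.integer(vapply(m, `[`, character(1), 3L))
  st <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "*",
               character(1))
  st[!st %in% c("+", "-")] <- "*"
  ids <- vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_character_,
                character(1))
  chrom <- defaults$chrom
  if (is.na(chrom)) chrom <- "chr"
  locus_set(species = defaults$species, chrom = chrom,
            start = s1 - 1L, end = e1, strand = st, id = ids)
}

resolve_columns <- function(column_map, header_names, required, what) {
  if (is.null(column_map)) {
    stop(sprintf("configuration error: a column map is required for tabular %s input",
                 what))
  }
  column_map <- as.list(column_map)
  for (f in required) {
    if (is.null(column_map[[f]])) {
      stop(sprintf("configuration error: mandatory field '%s' is not mapped to any column",
                   f))
    }
  }
  lapply(column_map, function(v) {
    if (is.character(v)) {
      j <- match(v, header_names)
      if (is.na(j)) stop(sprintf("configuration error: column '%s' not found in file header", v))
      j
    } else as.integer(v)
  })
}

read_dialect_table <- function(path, dialect) {
  dialect <- utils::modifyList(
    list(sep = "\t", quote = "\"", comment = "#", header = FALSE), dialect)
  utils::read.table(path, sep = dialect$sep, quote = dialect$quote,
                    comment.char = dialect$comment, header = dialect$header,
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, blank.lines.skip = TRUE)
}

numeric_column <- function(x, field) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v)) {
    stop(sprintf("parse error at data row %d: non-numeric %s value '%s'",
                 which(is.na(v))[1], field, x[which(is.na(v))[1]]))
  }
  v
}

parse_loci_tabular <- function(path, column_map, defaults, dialect,
                               coordinates) {
  tab <- read_dialect_table(path, dialect)
  cm <- resolve_columns(column_map, names(tab), "start", "locus")
  if (is.null(cm$end) && is.null(cm$length)) {
    stop("configuration error: mandatory field 'end' (or 'length') is not mapped to any column")
  }
  if (nrow(tab) == 0) {
    return(locus_set(chrom = character(), start = integer(), end = integer()))
  }
  pick <- function(field, default) {
    if (!is.null(cm[[field]])) tab[[cm[[field]]]] else rep(default, nrow(tab))
  }
  start <- numeric_column(tab[[cm$start]], "start")
  if (coordinates == "1-based") start <- start - 1
  # a 1-based inclusive end equals the 0-based exclusive end numerically;
  # length spans are origin-independent
  end <- if (!is.null(cm$end)) numeric_column(tab[[cm$end]], "end")
         else start + numeric_column(tab[[cm$length]], "length")
  strand <- as.character(pick("strand", defaults$strand))
  strand <- normalize_strand_tokens(strand, warn = FALSE)
  chrom <- pick("chrom", defaults$chrom)
  if (anyNA(chrom)) {
    stop("configuration error: no chromosome column mapped and no default chromosome given")
  }
  locus_set(species = pick("species", defaults$species), chrom = chrom,
            start = start, end = end, strand = strand,
            id = pick("id", NA_character_))
}

## Accepts +/-, F/R, 0/1; anything else becomes unstranded.
normalize_strand_tokens <- function(x, warn = TRUE) {
  out <- rep("*", length(x))
  out[x %in% c("+", "F", "f", "0")] <- "+"
  out[x %in% c("-", "−", "R", "r", "1")] <- "-"
  unknown <- !x %in% c("+", "F", "f", "0", "-", "−", "R", "r", "1", "*",
                       ".", NA)
  if (warn && any(unknown)) {
    warning(sprintf("%d unrecognized strand token(s) (e.g. '%s') treated as unstranded",
                    sum(unknown), x[which(unknown)[1]]))
  }
  out
}

#' Export loci as GFF3 or BED
#'
#' GFF3 output is 1-based inclusive; BED output keeps the internal 0-based
#' half-open convention.
#'
#' @param x a `LocusSet`.
#' @param path output file path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(x, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  ids <- ifelse(is.na(x$id), paste0("locus_", seq_len(nrow(x))), x$id)
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tseasight\tregion\t%d\t%d\t.\t%s\t.\tID=%s",
                       x$chrom, x$start + 1L, x$end,
                       ifelse(x$strand == "*", ".", x$strand), ids))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, ids,
                     ifelse(x$strand == "*", ".", x$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert a LocusSet to a GRanges object
#' @param x a `LocusSet`.
#' @return a `GRanges` (1-based inclusive, as GRanges requires).
#' @export
loci_as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand)
}
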