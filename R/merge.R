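#' Locus set merging
#'
#' Four methods to reconcile several locus sets into one common set of
#' interrogated positions.  All methods operate per (species, chromosome,
#' strand) group: loci on different strands are never merged, and
#' unstranded loci (`"*"`) form their own group; set `ignore_strand = TRUE`
#' to collapse strands first (e.g. for non-strand-specific protocols).
#'
#' \describe{
#'   \item{`merge_union`}{keeps all unique loci of all input sets (two loci
#'     are identical iff they share species, chromosome, start, end and
#'     strand), then drops loci shorter than `min_size`.}
#'   \item{`merge_pairwise`}{produces one candidate locus for each pair of
#'     neighboring boundary coordinates (the sorted unique starts and ends
#'     of all input loci) and keeps a candidate iff it is covered by at
#'     least one input locus; candidates shorter than `min_size` are
#'     dropped.  Gives the highest coordinate resolution.}
#'   \item{`merge_greedy`}{scans pooled loci in (start, end) order and joins
#'     a locus to the growing cluster iff it overlaps the cluster span by at
#'     least `min_overlap` bases (overlap mode) or lies within
#'     `max_distance` bases of it (distance mode); exactly one of the two
#'     criteria must be given.  Each cluster emits its spanning locus.}
#'   \item{`merge_minmax`}{finds maximal extensions by absorbing overlapping
#'     loci left to right as long as the extended span stays within
#'     `max_size`; an extension is emitted iff its length is at least
#'     `min_size`.}
#' }
#'
#' @param sets a list of `LocusSet` objects (a single `LocusSet` is
#'   accepted).
#' @param min_size minimal output locus length in bases (>= 1).
#' @param min_overlap minimal overlap in bases (greedy overlap mode).
#' @param max_distance maximal gap in bases (greedy distance mode).  The gap
#'   between two loci is `b$start - a$end` for `a` before `b`; overlapping
#'   loci have gap 0.
#' @param max_size maximal extension length in bases (minmax).
#' @param ignore_strand collapse strand information before merging.
#' @return a `LocusSet`, sorted by (species, chrom, start).
#' @name locus_merge
NULL

pool_loci <- function(sets, ignore_strand = FALSE) {
  if (inherits(sets, "LocusSet")) sets <- list(sets)
  if (!is.list(sets) || length(sets) < 1) {
    stop("parameter error: at least one input LocusSet is required")
  }
  pooled <- do.call(rbind, lapply(sets, as.data.frame))
  class(pooled) <- c("LocusSet", "data.frame")
  if (ignore_strand && nrow(pooled) > 0) pooled$strand <- "*"
  pooled
}

check_min_size <- function(min_size) {
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size < 1) {
    stop("parameter error: min_size must be a single number >= 1")
  }
}

#' @rdname locus_merge
#' @export
merge_union <- function(sets, min_size = 1, ignore_strand = FALSE) {
  check_min_size(min_size)
  pooled <- pool_loci(sets, ignore_strand)
  if (nrow(pooled) == 0) return(pooled)
  key <- paste(pooled$species, pooled$chrom, pooled$start, pooled$end,
               pooled$strand, sep = "\r")
  out <- pooled[!duplicated(key), ]
  out <- out[locus_lengths(out) >= min_size, ]
  sort_loci(out)
}

#' @rdname locus_merge
#' @export
merge_pairwise <- function(sets, min_size = 1, ignore_strand = FALSE) {
  check_min_size(min_size)
  pooled <- pool_loci(sets, ignore_strand)
  if (nrow(pooled) == 0) return(pooled)
  groups <- split(seq_len(nrow(pooled)), locus_group_key(pooled, FALSE))
  res <- lapply(groups, function(idx) {
    g <- pooled[idx, ]
    bounds <- sort(unique(c(g$start, g$end)))
    cs <- bounds[-length(bounds)]
    ce <- bounds[-1]
    # keep candidates covered by >= 1 input locus
    covered <- vapply(seq_along(cs), function(i) {
      any(g$start < ce[i] & g$end > cs[i])
    }, logical(1))
    keep <- covered & (ce - cs) >= min_size
    group_loci_df(g, cs[keep], ce[keep])
  })
  as_locus_set(do.call(rbind, res))
}

#' @rdname locus_merge
#' @export
merge_greedy <- function(sets, min_overlap = NULL, max_distance = NULL,
                         ignore_strand = FALSE) {
  if (is.null(min_overlap) == is.null(max_distance)) {
    stop("parameter error: exactly one of min_overlap and max_distance must be given")
  }
  overlap_mode <- !is.null(min_overlap)
  if (overlap_mode && min_overlap < 0) stop("parameter error: min_overlap must be >= 0")
  if (!overlap_mode && max_distance < 0) stop("parameter error: max_distance must be >= 0")
  pooled <- pool_loci(sets, ignore_strand)
  if (nrow(pooled) == 0) return(pooled)
  groups <- split(seq_len(nrow(pooled)), locus_group_key(pooled, FALSE))
  res <- lapply(groups, function(idx) {
    g <- pooled[idx, ]
    g <- g[order(g$start, g$end), ]
    cs <- g$start[1]; ce <- g$end[1]
    starts <- integer(); ends <- integer()
    for (i in seq_len(nrow(g))[-1]) {
      join <- if (overlap_mode) {
        min(ce, g$end[i]) - max(cs, g$start[i]) >= min_overlap
      } else {
        g$start[i] - ce <= max_distance
      }
      if (join) {
        ce <- max(ce, g$end[i])
      } else {
        starts <- c(starts, cs); ends <- c(ends, ce)
        cs <- g$start[i]; ce <- g$end[i]
      }
    }
    starts <- c(starts, cs); ends <- c(ends, ce)
    group_loci_df(g, starts, ends)
  })
  as_locus_set(do.call(rbind, res))
}

group_loci_df <- function(g, starts, ends) {
  n <- length(starts)
  data.frame(species = rep_len(g$species[1], n),
             chrom = rep_len(g$chrom[1], n),
             start = starts, end = ends,
             strand = rep_len(g$strand[1], n),
             id = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

#' @rdname locus_merge
#' @export
merge_minmax <- function(sets, min_size = 1, max_size = Inf,
                         ignore_strand = FALSE) {
  check_min_size(min_size)
  if (min_size > max_size) stop("parameter error: min_size must be <= max_size")
  pooled <- pool_loci(sets, ignore_strand)
  if (nrow(pooled) == 0) return(pooled)
  groups <- split(seq_len(nrow(pooled)), locus_group_key(pooled, FALSE))
  res <- lapply(groups, function(idx) {
    g <- pooled[idx, ]
    g <- g[order(g$start, g$end), ]
    cs <- g$start[1]; ce <- g$end[1]
    starts <- integer(); ends <- integer()
    emit <- function(s, e) {
      if (e - s >= min_size && e - s <= max_size) {
        starts <<- c(starts, s); ends <<- c(ends, e)
      }
    }
    for (i in seq_len(nrow(g))[-1]) {
      absorb <- g$start[i] < ce && max(ce, g$end[i]) - cs <= max_size
      if (absorb) {
        ce <- max(ce, g$end[i])
      } else {
        emit(cs, ce)
        cs <- g$start[i]; ce <- g$end[i]
      }
    }
    emit(cs, ce)
    group_loci_df(g, starts, ends)
  })
  as_locus_set(do.call(rbind, res))
}

as_locus_set <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(locus_set(chrom = character(), start = integer(), end = integer()))
  }
  rownames(df) <- NULL
  class(df) <- c("LocusSet", "data.frame")
  sort_loci(df)
}

#' Filter one locus set against another
#'
#' A target locus is kept iff some reference locus overlaps it by at least
#' `min_overlap` bases and lies within `max_distance` bases (the gap between
#' overlapping loci is 0).  Both criteria must hold for the same reference
#' locus.  Strand-compatible means equal strand or either locus unstranded.
#'
#' @param target,reference `LocusSet` objects.
#' @param min_overlap minimal overlap in bases (default 0).
#' @param max_distance maximal gap in bases (default 0).
#' @param ignore_strand disregard strand when matching.
#' @return the surviving subset of `target`, input order preserved.
#' @export
filter_loci <- function(target, reference, min_overlap = 0, max_distance = 0,
                        ignore_strand = FALSE) {
  if (min_overlap < 0 || max_distance < 0) {
    stop("parameter error: min_overlap and max_distance must be >= 0")
  }
  if (nrow(reference) == 0) {
    warning("empty reference set: filter_loci returns an empty set")
    return(target[integer(0), ])
  }
  keep <- vapply(seq_len(nrow(target)), function(i) {
    t <- target[i, ]
    cand <- reference$species == t$species & reference$chrom == t$chrom
    if (!ignore_strand) {
      cand <- cand & (reference$strand == t$strand | reference$strand == "*" |
                        t$strand == "*")
    }
    if (!any(cand)) return(FALSE)
    r <- reference[cand, ]
    ov <- pmax(0L, pmin(r$end, t$end) - pmax(r$start, t$start))
    gap <- pmax(0L, pmax(r$start, t$start) - pmin(r$end, t$end))
    any(ov >= min_overlap & gap <= max_distance)
  }, logical(1))
  target[keep, ]
}

#' Edit loci
#'
#' Applies coordinate and naming edits in a fixed order: rename, strand
#' operation, shift, then length change.  The input set is not modified.
#'
#' @param set a `LocusSet`.
#' @param shift signed number of bases to translate all loci by.
#' @param set_length either `NULL` or a list `list(value =, anchor =)` with
#'   `anchor` one of `"start"`, `"end"`, `"center"`; resizes every locus to
#'   `value` bases keeping the anchor fixed.
#' @param strand_op one of `"keep"`, `"flip"`, `"clear"`.
#' @param rename named character vector mapping old to new names, applied to
#'   both species and chromosome names.
#' @return the edited `LocusSet`.
#' @examples
#' edit_loci(locus_set(chrom = "c", start = 5, end = 15), shift = 10)
#' @export
edit_loci <- function(set, shift = 0, set_length = NULL,
                      strand_op = c("keep", "flip", "clear"), rename = NULL) {
  strand_op <- match.arg(strand_op)
  out <- as.data.frame(set)
  if (!is.null(rename)) {
    hit <- out$species %in% names(rename)
    out$species[hit] <- rename[out$species[hit]]
    hit <- out$chrom %in% names(rename)
    out$chrom[hit] <- rename[out$chrom[hit]]
  }
  if (strand_op == "flip") {
    out$strand <- c("+" = "-", "-" = "+", "*" = "*")[out$strand]
  } else if (strand_op == "clear") {
    out$strand <- "*"
  }
  if (shift != 0) {
    if (any(out$start + shift < 0)) {
      i <- which(out$start + shift < 0)[1]
      stop(sprintf("range error: shifting locus %s:%d-%d by %d would move its start below 0",
                   out$chrom[i], out$start[i], out$end[i], shift))
    }
    out$start <- out$start + as.integer(shift)
    out$end <- out$end + as.integer(shift)
  }
  if (!is.null(set_length)) {
    v <- as.integer(set_length$value)
    if (is.na(v) || v <= 0) stop("parameter error: set_length value must be > 0")
    anchor <- match.arg(set_length$anchor, c("start", "end", "center"))
    if (anchor == "start") {
      out$end <- out$start + v
    } else if (anchor == "end") {
      out$start <- out$end - v
      if (any(out$start < 0)) stop("range error: resizing would move a start below 0")
    } else {
      ctr <- (out$start + out$end) %/% 2L
      out$start <- ctr - v %/% 2L
      out$end <- out$start + v
      if (any(out$start < 0)) stop("range error: resizing would move a start below 0")
    }
  }
  rownames(out) <- NULL
  class(out) <- c("LocusSet", "data.frame")
  out
}
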