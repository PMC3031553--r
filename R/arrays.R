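#' Import raw microarray probe data
#'
#' Parses a generic delimited probe-level table into a `ProbeTable`:
#' per-probe foreground (and optional background) intensities for one or
#' two channels.  Binary vendor formats are out of scope; their standard
#' tabular exports are read via the column map.  Channel count is inferred
#' from the number of mapped foreground columns.
#'
#' @param path input file path.
#' @param column_map named list mapping `probe_id`, `fg` (one column, or a
#'   vector of two for two-channel data), optional `bg` (same length as
#'   `fg`), optional `block` (printtip/block index) to column positions or
#'   header names.
#' @param dialect tabular dialect, see [parse_loci()].
#' @return A `ProbeTable`: list with `probes` (character), `fg` (numeric
#'   matrix, probes x channels), `bg` (matrix or `NULL`), `block` (integer
#'   or `NULL`), `channels`.
#' @export
parse_array <- function(path, column_map, dialect = list()) {
  tab <- read_dialect_table(path, dialect)
  cm <- as.list(column_map)
  if (is.null(cm$probe_id) || is.null(cm$fg)) {
    stop("configuration error: column map must assign 'probe_id' and 'fg'")
  }
  resolve_one <- function(v) {
    if (is.character(v)) {
      j <- match(v, names(tab))
      if (anyNA(j)) stop(sprintf("configuration error: column '%s' not found",
                                 v[which(is.na(j))[1]]))
      j
    } else as.integer(v)
  }
  pid_col <- resolve_one(cm$probe_id)
  fg_cols <- resolve_one(cm$fg)
  bg_cols <- if (!is.null(cm$bg)) resolve_one(cm$bg) else NULL
  if (!is.null(bg_cols) && length(bg_cols) != length(fg_cols)) {
    stop("configuration error: bg columns must match fg columns in number")
  }
  probes <- as.character(tab[[pid_col]])
  if (anyDuplicated(probes)) {
    stop(sprintf("duplicate probe_id '%s'", probes[anyDuplicated(probes)]))
  }
  to_mat <- function(cols, what) {
    m <- vapply(cols, function(j) numeric_column(tab[[j]], what),
                numeric(nrow(tab)))
    m <- matrix(m, nrow = nrow(tab))
    if (any(m < 0)) {
      stop(sprintf("parse error: negative %s intensity at data row %d", what,
                   which(apply(m < 0, 1, any))[1]))
    }
    rownames(m) <- probes
    m
  }
  fg <- to_mat(fg_cols, "foreground")
  bg <- if (!is.null(bg_cols)) to_mat(bg_cols, "background") else NULL
  block <- if (!is.null(cm$block)) {
    as.integer(numeric_column(tab[[resolve_one(cm$block)]], "block"))
  } else NULL
  probe_table(probes, fg, bg, block)
}

#' Construct a ProbeTable in memory
#' @param probes character probe identifiers (unique).
#' @param fg numeric matrix probes x channels of foreground intensities.
#' @param bg optional matching background matrix.
#' @param block optional integer printtip/block index per probe.
#' @return a `ProbeTable`.
#' @export
probe_table <- function(probes, fg, bg = NULL, block = NULL) {
  fg <- as.matrix(fg)
  rownames(fg) <- probes
  if (!is.null(bg)) {
    bg <- as.matrix(bg)
    rownames(bg) <- probes
  }
  structure(list(probes = probes, fg = fg, bg = bg, block = block,
                 channels = ncol(fg)), class = "ProbeTable")
}

#' @export
print.ProbeTable <- function(x, ...) {
  cat(sprintf("ProbeTable: %d probes, %d channel(s)%s\n", length(x$probes),
              x$channels, if (!is.null(x$bg)) ", with background" else ""))
  invisible(x)
}

#' Import a probe-to-feature map
#'
#' Reads a two-column table mapping probe identifiers (many) to feature /
#' probeset identifiers (one).  A probe mapped to two distinct features is
#' an error; probes absent from the map are permitted.
#'
#' @param path input file path.
#' @param dialect tabular dialect, see [parse_loci()]; unlike the other
#'   parsers, maps default to `header = TRUE` (matching
#'   [write_probeset_map()] and typical annotation exports).
#' @param columns length-2 vector: probe column, feature column (positions
#'   or header names; default first two columns).
#' @return a named character vector `probe_id -> feature_id` of class
#'   `ProbesetMap`.
#' @export
parse_probeset_map <- function(path, dialect = list(), columns = c(1, 2)) {
  dialect <- utils::modifyList(list(header = TRUE), dialect)
  tab <- read_dialect_table(path, dialect)
  if (nrow(tab) == 0) {
    warning("empty probeset map file")
    return(probeset_map(character(), character()))
  }
  if (ncol(tab) < 2) stop("probeset map needs two mappable columns")
  j <- if (is.character(columns)) match(columns, names(tab)) else as.integer(columns)
  probeset_map(as.character(tab[[j[1]]]), as.character(tab[[j[2]]]))
}

#' @rdname parse_probeset_map
#' @param probes,features character vectors of equal length.
#' @export
probeset_map <- function(probes, features) {
  dup <- duplicated(probes)
  if (any(dup)) {
    conflict <- tapply(features, probes, function(f) length(unique(f)) > 1)
    if (any(conflict)) {
      stop(sprintf("ambiguous map: probe '%s' is assigned to multiple features",
                   names(conflict)[which(conflict)[1]]))
    }
    features <- features[!dup]
    probes <- probes[!dup]
  }
  structure(stats::setNames(features, probes), class = "ProbesetMap")
}

#' Write a probeset map as TSV
#' @param map a `ProbesetMap`.
#' @param path output path.
#' @export
write_probeset_map <- function(map, path) {
  utils::write.table(data.frame(probe = names(map),
                                feature = as.character(unclass(map))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
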