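#' Data states
#'
#' A `DataState` describes the semantics of one experiment's data at one
#' point of the processing pipeline: what entity the rows are (probes,
#' probesets, reads, loci, plain identifiers), how many channels, whether
#' values are on linear or log scale, what they measure, and processing
#' flags.  Transformations declare which states they accept and which
#' state they produce, so a whole pipeline can be validated before any
#' value is computed.
#'
#' @param entity one of `"probe"`, `"probeset"`, `"read"`, `"locus"`,
#'   `"identifier"`.
#' @param channels 1 or 2.
#' @param scale `"linear"` or `"log"`.
#' @param measure one of `"intensity"`, `"ratio"`, `"count"`,
#'   `"coverage"`, `"expression"`.
#' @param bg_corrected,normalized,loci_attached logical flags.
#' @param row_count number of rows (features / reads) in the experiment.
#' @return a `DataState`.
#' @export
data_state <- function(entity, channels = 1L, scale = "linear",
                       measure = "intensity", bg_corrected = FALSE,
                       normalized = FALSE, row_count = NA_integer_,
                       loci_attached = FALSE) {
  entity <- match.arg(entity, c("probe", "probeset", "read", "locus",
                                "identifier"))
  scale <- match.arg(scale, c("linear", "log"))
  measure <- match.arg(measure, c("intensity", "ratio", "count", "coverage",
                                  "expression"))
  if (!channels %in% c(1L, 2L)) stop("channels must be 1 or 2")
  if (measure == "ratio" && channels < 1) stop("ratio measure implies a channel origin")
  structure(list(entity = entity, channels = as.integer(channels),
                 scale = scale, measure = measure,
                 bg_corrected = isTRUE(bg_corrected),
                 normalized = isTRUE(normalized),
                 row_count = as.integer(row_count),
                 loci_attached = isTRUE(loci_attached)),
            class = "DataState")
}

state_update <- function(state, ...) {
  do.call(data_state, utils::modifyList(unclass(state), list(...)))
}

#' @method format DataState
#' @export
format.DataState <- function(x, ...) {
  sprintf("%s[%d] %s %s%s%s%s n=%s", x$entity, x$channels, x$scale,
          x$measure, if (x$bg_corrected) " bg" else "",
          if (x$normalized) " norm" else "",
          if (x$loci_attached) " loci" else "",
          ifelse(is.na(x$row_count), "?", x$row_count))
}

#' @export
print.DataState <- function(x, ...) {
  cat("DataState:", format(x), "\n")
  invisible(x)
}

states_equal <- function(a, b) {
  identical(unclass(a)[c("entity", "channels", "scale", "measure",
                         "bg_corrected", "normalized", "loci_attached")],
            unclass(b)[c("entity", "channels", "scale", "measure",
                         "bg_corrected", "normalized", "loci_attached")]) &&
    (is.na(a$row_count) || is.na(b$row_count) ||
       a$row_count == b$row_count)
}

## ---- experiments ----------------------------------------------------------

#' Experiments
#'
#' An `Experiment` is one data column of the study: a microarray replicate
#' or a sequencing lane, together with its current `DataState`.
#' `experiment_from_array` wraps a parsed `ProbeTable`;
#' `experiment_from_reads` wraps a `ReadCollection`.  The `*_file`
#' variants parse the file and record its provenance (path, format,
#' column map, md5 checksum) so the pipeline configuration can be saved
#' and reloaded.
#'
#' @param name unique experiment name.
#' @param probe_table a `ProbeTable`.
#' @return an `Experiment`.
#' @export
experiment_from_array <- function(name, probe_table, provenance = NULL) {
  channels <- lapply(seq_len(probe_table$channels), function(j) {
    stats::setNames(probe_table$fg[, j], probe_table$probes)
  })
  bg <- if (!is.null(probe_table$bg)) {
    lapply(seq_len(ncol(probe_table$bg)), function(j) {
      stats::setNames(probe_table$bg[, j], probe_table$probes)
    })
  } else NULL
  structure(list(
    name = name,
    data = list(channels = channels, bg = bg, reads = NULL, loci = NULL,
                block = probe_table$block),
    state = data_state("probe", channels = probe_table$channels,
                       scale = "linear", measure = "intensity",
                       row_count = length(probe_table$probes)),
    provenance = provenance), class = "Experiment")
}

#' @rdname experiment_from_array
#' @param reads a `ReadCollection`.
#' @param provenance internal; source description recorded by the `_file`
#'   constructors.
#' @export
experiment_from_reads <- function(name, reads, provenance = NULL) {
  structure(list(
    name = name,
    data = list(channels = list(), bg = NULL, reads = reads, loci = NULL,
                block = NULL),
    state = data_state("read", channels = 1L, scale = "linear",
                       measure = "count", row_count = reads$total_mapped),
    provenance = provenance), class = "Experiment")
}

#' @rdname experiment_from_array
#' @param path source file path.
#' @param column_map,dialect,defaults,format,coordinates passed to the
#'   respective parser ([parse_array()], [parse_reads()]).
#' @export
experiment_from_array_file <- function(name, path, column_map,
                                       dialect = list()) {
  pt <- parse_array(path, column_map, dialect)
  prov <- list(type = "array_file", path = path, column_map = column_map,
               dialect = dialect, checksum = unname(tools::md5sum(path)))
  experiment_from_array(name, pt, provenance = prov)
}

#' @rdname experiment_from_array
#' @export
experiment_from_reads_file <- function(name, path, format = "sam",
                                       column_map = NULL, defaults = list(),
                                       dialect = list(),
                                       coordinates = "0-based") {
  rc <- parse_reads(path, format, column_map, defaults, dialect, coordinates)
  prov <- list(type = "reads_file", path = path, format = format,
               column_map = column_map, defaults = defaults,
               dialect = dialect, coordinates = coordinates,
               checksum = unname(tools::md5sum(path)))
  experiment_from_reads(name, rc, provenance = prov)
}

#' @export
print.Experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s': %s\n", x$name, format(x$state)))
  invisible(x)
}

observed_row_count <- function(exp) {
  if (exp$state$entity == "read") return(exp$data$reads$total_mapped)
  if (length(exp$data$channels) == 0) return(NA_integer_)
  length(exp$data$channels[[1]])
}

## ---- transformation registry ----------------------------------------------

.transformations <- new.env(parent = emptyenv())

#' Register a transformation
#'
#' A transformation supplies a predicate over input data states
#' (`accepts`), a state transition (`produces`), and the actual value
#' computation (`apply`).  `accepts` and `produces` let the engine
#' validate whole pipelines without computing anything.
#'
#' @param name unique transformation name (used in configurations).
#' @param arity `"per_experiment"` (applied independently to each selected
#'   experiment), `"group"` (one joint application over >= 2 experiments),
#'   or `"either"`.
#' @param accepts `function(state, params, exp)` returning `TRUE` or a
#'   character diagnostic; `exp` may be `NULL` during pure prediction.
#' @param produces `function(state, params)` returning the output
#'   `DataState`.
#' @param apply `function(exps, params)` mapping a list of `Experiment`s to
#'   the transformed list (same order; `data` fields updated).
#' @param params_default named list of default parameters.
#' @return `name`, invisibly.
#' @export
register_transformation <- function(name, arity, accepts, produces, apply,
                                    params_default = list()) {
  assign(name, list(name = name, arity = arity, accepts = accepts,
                    produces = produces, apply = apply,
                    params_default = params_default),
         envir = .transformations)
  invisible(name)
}

#' @rdname register_transformation
#' @export
list_transformations <- function() sort(ls(.transformations))

get_transformation <- function(name) {
  if (!exists(name, envir = .transformations, inherits = FALSE)) {
    stop(sprintf("unknown transformation '%s' (known: %s)", name,
                 paste(list_transformations(), collapse = ", ")))
  }
  get(name, envir = .transformations, inherits = FALSE)
}

## ---- transformation matrix -------------------------------------------------

#' Create a transformation matrix
#'
#' The transformation matrix is the pipeline container: experiments are
#' rows, successive transformation steps are columns, and each cell holds
#' at most one transformation instance.  Instances within one column must
#' touch pairwise-disjoint experiment sets and can therefore be executed
#' in any order; empty cells leave the data untouched.
#'
#' @param experiments list of `Experiment` objects (unique names).
#' @return a `TransformationMatrix`.
#' @export
transformation_matrix <- function(experiments = list()) {
  if (inherits(experiments, "Experiment")) experiments <- list(experiments)
  nms <- vapply(experiments, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("experiment names must be unique")
  names(experiments) <- nms
  structure(list(experiments = experiments, instances = list()),
            class = "TransformationMatrix")
}

n_columns <- function(tm) {
  if (length(tm$instances) == 0) return(0L)
  max(vapply(tm$instances, `[[`, integer(1), "column"))
}

#' @export
print.TransformationMatrix <- function(x, ...) {
  cat(sprintf("TransformationMatrix: %d experiment(s) x %d column(s), %d instance(s)\n",
              length(x$experiments), n_columns(x), length(x$instances)))
  for (ins in x$instances) {
    cat(sprintf("  col %d: %s (%s)\n", ins$column, ins$name,
                paste(ins$experiments, collapse = ", ")))
  }
  invisible(x)
}

instance_at <- function(tm, exp_name, column) {
  for (ins in tm$instances) {
    if (ins$column == column && exp_name %in% ins$experiments) return(ins)
  }
  NULL
}

#' Add a transformation instance
#'
#' Validates and inserts one transformation instance at the given column.
#' Validation is purely state-based -- no values are computed: the target
#' cells must be empty, the transformation must accept every selected
#' experiment's predicted state at that column, and no downstream instance
#' may be invalidated by the new output states.  On violation the matrix
#' is left unchanged and an error describing the conflict is thrown.
#'
#' @param tm a `TransformationMatrix`.
#' @param column 1-based step index; `n_columns(tm) + 1` appends a column.
#' @param experiments character vector of experiment names.
#' @param name registered transformation name.
#' @param params named list of parameters.
#' @return the updated matrix.
#' @export
add_instance <- function(tm, column, experiments, name, params = list()) {
  spec <- get_transformation(name)
  params <- prepare_instance_params(utils::modifyList(spec$params_default,
                                                      params))
  if (column < 1 || column > n_columns(tm) + 1) {
    stop(sprintf("column %d out of range (current columns: %d)", column,
                 n_columns(tm)))
  }
  missing <- setdiff(experiments, names(tm$experiments))
  if (length(missing) > 0) {
    stop("unknown experiment(s): ", paste(missing, collapse = ", "))
  }
  if (length(experiments) == 0) stop("an instance needs at least one experiment")
  if (spec$arity == "group" && length(experiments) < 2) {
    stop(sprintf("transformation '%s' works on a group and needs >= 2 experiments",
                 name))
  }
  for (e in experiments) {
    if (!is.null(instance_at(tm, e, column))) {
      stop(sprintf("cell (%s, column %d) is already occupied by '%s'",
                   e, column, instance_at(tm, e, column)$name))
    }
  }
  cand <- tm
  cand$instances <- c(cand$instances,
                      list(list(column = as.integer(column), name = name,
                                params = params, experiments = experiments)))
  problems <- validate_matrix(cand)
  if (length(problems) > 0) {
    stop("rejected: ", paste(problems, collapse = "; "))
  }
  cand
}

## Checks every occupied cell's accepts() against the predicted input
## state; returns a character vector of diagnostics (empty = valid).
validate_matrix <- function(tm) {
  problems <- character()
  m <- n_columns(tm)
  states <- lapply(tm$experiments, `[[`, "state")
  for (j in seq_len(m)) {
    for (ins in tm$instances) {
      if (ins$column != j) next
      spec <- get_transformation(ins$name)
      for (e in ins$experiments) {
        ok <- spec$accepts(states[[e]], ins$params, tm$experiments[[e]])
        if (!isTRUE(ok)) {
          problems <- c(problems,
                        sprintf("'%s' at column %d cannot accept experiment '%s' (%s): %s",
                                ins$name, j, e, format(states[[e]]),
                                as.character(ok)))
        }
      }
      if (spec$arity %in% c("group", "either") &&
          length(ins$experiments) > 1) {
        scales <- unique(vapply(ins$experiments,
                                function(e) states[[e]]$scale, character(1)))
        if (length(scales) > 1) {
          problems <- c(problems,
                        sprintf("'%s' at column %d mixes scales (%s) across its group",
                                ins$name, j, paste(scales, collapse = ", ")))
        }
      }
    }
    for (e in names(states)) {
      ins <- instance_at(tm, e, j)
      if (!is.null(ins)) {
        spec <- get_transformation(ins$name)
        states[[e]] <- spec$produces(states[[e]], ins$params)
      }
    }
  }
  problems
}

#' Predict the state matrix
#'
#' Pure state propagation: cell `(e, j+1)` is `produces(state(e, j))` of
#' the instance occupying `(e, j)`, or `state(e, j)` for an empty cell.
#' Column 1 holds the post-parse states.  No data values are touched.
#'
#' @param tm a `TransformationMatrix`.
#' @return a `StateMatrix`: named list (one entry per experiment) of lists
#'   of `DataState`, each of length `n_columns(tm) + 1`.
#' @export
predict_states <- function(tm) {
  m <- n_columns(tm)
  out <- lapply(tm$experiments, function(exp) {
    states <- vector("list", m + 1L)
    states[[1]] <- exp$state
    states
  })
  for (j in seq_len(m)) {
    for (e in names(out)) {
      ins <- instance_at(tm, e, j)
      st <- out[[e]][[j]]
      out[[e]][[j + 1L]] <- if (is.null(ins)) st else {
        get_transformation(ins$name)$produces(st, ins$params)
      }
    }
  }
  structure(out, class = "StateMatrix", m = m)
}

#' @export
print.StateMatrix <- function(x, ...) {
  m <- attr(x, "m")
  for (e in names(x)) {
    cat(sprintf("%-14s %s\n", e,
                paste(vapply(x[[e]], format, character(1)),
                      collapse = " -> ")))
  }
  invisible(x)
}

#' Execute a transformation matrix
#'
#' Processes the matrix column by column; instances within a column touch
#' disjoint experiment sets, so their order does not affect the result.
#' After each instance the engine sets the experiment's state to the
#' transformation's declared output state and verifies that the actual
#' data matches it (row count, channel count), so prediction and execution
#' cannot silently diverge.  Finally all experiments are assembled into
#' one features x experiments matrix.
#'
#' @param tm a valid `TransformationMatrix`.
#' @param assembly `"union"` (all feature ids, missing values `NA`) or
#'   `"intersection"` (shared feature ids only).
#' @return a `SeasightDataset`: list with `values` (numeric matrix),
#'   `loci` (per-feature locus annotation data.frame or `NULL`), `states`
#'   (final `DataState` per experiment).
#' @export
execute <- function(tm, assembly = c("union", "intersection")) {
  assembly <- match.arg(assembly)
  problems <- validate_matrix(tm)
  if (length(problems) > 0) {
    stop("invalid transformation matrix: ", paste(problems, collapse = "; "))
  }
  exps <- tm$experiments
  m <- n_columns(tm)
  for (j in seq_len(m)) {
    for (ins in tm$instances) {
      if (ins$column != j) next
      spec <- get_transformation(ins$name)
      sub <- exps[ins$experiments]
      new_states <- lapply(sub, function(x) spec$produces(x$state, ins$params))
      res <- tryCatch(spec$apply(sub, ins$params), error = function(e) {
        stop(sprintf("runtime failure in '%s' at column %d: %s", ins$name, j,
                     conditionMessage(e)), call. = FALSE)
      })
      for (k in seq_along(res)) {
        res[[k]]$state <- new_states[[k]]
        obs <- observed_row_count(res[[k]])
        if (!is.na(res[[k]]$state$row_count) && !is.na(obs) &&
            obs != res[[k]]$state$row_count) {
          stop(sprintf("state mismatch after '%s' at column %d: experiment '%s' has %d rows, predicted %d",
                       ins$name, j, res[[k]]$name, obs,
                       res[[k]]$state$row_count))
        }
        if (res[[k]]$state$entity != "read" &&
            length(res[[k]]$data$channels) != res[[k]]$state$channels) {
          stop(sprintf("state mismatch after '%s' at column %d: experiment '%s' has %d channel(s), predicted %d",
                       ins$name, j, res[[k]]$name,
                       length(res[[k]]$data$channels),
                       res[[k]]$state$channels))
        }
      }
      exps[ins$experiments] <- res
    }
  }
  assemble_dataset(exps, assembly)
}

assemble_dataset <- function(exps, assembly) {
  finals <- lapply(exps, `[[`, "state")
  summarized <- c("probeset", "locus", "identifier")
  entities <- unique(vapply(finals, `[[`, character(1), "entity"))
  scales <- unique(vapply(finals, `[[`, character(1), "scale"))
  channels <- unique(vapply(finals, `[[`, integer(1), "channels"))
  compatible <- length(scales) == 1 && length(channels) == 1 &&
    channels == 1L && (length(entities) == 1 || all(entities %in% summarized))
  if (!compatible) {
    desc <- vapply(names(exps), function(e) {
      sprintf("%s: %s", e, format(finals[[e]]))
    }, character(1))
    stop("assembly incompatibility; final states diverge:\n  ",
         paste(desc, collapse = "\n  "))
  }
  vecs <- lapply(exps, function(x) {
    if (length(x$data$channels) == 0) {
      stop(sprintf("experiment '%s' holds no value vector (was it quantified?)",
                   x$name))
    }
    x$data$channels[[1]]
  })
  feat_sets <- lapply(vecs, names)
  features <- if (assembly == "union") {
    Reduce(union, feat_sets)
  } else {
    Reduce(intersect, feat_sets)
  }
  features <- sort(features)
  mat <- vapply(vecs, function(v) unname(v[features]), numeric(length(features)))
  mat <- matrix(mat, nrow = length(features),
                dimnames = list(features, names(exps)))
  loci <- NULL
  for (x in exps) {
    if (!is.null(x$data$loci)) {
      l <- ensure_locus_ids(x$data$loci)
      l <- l[l$id %in% features, , drop = FALSE]
      if (is.null(loci)) loci <- as.data.frame(l)
      else loci <- rbind(loci, as.data.frame(l[!l$id %in% loci$id, ,
                                               drop = FALSE]))
    }
  }
  structure(list(values = mat, loci = loci, states = finals),
            class = "SeasightDataset")
}

#' @export
print.SeasightDataset <- function(x, ...) {
  cat(sprintf("SeasightDataset: %d features x %d experiments (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Write the assembled dataset as TSV
#'
#' Columns: `feature_id`, optional `chrom`/`start`/`end`/`strand` when
#' locus annotation is attached, then one column per experiment; missing
#' values are written as `NA`.
#'
#' @param x a `SeasightDataset`.
#' @param path output path.
#' @export
write_dataset <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$values), stringsAsFactors = FALSE)
  if (!is.null(x$loci)) {
    idx <- match(df$feature_id, x$loci$id)
    df$chrom <- x$loci$chrom[idx]
    df$start <- x$loci$start[idx]
    df$end <- x$loci$end[idx]
    df$strand <- x$loci$strand[idx]
  }
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
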