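## Pipeline configuration persistence.  A configuration is a structured
## JSON document declaring experiments (by source file + checksum, or
## inline for in-memory data) and transformation instances (column,
## transformation name, parameters, experiment names).  Bulk data is
## persisted by reference; `embed_data = TRUE` switches to an archive mode
## that inlines all parsed values.

CONFIG_FORMAT <- "seasight-config"
CONFIG_VERSION <- 1L

serialize_param <- function(v) {
  if (inherits(v, "LocusSet")) {
    list(`_type` = "LocusSet",
         records = lapply(as.data.frame(v), function(col) unname(col)))
  } else if (inherits(v, "ProbesetMap")) {
    list(`_type` = "ProbesetMap", probes = names(v),
         features = unname(as.character(unclass(v))))
  } else v
}

deserialize_param <- function(v, base_dir) {
  if (is.list(v) && !is.null(v$`_type`)) {
    switch(v$`_type`,
           LocusSet = {
             r <- v$records
             locus_set(species = unlist(r$species), chrom = unlist(r$chrom),
                       start = unlist(r$start), end = unlist(r$end),
                       strand = unlist(r$strand), id = unlist(r$id))
           },
           ProbesetMap = probeset_map(unlist(v$probes), unlist(v$features)),
           stop("unknown serialized parameter type '", v$`_type`, "'"))
  } else if (is.list(v)) {
    lapply(v, deserialize_param, base_dir = base_dir)
  } else v
}

serialize_instance_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    if (nm == "loci" && !is.null(params$loci_source)) next
    if (nm == "map" && !is.null(params$map_source)) next
    out[[nm]] <- serialize_param(params[[nm]])
  }
  out
}

serialize_experiment <- function(exp, embed_data, base_dir) {
  doc <- list(name = exp$name,
              kind = if (exp$state$entity == "read") "reads" else "array")
  if (!embed_data && !is.null(exp$provenance)) {
    doc$source <- exp$provenance
  } else {
    doc$source <- list(type = "inline")
    if (doc$kind == "reads") {
      df <- exp$data$reads$reads
      doc$source$reads <- as.list(df)
      doc$source$total_mapped <- exp$data$reads$total_mapped
      doc$source$species <- exp$data$reads$species
    } else {
      doc$source$channels <- lapply(exp$data$channels, function(v) {
        list(features = names(v), values = unname(v))
      })
      if (!is.null(exp$data$bg)) {
        doc$source$bg <- lapply(exp$data$bg, function(v) {
          list(features = names(v), values = unname(v))
        })
      }
      if (!is.null(exp$data$block)) doc$source$block <- exp$data$block
    }
  }
  doc
}

#' Save and load pipeline configurations
#'
#' `save_config` writes the transformation matrix (experiments with their
#' data sources and checksums, plus all transformation instances) as a
#' JSON document; `load_config` re-parses the sources, re-validates every
#' instance, and returns an equivalent matrix whose execution reproduces
#' the original output bit for bit.  A missing source file or a checksum
#' mismatch is an error at load time, as is an unknown transformation
#' name or an unsupported config version.
#'
#' @param tm a `TransformationMatrix`.
#' @param path config file path.
#' @param embed_data inline all parsed experiment data instead of
#'   referencing source files (archive mode).
#' @return `save_config`: `path`, invisibly; `load_config`: a
#'   `TransformationMatrix`.
#' @export
save_config <- function(tm, path, embed_data = FALSE) {
  base_dir <- dirname(path)
  doc <- list(
    format = CONFIG_FORMAT,
    version = CONFIG_VERSION,
    experiments = lapply(unname(tm$experiments), serialize_experiment,
                         embed_data = embed_data, base_dir = base_dir),
    instances = lapply(tm$instances, function(ins) {
      list(column = ins$column, name = ins$name,
           experiments = as.list(ins$experiments),
           params = serialize_instance_params(ins$params))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

resolve_source_path <- function(p, base_dir) {
  if (file.exists(p)) return(p)
  alt <- file.path(base_dir, p)
  if (file.exists(alt)) return(alt)
  stop(sprintf("dangling source-file reference: '%s' does not exist", p))
}

load_experiment <- function(doc, base_dir) {
  src <- doc$source
  if (src$type == "inline") {
    if (doc$kind == "reads") {
      df <- data.frame(chrom = unlist(src$reads$chrom),
                       start = unlist(src$reads$start),
                       end = unlist(src$reads$end),
                       strand = unlist(src$reads$strand),
                       stringsAsFactors = FALSE)
      rc <- read_collection(df, total_mapped = src$total_mapped,
                            species = src$species)
      return(experiment_from_reads(doc$name, rc))
    }
    channels <- lapply(src$channels, function(ch) {
      stats::setNames(unlist(ch$values), unlist(ch$features))
    })
    fg <- do.call(cbind, channels)
    bg <- if (!is.null(src$bg)) {
      do.call(cbind, lapply(src$bg, function(ch) unlist(ch$values)))
    } else NULL
    pt <- probe_table(names(channels[[1]]), fg, bg,
                      block = if (!is.null(src$block)) unlist(src$block))
    return(experiment_from_array(doc$name, pt))
  }
  p <- resolve_source_path(src$path, base_dir)
  actual <- unname(tools::md5sum(p))
  if (!is.null(src$checksum) && !identical(actual, src$checksum)) {
    stop(sprintf("checksum mismatch for source file '%s' (expected %s, found %s)",
                 p, src$checksum, actual))
  }
  if (src$type == "reads_file") {
    experiment_from_reads_file(doc$name, p, format = src$format,
                               column_map = src$column_map,
                               defaults = src$defaults,
                               dialect = src$dialect,
                               coordinates = if (is.null(src$coordinates))
                                 "0-based" else src$coordinates)
  } else if (src$type == "array_file") {
    experiment_from_array_file(doc$name, p, column_map = src$column_map,
                               dialect = src$dialect)
  } else {
    stop("unknown experiment source type '", src$type, "'")
  }
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, CONFIG_FORMAT)) {
    stop("not a seasight pipeline configuration: ", path)
  }
  if (!identical(as.integer(doc$version), CONFIG_VERSION)) {
    stop(sprintf("config version mismatch: file has version %s, this build supports %d",
                 doc$version, CONFIG_VERSION))
  }
  base_dir <- dirname(path)
  exps <- lapply(doc$experiments, load_experiment, base_dir = base_dir)
  tm <- transformation_matrix(exps)
  instances <- doc$instances
  cols <- vapply(instances, function(i) as.integer(i$column), integer(1))
  for (k in order(cols)) {
    ins <- instances[[k]]
    get_transformation(ins$name)  # unknown name -> error naming it
    params <- deserialize_param(ins$params, base_dir)
    # re-resolve file-path params relative to the config location
    if (!is.null(params$loci_source)) {
      params$loci <- resolve_source_path(params$loci_source, base_dir)
      params$loci_source <- NULL
    }
    if (!is.null(params$map_source)) {
      params$map <- resolve_source_path(params$map_source, base_dir)
      params$map_source <- NULL
    }
    tm <- add_instance(tm, as.integer(ins$column),
                       unlist(ins$experiments), ins$name, params)
  }
  tm
}
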