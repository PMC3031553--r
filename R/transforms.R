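## The built-in transformation catalog: wires the normalization and
## quantification functions into the state-typed engine.  Each entry
## declares the input states it accepts and the state it produces, so the
## engine can validate pipelines without computing values.

## Resolve file-path parameters (loci, probeset/identifier maps) into
## objects once, keeping the original path for config persistence.
prepare_instance_params <- function(params) {
  if (!is.null(params$loci) && is.character(params$loci)) {
    params$loci_source <- params$loci
    params$loci <- parse_loci(params$loci, format = "gff")
  }
  if (!is.null(params$map) && is.character(params$map) &&
      length(params$map) == 1 && is.null(names(params$map))) {
    params$map_source <- params$map
    params$map <- parse_probeset_map(params$map)
  }
  if (!is.null(params$map) && is.character(params$map) &&
      !is.null(names(params$map)) && !inherits(params$map, "ProbesetMap")) {
    params$map <- probeset_map(names(params$map), unname(params$map))
  }
  params
}

accept_if <- function(cond, msg) if (cond) TRUE else msg

exp_matrix_from_group <- function(exps) {
  vecs <- lapply(exps, function(x) x$data$channels[[1]])
  check_same_features(vecs)
  nms <- names(vecs[[1]])
  mat <- vapply(vecs, function(v) if (is.null(nms)) v else v[nms],
                numeric(length(vecs[[1]])))
  matrix(mat, ncol = length(vecs),
         dimnames = list(nms, vapply(exps, `[[`, character(1), "name")))
}

map_targets <- function(map) sort(unique(as.character(unclass(map))))

register_builtin_transformations <- function() {

  register_transformation("bg_subtract", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "probe") return("needs probe-level data")
      if (state$scale != "linear") return("needs linear-scale data")
      if (state$bg_corrected) {
        return("data is already background-corrected; further background correction is neither possible nor useful")
      }
      if (!is.null(exp) && is.null(exp$data$bg)) {
        return("no background intensities were imported for this experiment")
      }
      TRUE
    },
    produces = function(state, params) state_update(state, bg_corrected = TRUE),
    apply = function(exps, params) {
      lapply(exps, function(x) {
        if (is.null(x$data$bg)) stop("no background intensities present")
        x$data$channels <- mapply(function(fg, bg) {
          bg_subtract(fg, bg, floor = params$floor)
        }, x$data$channels, x$data$bg, SIMPLIFY = FALSE)
        x
      })
    },
    params_default = list(floor = 0.5))

  register_transformation("normexp", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$scale != "linear") return("needs linear-scale data")
      if (state$measure != "intensity") return("needs raw intensities")
      if (state$bg_corrected) {
        return("data is already background-corrected; further background correction is neither possible nor useful")
      }
      TRUE
    },
    produces = function(state, params) state_update(state, bg_corrected = TRUE),
    apply = function(exps, params) {
      lapply(exps, function(x) {
        x$data$channels <- lapply(x$data$channels, function(v) {
          stats::setNames(normexp_correct(v, normexp_fit(v)), names(v))
        })
        x
      })
    })

  register_transformation("quantile", "group",
    accepts = function(state, params, exp = NULL) {
      accept_if(state$channels == 1L, "needs single-channel data")
    },
    produces = function(state, params) state_update(state, normalized = TRUE),
    apply = function(exps, params) {
      mat <- exp_matrix_from_group(exps)
      norm <- quantile_normalize(mat)
      for (k in seq_along(exps)) {
        old <- exps[[k]]$data$channels[[1]]
        exps[[k]]$data$channels[[1]] <-
          stats::setNames(norm[names(old), k], names(old))
      }
      exps
    })

  register_transformation("reference_quantile", "group",
    accepts = function(state, params, exp = NULL) {
      accept_if(state$channels == 1L, "needs single-channel data")
    },
    produces = function(state, params) state_update(state, normalized = TRUE),
    apply = function(exps, params) {
      ref_name <- params$reference
      nms <- vapply(exps, `[[`, character(1), "name")
      if (is.null(ref_name) || !ref_name %in% nms) {
        stop("reference_quantile needs params$reference naming a group member")
      }
      mat <- exp_matrix_from_group(exps)
      ref <- mat[, which(nms == ref_name)]
      norm <- quantile_normalize(mat, reference = ref)
      for (k in seq_along(exps)) {
        old <- exps[[k]]$data$channels[[1]]
        exps[[k]]$data$channels[[1]] <-
          stats::setNames(norm[names(old), k], names(old))
      }
      exps
    })

  for (mode in c("average", "percentile")) {
    local({
      mode_ <- mode
      register_transformation(paste0("scale_", mode_), "group",
        accepts = function(state, params, exp = NULL) {
          if (state$channels != 1L) return("needs single-channel data")
          accept_if(state$scale == "linear", "needs linear-scale data")
        },
        produces = function(state, params) state_update(state, normalized = TRUE),
        apply = function(exps, params) {
          vecs <- lapply(exps, function(x) x$data$channels[[1]])
          scaled <- scale_normalize(vecs, mode = mode_,
                                    p = if (is.null(params$p)) 75 else params$p)
          for (k in seq_along(exps)) exps[[k]]$data$channels[[1]] <- scaled[[k]]
          exps
        },
        params_default = list(p = 75))
    })
  }

  loess_like <- function(use_printtip) {
    function(exps, params) {
      lapply(exps, function(x) {
        tips <- if (use_printtip) x$data$block else NULL
        res <- loess_ma(x$data$channels[[1]], x$data$channels[[2]],
                        span = params$span, printtip = tips)
        x$data$channels <- list(M = res$M, A = res$A)
        x
      })
    }
  }
  loess_accepts <- function(state, params, exp = NULL) {
    if (state$channels != 2L) return("needs two-channel data")
    if (state$scale != "linear") return("needs linear-scale intensities")
    accept_if(state$measure == "intensity", "needs raw intensities")
  }
  loess_produces <- function(state, params) {
    state_update(state, scale = "log", measure = "ratio", normalized = TRUE)
  }
  register_transformation("loess", "per_experiment", loess_accepts,
                          loess_produces, loess_like(FALSE),
                          params_default = list(span = 0.3))
  register_transformation("printtip_loess", "per_experiment", loess_accepts,
                          loess_produces, loess_like(TRUE),
                          params_default = list(span = 0.3))

  register_transformation("ma_transform", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$channels != 2L) return("needs two-channel data")
      if (state$scale != "linear") return("needs linear-scale intensities")
      accept_if(state$measure == "intensity", "needs raw intensities")
    },
    produces = function(state, params) {
      state_update(state, scale = "log", measure = "ratio")
    },
    apply = function(exps, params) {
      lapply(exps, function(x) {
        res <- ma_transform(x$data$channels[[1]], x$data$channels[[2]])
        x$data$channels <- list(M = res$M, A = res$A)
        x
      })
    })

  register_transformation("dye_swap", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      accept_if(state$channels == 2L, "needs two-channel data")
    },
    produces = function(state, params) state,
    apply = function(exps, params) {
      lapply(exps, function(x) {
        if (x$state$measure == "ratio") {
          x$data$channels[[1]] <- -x$data$channels[[1]]  # M -> -M
        } else {
          x$data$channels <- dye_swap(x$data$channels)
          if (!is.null(x$data$bg)) x$data$bg <- dye_swap(x$data$bg)
        }
        x
      })
    })

  register_transformation("log2", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      accept_if(state$scale == "linear", "data is already on log scale")
    },
    produces = function(state, params) state_update(state, scale = "log"),
    apply = function(exps, params) {
      lapply(exps, function(x) {
        x$data$channels <- lapply(x$data$channels, log2_transform,
                                  c = params$c)
        x
      })
    },
    params_default = list(c = 1))

  register_transformation("summarize", "group",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "probe") return("needs probe-level data")
      if (state$channels != 1L) return("needs single-channel data")
      if (identical(params$method, "median_polish") && state$scale != "log") {
        return("median polish summarization expects log-scale data")
      }
      if (is.null(params$map)) return("needs a probe-to-feature map (params$map)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, entity = "probeset",
                   row_count = length(map_targets(params$map)),
                   loci_attached = FALSE)
    },
    apply = function(exps, params) {
      mat <- exp_matrix_from_group(exps)
      summ <- summarize_probes(mat, params$map, method = params$method)
      targets <- map_targets(params$map)
      full <- matrix(NA_real_, nrow = length(targets), ncol = ncol(summ),
                     dimnames = list(targets, colnames(summ)))
      full[rownames(summ), ] <- summ
      for (k in seq_along(exps)) {
        exps[[k]]$data$channels <- list(stats::setNames(full[, k], targets))
        exps[[k]]$data$loci <- NULL
      }
      exps
    },
    params_default = list(method = "median_polish"))

  register_transformation("count", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "read") return("needs mapped reads")
      if (is.null(params$loci)) return("needs a locus set (params$loci)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, entity = "locus", measure = "count",
                   scale = "linear", loci_attached = TRUE,
                   row_count = nrow(params$loci))
    },
    apply = function(exps, params) {
      lapply(exps, function(x) {
        le <- count_reads(x$data$reads, params$loci, rule = params$rule,
                          stranded = isTRUE(params$stranded))
        x$data$channels <- list(le$values)
        x$data$loci <- le$loci
        x
      })
    },
    params_default = list(rule = "overlap_any", stranded = FALSE))

  register_transformation("coverage", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "read") return("needs mapped reads")
      if (is.null(params$loci)) return("needs a locus set (params$loci)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, entity = "locus", measure = "coverage",
                   scale = "linear", loci_attached = TRUE,
                   row_count = nrow(params$loci))
    },
    apply = function(exps, params) {
      lapply(exps, function(x) {
        track <- build_coverage(x$data$reads)
        le <- coverage_value(track, params$loci, N = x$data$reads$total_mapped)
        x$data$channels <- list(le$values)
        x$data$loci <- le$loci
        x
      })
    })

  register_transformation("rpkm", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "locus" || state$measure != "count") {
        return("needs per-locus read counts (apply 'count' first)")
      }
      accept_if(state$scale == "linear", "needs linear-scale counts")
    },
    produces = function(state, params) {
      state_update(state, measure = "expression")
    },
    apply = function(exps, params) {
      lapply(exps, function(x) {
        counts <- x$data$channels[[1]]
        loci <- x$data$loci
        L <- stats::setNames(locus_lengths(loci), loci$id)[names(counts)]
        x$data$channels <- list(rpkm(counts, x$data$reads$total_mapped, L))
        x
      })
    })

  register_transformation("dcpm", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity != "read") return("needs mapped reads")
      if (is.null(params$loci)) return("needs a locus set (params$loci)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, entity = "locus", measure = "expression",
                   scale = "linear", loci_attached = TRUE,
                   row_count = nrow(params$loci))
    },
    apply = function(exps, params) {
      lapply(exps, function(x) {
        track <- build_coverage(x$data$reads)
        le <- dcpm(track, params$loci, N = x$data$reads$total_mapped)
        x$data$channels <- list(le$values)
        x$data$loci <- le$loci
        x
      })
    })

  register_transformation("interval_map_log", "either",
    accepts = function(state, params, exp = NULL) {
      if (state$channels != 1L) return("needs single-channel data")
      accept_if(state$scale == "linear",
                "interval mapping expects linear (unlogged) values")
    },
    produces = function(state, params) state_update(state, scale = "log"),
    apply = function(exps, params) {
      shared <- if (length(exps) > 1) {
        lx <- unlist(lapply(exps, function(x) log2(x$data$channels[[1]] + 1)))
        c(min(lx), max(lx))
      } else NULL
      lapply(exps, function(x) {
        x$data$channels <- list(interval_map_log(x$data$channels[[1]],
                                                 lo = params$lo,
                                                 hi = params$hi,
                                                 range = shared))
        x
      })
    },
    params_default = list(lo = 0, hi = 16))

  register_transformation("map_identifiers", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$channels != 1L) return("needs single-channel data")
      if (is.null(params$map)) return("needs an identifier map (params$map)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, entity = "identifier",
                   row_count = length(map_targets(params$map)),
                   loci_attached = FALSE)
    },
    apply = function(exps, params) {
      targets <- map_targets(params$map)
      lapply(exps, function(x) {
        v <- map_identifiers(x$data$channels[[1]], params$map)
        full <- stats::setNames(rep(NA_real_, length(targets)), targets)
        full[names(v)] <- v
        x$data$channels <- list(full)
        x$data$loci <- NULL
        x
      })
    })

  register_transformation("import_loci", "per_experiment",
    accepts = function(state, params, exp = NULL) {
      if (state$entity == "read") return("reads carry coordinates already; use 'count'/'coverage'/'dcpm'")
      if (is.null(params$loci)) return("needs a locus set (params$loci)")
      TRUE
    },
    produces = function(state, params) {
      state_update(state, loci_attached = TRUE)
    },
    apply = function(exps, params) {
      loci <- ensure_locus_ids(params$loci)
      lapply(exps, function(x) {
        x$data$loci <- loci[loci$id %in% names(x$data$channels[[1]]), ,
                            drop = FALSE]
        x
      })
    })

  invisible(TRUE)
}
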