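# The transformation-matrix engine: state-typed validation, prediction,
# execution, persistence.

test_that("add_instance validates states without computing values", {
  e <- tiny_array_experiment("a1", bg = TRUE)
  tm <- transformation_matrix(list(e))
  tm <- add_instance(tm, 1, "a1", "bg_subtract")
  # second background correction is rejected on state grounds
  expect_error(add_instance(tm, 2, "a1", "bg_subtract"),
               "already background-corrected")
  expect_error(add_instance(tm, 2, "a1", "normexp"),
               "already background-corrected")
  # occupied cell
  expect_error(add_instance(tm, 1, "a1", "log2"), "occupied")
  # unknown names are reported
  expect_error(add_instance(tm, 2, "a1", "frobnicate"),
               "unknown transformation 'frobnicate'")
  expect_error(add_instance(tm, 2, "nope", "log2"), "unknown experiment")
  expect_error(add_instance(tm, 9, "a1", "log2"), "out of range")
})

test_that("experiments lacking background cannot be background-subtracted", {
  e <- tiny_array_experiment("a1", bg = FALSE)
  tm <- transformation_matrix(list(e))
  expect_error(add_instance(tm, 1, "a1", "bg_subtract"),
               "no background intensities")
})

test_that("group transformations need at least two experiments", {
  tm <- transformation_matrix(list(tiny_array_experiment("a1"),
                                   tiny_array_experiment("a2", seed = 2)))
  expect_error(add_instance(tm, 1, "a1", "quantile"), ">= 2 experiments")
  tm <- add_instance(tm, 1, c("a1", "a2"), "quantile")
  expect_length(tm$instances, 1L)
})

test_that("inserting an instance that invalidates a downstream step is rejected", {
  tm <- transformation_matrix(list(tiny_array_experiment("a1"),
                                   tiny_array_experiment("a2", seed = 2)))
  tm <- add_instance(tm, 1, "a2", "log2")        # a1's column-1 cell empty
  tm <- add_instance(tm, 2, "a1", "log2")
  # a log2 at column 1 would flip the scale seen by the downstream log2
  err <- tryCatch(add_instance(tm, 1, "a1", "log2"), error = conditionMessage)
  expect_match(err, "'log2' at column 2")
  expect_match(err, "already on log scale")
  # the matrix is unchanged by the failed insertion
  expect_length(tm$instances, 2L)
})

test_that("predict_states is pure, local and consistent with initial states", {
  exps <- list(tiny_array_experiment("a1"), tiny_array_experiment("a2", seed = 2),
               tiny_array_experiment("a3", seed = 3))
  tm <- transformation_matrix(exps)
  st0 <- predict_states(tm)
  for (e in names(st0)) expect_length(st0[[e]], 1L)
  tm <- add_instance(tm, 1, "a1", "log2")
  st <- predict_states(tm)
  expect_equal(st[["a1"]][[2]]$scale, "log")
  expect_equal(st[["a2"]][[2]]$scale, "linear")   # untouched rows unchanged
  expect_equal(st[["a3"]][[2]]$scale, "linear")
  expect_equal(st[["a1"]][[1]]$scale, "linear")   # column 1 = post-parse
})

test_that("execute on an empty matrix aligns parsed values by feature id", {
  e1 <- tiny_array_experiment("a1")
  e2 <- tiny_array_experiment("a2", seed = 2)
  ds <- execute(transformation_matrix(list(e1, e2)))
  expect_equal(dim(ds$values), c(20L, 2L))
  expect_equal(ds$values[, "a1"],
               e1$data$channels[[1]][rownames(ds$values)])
})

test_that("union vs intersection assembly and missing-value marking", {
  p1 <- probe_table(c("x", "y"), matrix(c(1, 2), ncol = 1))
  p2 <- probe_table(c("y", "z"), matrix(c(5, 6), ncol = 1))
  tm <- transformation_matrix(list(experiment_from_array("e1", p1),
                                   experiment_from_array("e2", p2)))
  u <- execute(tm, assembly = "union")
  expect_equal(rownames(u$values), c("x", "y", "z"))
  expect_true(is.na(u$values["z", "e1"]) && is.na(u$values["x", "e2"]))
  i <- execute(tm, assembly = "intersection")
  expect_equal(rownames(i$values), "y")
})

test_that("assembly rejects experiments with divergent final states", {
  tm <- transformation_matrix(list(tiny_array_experiment("a1"),
                                   tiny_array_experiment("a2", seed = 2)))
  tm <- add_instance(tm, 1, "a1", "log2")
  expect_error(execute(tm), "assembly incompatibility")
})

test_that("within-column instance order does not affect the result", {
  tm <- golden_matrix()
  ds1 <- execute(tm)
  tm2 <- tm
  perm <- c(2, 1, 4, 3, 5, 6, 8, 7)
  tm2$instances <- tm2$instances[perm]
  ds2 <- execute(tm2)
  expect_identical(ds1$values, ds2$values)
})

test_that("predicted final states match the executed dataset", {
  tm <- golden_matrix()
  st <- predict_states(tm)
  ds <- execute(tm)
  m <- attr(st, "m")
  for (e in names(st)) {
    fin <- st[[e]][[m + 1]]
    expect_identical(fin, ds$states[[e]])
    expect_equal(fin$row_count, sum(!is.na(ds$values[, e])))
    expect_equal(fin$scale, "log")
    expect_true(fin$normalized)
  }
  expect_equal(nrow(ds$values), small_design()$genes)
})

test_that("config round-trip preserves the matrix and reproduces output", {
  # empty matrix
  tm0 <- transformation_matrix(list(tiny_array_experiment("a1")))
  f0 <- tempfile(fileext = ".json")
  save_config(tm0, f0, embed_data = TRUE)
  back0 <- load_config(f0)
  expect_equal(names(back0$experiments), "a1")
  expect_length(back0$instances, 0L)
  expect_equal(back0$experiments$a1$data$channels,
               tm0$experiments$a1$data$channels)
  # golden pipeline
  tm <- golden_matrix()
  f <- file.path(golden_bundle(), "config_roundtrip.json")
  save_config(tm, f)
  back <- load_config(f)
  expect_equal(length(back$instances), length(tm$instances))
  expect_equal(lapply(back$instances, `[[`, "name"),
               lapply(tm$instances, `[[`, "name"))
  expect_identical(execute(back)$values, execute(tm)$values)
})

test_that("config loading rejects tampered and unknown content", {
  tm <- golden_matrix()
  f <- tempfile(fileext = ".json")
  save_config(tm, f)
  doc <- jsonlite::read_json(f)
  doc$instances[[1]]$name <- "mystery_step"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, null = "null")
  expect_error(load_config(f2), "unknown transformation 'mystery_step'")
  doc$version <- 99
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, null = "null")
  expect_error(load_config(f2), "version mismatch")
  # dangling source reference
  doc2 <- jsonlite::read_json(f)
  doc2$experiments[[1]]$source$path <- "does-not-exist.tsv"
  jsonlite::write_json(doc2, f2, auto_unbox = TRUE, null = "null")
  expect_error(load_config(f2), "dangling source-file reference")
  # checksum mismatch
  doc3 <- jsonlite::read_json(f)
  doc3$experiments[[1]]$source$checksum <- "0000"
  jsonlite::write_json(doc3, f2, auto_unbox = TRUE, null = "null")
  expect_error(load_config(f2), "checksum mismatch")
})

test_that("custom transformations can be registered and used", {
  register_transformation("test_double", "per_experiment",
    accepts = function(state, params, exp = NULL) TRUE,
    produces = function(state, params) state,
    apply = function(exps, params) {
      lapply(exps, function(x) {
        x$data$channels <- lapply(x$data$channels, `*`, 2)
        x
      })
    })
  expect_true("test_double" %in% list_transformations())
  tm <- transformation_matrix(list(tiny_array_experiment("a1")))
  tm <- add_instance(tm, 1, "a1", "test_double")
  ds <- execute(tm)
  e <- tiny_array_experiment("a1")
  expect_equal(ds$values[, "a1"],
               2 * e$data$channels[[1]][rownames(ds$values)])
})
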