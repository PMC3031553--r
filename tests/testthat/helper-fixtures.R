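# Shared fixtures, generated in code.  The scaled-down study keeps the
# default-design structure (2 conditions x 2 platforms x 2 replicates,
# 10% DE at fold change 4) at a size that keeps the suite fast; the
# spec-level default design is exercised in test-acceptance.R.

small_design <- function(seed = 11L) {
  study_design(genes = 60L, depth = 2e4, probes_per_gene = 5L,
               genome_length = 5e5, seed = seed)
}

# One golden bundle per R session, cached on first use.
.fixture_cache <- new.env(parent = emptyenv())

golden_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "seasight-golden")
    synth_study(small_design(), dir)
    .fixture_cache$bundle <- dir
  }
  .fixture_cache$bundle
}

golden_matrix <- function() load_config(file.path(golden_bundle(), "config.json"))

# The spec-level default study (G = 200, 2 x 2 x 2, 10% DE at fold change
# 4, 1e5 reads/lane), cached once per session for the acceptance criteria.
default_bundle <- function() {
  if (is.null(.fixture_cache$default_bundle)) {
    dir <- file.path(tempdir(), "seasight-default")
    synth_study(study_design(seed = 1L), dir)
    .fixture_cache$default_bundle <- dir
  }
  .fixture_cache$default_bundle
}

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

read_collection_from_df <- function(df) seasight:::read_collection(df)

coverage_window_vec <- function(track, chrom, start, end) {
  seasight:::coverage_window(track, chrom, start, end)
}

# A tiny in-memory array experiment with optional background.
tiny_array_experiment <- function(name = "a1", n = 20, channels = 1,
                                  bg = FALSE, seed = 1) {
  set.seed(seed)
  probes <- sprintf("p%03d", seq_len(n))
  fg <- matrix(stats::runif(n * channels, 50, 1000), ncol = channels)
  bgm <- if (bg) matrix(stats::runif(n * channels, 10, 40),
                        ncol = channels) else NULL
  experiment_from_array(name, probe_table(probes, fg, bgm))
}
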