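# Read counting, coverage values, RPKM/DCPM, locus derivation.

test_that("counting rules behave as specified on the boundary cases", {
  rc <- read_collection_from_df(data.frame(chrom = "c", start = 10L,
                                           end = 20L, strand = "+"))
  loci <- locus_set(chrom = "c", start = 0, end = 15, id = "L1")
  expect_equal(unname(count_reads(rc, loci, rule = "overlap_any")$values), 1)
  expect_equal(unname(count_reads(rc, loci, rule = "contained")$values), 0)
  expect_equal(unname(count_reads(rc, loci, rule = "start_in")$values), 1)
  # start_in: start exactly at locus end is outside
  at_end <- read_collection_from_df(data.frame(chrom = "c", start = 15L,
                                               end = 30L, strand = "+"))
  expect_equal(unname(count_reads(at_end, loci, rule = "start_in")$values), 0)
  un <- read_collection_from_df(data.frame(chrom = "c", start = 1L,
                                           end = 5L, strand = "*"))
  expect_error(count_reads(un, loci, stranded = TRUE), "unstranded")
})

test_that("count_reads equals the brute-force double loop for all rules", {
  set.seed(9)
  n <- 1e4
  start <- sample(0:9000, n, replace = TRUE)
  df <- data.frame(chrom = "c", start = start,
                   end = start + sample(20:50, n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE))
  rc <- read_collection_from_df(df)
  ls <- sort(sample(0:9000, 200))
  loci <- locus_set(chrom = "c", start = ls[seq(1, 200, 2)],
                    end = ls[seq(1, 200, 2)] + sample(30:400, 100, TRUE),
                    strand = sample(c("+", "-", "*"), 100, TRUE),
                    id = sprintf("L%03d", 1:100))
  for (rule in c("overlap_any", "start_in", "contained")) {
    for (stranded in c(FALSE, TRUE)) {
      got <- count_reads(rc, loci, rule = rule, stranded = stranded)$values
      want <- vapply(seq_len(nrow(loci)), function(i) {
        hit <- switch(rule,
          overlap_any = df$start < loci$end[i] & df$end > loci$start[i],
          start_in = df$start >= loci$start[i] & df$start < loci$end[i],
          contained = df$start >= loci$start[i] & df$end <= loci$end[i])
        if (stranded && loci$strand[i] != "*") {
          hit <- hit & df$strand == loci$strand[i]
        }
        sum(hit)
      }, numeric(1))
      expect_equal(unname(got), want, info = paste(rule, stranded))
    }
  }
})

test_that("coverage_value is mean per-base depth", {
  df <- data.frame(chrom = "c", start = rep(0L, 3), end = rep(100L, 3),
                   strand = "+")
  tr <- build_coverage(read_collection_from_df(df))
  loci <- locus_set(chrom = "c", start = 0, end = 100, id = "L")
  expect_equal(unname(coverage_value(tr, loci)$values), 3)
  # depth 2 over half the locus, 0 over the rest -> mean 1
  df2 <- data.frame(chrom = "c", start = c(0L, 0L), end = c(50L, 50L),
                    strand = "+")
  tr2 <- build_coverage(read_collection_from_df(df2))
  expect_equal(unname(coverage_value(tr2, loci)$values), 1)
  # random track vs position-wise brute force
  set.seed(10)
  start <- sample(0:2000, 500, TRUE)
  df3 <- data.frame(chrom = "c", start = start, end = start + 30L,
                    strand = "+")
  tr3 <- build_coverage(read_collection_from_df(df3))
  depth <- oracle_coverage(df3, 2100)
  loci3 <- locus_set(chrom = "c", start = c(0, 500, 1990),
                     end = c(100, 1500, 2090), id = c("a", "b", "d"))
  want <- vapply(seq_len(3), function(i) {
    mean(depth[(loci3$start[i] + 1):loci3$end[i]])
  }, numeric(1))
  expect_equal(unname(coverage_value(tr3, loci3)$values), want)
})

test_that("rpkm implements 1e9 * count / (N * L) with its scaling laws", {
  expect_equal(rpkm(100, 1e6, 1000), 100)
  expect_equal(rpkm(0, 1e6, 1000), 0)
  set.seed(11)
  for (i in 1:20) {
    cnt <- sample(1:1000, 1); N <- sample(1e5:1e7, 1); L <- sample(100:1e4, 1)
    expect_equal(rpkm(2 * cnt, N, L), 2 * rpkm(cnt, N, L))
    expect_equal(rpkm(cnt, 2 * N, L), rpkm(cnt, N, L) / 2)
    expect_equal(rpkm(cnt, N, 2 * L), rpkm(cnt, N, L) / 2)
  }
  expect_error(rpkm(1, 0, 100), "domain error")
  expect_error(rpkm(1, 100, 0), "domain error")
})

test_that("rpkm recovers relative abundances exactly from known counts", {
  # ratio of RPKM values equals ratio of count/length at fixed N
  counts <- c(g1 = 300, g2 = 120, g3 = 77)
  lens <- c(g1 = 1500, g2 = 800, g3 = 2100)
  v <- rpkm(counts, 1e6, lens)
  expect_equal(v["g1"] / v["g2"],
               (counts["g1"] / lens["g1"]) / (counts["g2"] / lens["g2"]))
  expect_equal(v["g3"] / v["g1"],
               (counts["g3"] / lens["g3"]) / (counts["g1"] / lens["g1"]))
})

test_that("dcpm is depth per base per million reads, scale-invariant", {
  df <- data.frame(chrom = "c", start = rep(0L, 5), end = rep(100L, 5),
                   strand = "+")
  tr <- build_coverage(read_collection_from_df(df))
  loci <- locus_set(chrom = "c", start = 0, end = 100, id = "L")
  expect_equal(unname(dcpm(tr, loci, N = 1e6)$values), 5)
  # scaling depth and N together leaves DCPM unchanged
  df2 <- df[rep(1, 10), ]
  tr2 <- build_coverage(read_collection_from_df(df2))
  expect_equal(unname(dcpm(tr2, loci, N = 2e6)$values),
               unname(dcpm(tr, loci, N = 1e6)$values))
  expect_equal(unname(dcpm(tr, locus_set(chrom = "zzz", start = 0, end = 10,
                                         id = "x"), N = 1e6)$values), 0)
  expect_error(dcpm(tr, loci, N = 0), "domain error")
})

test_that("derive_loci finds thresholded runs with gap closing", {
  df <- data.frame(chrom = "c", start = rep(100L, 2), end = rep(200L, 2),
                   strand = "+")
  tr <- build_coverage(read_collection_from_df(df))
  out <- derive_loci(tr, min_depth = 2)
  expect_equal(c(out$start, out$end), c(100, 200))
  # two runs separated by a 3-base gap merge when max_gap >= 3
  df2 <- data.frame(chrom = "c", start = c(10L, 23L), end = c(20L, 40L),
                    strand = "+")
  tr2 <- build_coverage(read_collection_from_df(df2))
  expect_equal(nrow(derive_loci(tr2, min_depth = 1, max_gap = 0)), 2L)
  merged <- derive_loci(tr2, min_depth = 1, max_gap = 5)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(10, 40))
  # flat zero track
  empty <- build_coverage(read_collection_from_df(
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())))
  expect_equal(nrow(derive_loci(empty, min_depth = 1)), 0L)
  # derived loci re-find at least min_depth * 1 reads each
  set.seed(12)
  start <- sample(0:3000, 800, TRUE)
  df3 <- data.frame(chrom = "c", start = start, end = start + 40L,
                    strand = "+")
  rc3 <- read_collection_from_df(df3)
  d3 <- derive_loci(build_coverage(rc3), min_depth = 3, min_length = 50)
  cnt <- count_reads(rc3, d3, rule = "overlap_any")
  expect_true(all(cnt$values >= 3))
})
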