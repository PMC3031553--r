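# Background correction, normalization, summarization and value
# transforms.

test_that("bg_subtract floors negative differences", {
  expect_equal(bg_subtract(100, 40), 60)
  expect_equal(bg_subtract(10, 50), 0.5)
  expect_equal(bg_subtract(10, 50, floor = 2), 2)
  x <- c(a = 5, b = 10)
  expect_equal(bg_subtract(x, c(a = 0, b = 0)), x)
  expect_error(bg_subtract(c(a = 1), c(b = 1)), "feature sets differ")
})

test_that("normexp_fit is consistent and scale-equivariant", {
  set.seed(21)
  x <- rexp(1e5, 1 / 100) + rnorm(1e5, 50, 10)
  p <- normexp_fit(x)
  expect_lt(abs(p$alpha - 100) / 100, 0.05)
  expect_lt(abs(p$mu - 50) / 50, 0.05)
  expect_lt(abs(p$sigma - 10) / 10, 0.05)
  # scaling all inputs by c scales every parameter by c
  p2 <- normexp_fit(3 * x)
  expect_equal(p2$alpha / p$alpha, 3, tolerance = 0.02)
  expect_equal(p2$mu / p$mu, 3, tolerance = 0.02)
  expect_equal(p2$sigma / p$sigma, 3, tolerance = 0.05)
  expect_error(normexp_fit(rep(5, 500)), "degenerate")
  # background-only input: alpha flagged as near zero relative to sigma
  set.seed(22)
  expect_warning(p0 <- normexp_fit(rnorm(5000, 100, 5)), "near zero")
  expect_lt(p0$alpha, p0$sigma)
})

test_that("normexp_correct matches the quadrature conditional expectation", {
  params <- structure(list(alpha = 100, mu = 50, sigma = 10),
                      class = "NormexpParams")
  xs <- seq(20, 400, length.out = 20)
  want <- vapply(xs, function(x) {
    dens <- function(s) dexp(s, 1 / 100) * dnorm(x - s, 50, 10)
    # integrate around the Gaussian peak at s = x - mu; the density is
    # negligible more than 12 sd away
    lo <- max(0, x - 50 - 120); hi <- max(0, x - 50) + 120
    num <- integrate(function(s) s * dens(s), lo, hi,
                     rel.tol = 1e-10)$value
    den <- integrate(dens, lo, hi, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
  expect_equal(normexp_correct(xs, params), want, tolerance = 1e-6)
  # strictly positive even far below the background mean, and monotone
  lo <- normexp_correct(seq(-50, 45, 5), params)
  expect_true(all(lo > 0))
  xs2 <- seq(-100, 1000, 7)
  expect_true(all(diff(normexp_correct(xs2, params)) > 0))
  # noiseless limit: corrected(x) ~ x for x >> 0 when sigma -> 0, mu = 0
  tiny <- structure(list(alpha = 100, mu = 0, sigma = 1e-4),
                    class = "NormexpParams")
  expect_equal(normexp_correct(c(50, 200, 500), tiny), c(50, 200, 500),
               tolerance = 1e-6)
  expect_error(normexp_correct(1, structure(list(alpha = -1, mu = 0,
                                                 sigma = 1),
                                            class = "NormexpParams")),
               "domain error")
})

test_that("quantile normalization: worked example, fixed points, defining property", {
  out <- quantile_normalize(cbind(a = c(2, 6), b = c(4, 8)))
  expect_equal(unname(out), cbind(c(3, 7), c(3, 7)))
  same <- cbind(x = c(1, 5, 9), y = c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)
  set.seed(23)
  m <- matrix(rnorm(1000 * 6), 1000, 6)
  q <- quantile_normalize(m)
  sorted <- apply(q, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  # idempotent to 1e-12
  expect_lt(max(abs(quantile_normalize(q) - q)), 1e-12)
  # ties get the mean of their spanned rank values
  tied <- cbind(c(1, 1, 10), c(2, 4, 6))
  qt <- quantile_normalize(tied)
  expect_equal(qt[1, 1], qt[2, 1])
  # cross-check against the reference implementation in limma (no ties)
  skip_if_not_installed("limma")
  expect_equal(unname(q), unname(limma::normalizeQuantiles(m)),
               tolerance = 1e-12)
  # reference mode maps onto the reference's distribution
  r <- quantile_normalize(m[, 1, drop = FALSE], reference = m[, 2])
  expect_equal(sort(r[, 1]), sort(m[, 2]))
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), ">= 2 vectors")
  expect_error(quantile_normalize(list(c(a = 1, b = 2), c(a = 1, zz = 2))),
               "feature sets differ")
})

test_that("scaling normalization equalizes the target statistic exactly", {
  v <- list(a = c(5, 10, 15), b = c(10, 30, 50))   # means 10 and 30
  out <- scale_normalize(v, mode = "average")
  expect_equal(vapply(out, mean, numeric(1)), c(a = 20, b = 20))
  set.seed(24)
  m <- matrix(rlnorm(200 * 4), 200, 4)
  sm <- scale_normalize(m, mode = "average")
  expect_equal(diff(range(colMeans(sm))), 0, tolerance = 1e-12)
  sp <- scale_normalize(m, mode = "percentile", p = 75)
  q75 <- apply(sp, 2, quantile, 0.75)
  expect_equal(diff(range(q75)), 0, tolerance = 1e-12)
  one <- scale_normalize(list(z = c(1, 2, 3)), mode = "average")
  expect_equal(one$z, c(1, 2, 3))
  expect_error(scale_normalize(list(c(0, 0)), mode = "average"), "zero")
  expect_error(scale_normalize(m, mode = "percentile", p = 0), "parameter")
})

test_that("loess MA normalization removes intensity-dependent dye bias", {
  set.seed(25)
  green <- rlnorm(2000, 8, 1)
  # constant ratio: corrected M centered at 0
  res <- loess_ma(3 * green, green)
  expect_lt(max(abs(res$M)), 0.05)
  # banana-shaped bias M = f(A) + eps: residual uncorrelated with A
  A_true <- log2(green) + rnorm(2000, 0, 0.3)
  bias <- 0.6 * sin(A_true / 2) + 0.1 * A_true
  M_true <- bias + rnorm(2000, 0, 0.1)
  red <- 2^(A_true + M_true / 2)
  grn <- 2^(A_true - M_true / 2)
  out <- loess_ma(red, grn)
  expect_lt(abs(cor(out$M, out$A)), 0.05)
  # printtip mode: per-block constant biases are both removed
  block <- rep(1:2, each = 1000)
  shift <- ifelse(block == 1, 1, -1)
  r2 <- grn * 2^shift
  pt <- loess_ma(r2, grn, printtip = block)
  expect_lt(abs(mean(pt$M[block == 1])), 0.05)
  expect_lt(abs(mean(pt$M[block == 2])), 0.05)
  expect_warning(loess_ma(grn[1:30], grn[1:30] * 2,
                          printtip = c(rep(1, 25), rep(2, 5))),
                 "< 10 features")
  expect_error(loess_ma(c(1, -2), c(1, 1)), "positive")
})

test_that("median polish: worked example, fixed point, oracle, row invariance", {
  mp <- median_polish(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(mp$overall + mp$col, c(2, 3))
  # residual row and column medians vanish
  set.seed(26)
  m <- matrix(rnorm(11 * 6), 11, 6)
  mp2 <- median_polish(m, tol = 1e-10, max_iter = 100)
  expect_lt(max(abs(apply(mp2$residuals, 1, median))), 1e-9)
  expect_lt(max(abs(apply(mp2$residuals, 2, median))), 1e-9)
  # independent oracle: stats::medpolish converges to the same decomposition
  or <- stats::medpolish(m, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
  expect_equal(mp2$overall + mp2$col, or$overall + or$col, tolerance = 1e-6)
  # adding a constant to one probe row is absorbed into the row effect
  m2 <- m
  m2[3, ] <- m2[3, ] + 7
  mp3 <- median_polish(m2, tol = 1e-10, max_iter = 100)
  expect_equal(mp3$overall + mp3$col, mp2$overall + mp2$col,
               tolerance = 1e-9)
})

test_that("summarize_probes collapses probesets per method", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("p1", "p2"), c("e1", "e2")))
  map <- probeset_map(c("p1", "p2", "q1"), c("g", "g", "h"))
  expect_warning(s <- summarize_probes(rbind(m, q1 = c(9, 9)), map,
                                       method = "median_polish"),
                 NA)
  expect_equal(unname(s["g", ]), c(2, 3))
  expect_equal(unname(s["h", ]), c(9, 9))  # single-probe group passthrough
  s2 <- summarize_probes(m, probeset_map(c("p1", "p2"), c("g", "g")),
                         method = "mean")
  expect_equal(unname(s2["g", ]), c(2, 3))
  expect_error(summarize_probes(m, probeset_map("zz", "g")), "no probe")
})

test_that("value transforms implement their contracts", {
  expect_equal(log2_transform(c(0, 1, 3)), log2(c(1, 2, 4)))
  expect_error(log2_transform(-1), "non-negative")
  x <- c(a = 0, b = 3, c = 1023)
  y <- interval_map_log(x, lo = 0, hi = 16)
  expect_equal(unname(y[c("a", "c")]), c(0, 16))  # endpoints map exactly
  expect_true(y["b"] > 0 && y["b"] < 16)
  expect_warning(cst <- interval_map_log(c(5, 5, 5), lo = 2, hi = 16),
                 "constant")
  expect_equal(unname(cst), rep(2, 3))
  ma <- ma_transform(c(g1 = 8), c(g1 = 2))
  expect_equal(unname(ma$M), 2)
  expect_equal(unname(ma$A), 2)
  ch <- list(R = c(1, 2), G = c(3, 4))
  expect_identical(dye_swap(dye_swap(ch)), ch)
  v <- c(p1 = 1, p2 = 2, p3 = 3)
  mapped <- map_identifiers(v, probeset_map(c("p1", "p2", "p3"),
                                            c("g", "g", "g")))
  expect_equal(mapped, c(g = 2))
})

test_that("the RMA-style chain recovers the true gene ranking", {
  # normexp -> quantile -> log2 -> median polish on synthetic probe data
  d <- study_design(seed = 31L)
  a1 <- synth_array(d, condition = 1, replicate = 1)
  a2 <- synth_array(d, condition = 1, replicate = 2)
  mat <- cbind(e1 = a1$table$fg[, 1], e2 = a2$table$fg[, 1])
  rownames(mat) <- a1$table$probes
  corrected <- apply(mat, 2, function(v) normexp_correct(v, normexp_fit(v)))
  rownames(corrected) <- rownames(mat)
  qn <- quantile_normalize(corrected)
  lg <- log2(qn + 1)
  summ <- summarize_probes(lg, a1$map, method = "median_polish")
  est <- rowMeans(summ)
  truth <- a1$truth[rownames(summ)]
  expect_gte(cor(est, truth, method = "spearman"), 0.95)
})
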