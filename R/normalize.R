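#' Background subtraction
#'
#' Subtracts a background intensity vector from a foreground vector,
#' flooring the result at a small positive constant so that subsequent log
#' transforms remain defined.
#'
#' @param fg,bg numeric vectors (linear scale, same features; names are
#'   compared when present).
#' @param floor lower bound for corrected values (default 0.5).
#' @return the corrected vector.
#' @export
bg_subtract <- function(fg, bg, floor = 0.5) {
  check_same_features(list(fg, bg))
  pmax(fg - bg, floor)
}

check_same_features <- function(vectors) {
  nms <- lapply(vectors, names)
  if (any(vapply(nms, is.null, logical(1)))) {
    lens <- vapply(vectors, length, integer(1))
    if (length(unique(lens)) > 1) {
      stop("feature sets differ: vector lengths ",
           paste(unique(lens), collapse = " vs "))
    }
    return(invisible(TRUE))
  }
  ref <- nms[[1]]
  for (i in seq_along(nms)[-1]) {
    if (!identical(sort(nms[[i]]), sort(ref))) {
      diff <- c(setdiff(ref, nms[[i]]), setdiff(nms[[i]], ref))
      stop("feature sets differ, e.g.: ",
           paste(utils::head(diff, 3), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Fit the normexp convolution model
#'
#' Models observed intensities as `X = S + B` with signal
#' `S ~ Exponential(mean alpha)` and background `B ~ Normal(mu, sigma^2)`.
#' Parameters are estimated by moment/quantile matching, not maximum
#' likelihood: `mu` and `sigma` are obtained from the lower tail by
#' weighted least-squares matching of the model CDF to a grid of
#' empirical lower-tail quantiles (default 0.5%..35%, where the
#' background dominates; weights `1/(p(1-p))` emphasize the extreme
#' tail, where `sigma` carries most information), and `alpha` from the
#' mean excess
#' `mean(x) - mu` (since `E[X] = mu + alpha`).  The three estimates are
#' iterated to a joint fixed point.  Results are therefore not expected to
#' match any specific likelihood-based implementation bit-for-bit.
#'
#' @param x numeric vector of observed intensities.
#' @param probs lower-tail probabilities used for quantile matching.
#' @param max_iter fixed-point iterations.
#' @return a list with elements `alpha`, `mu`, `sigma` (class
#'   `NormexpParams`).
#' @export
normexp_fit <- function(x, probs = seq(0.005, 0.35, by = 0.005),
                        max_iter = 10L) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || stats::sd(x) == 0) {
    stop("fit error: degenerate (constant or near-empty) input")
  }
  if (length(x) < 100) {
    warning("normexp_fit: fewer than 100 observations; estimates may be unstable")
  }
  q_emp <- stats::quantile(x, probs, names = FALSE, type = 7)
  mean_x <- mean(x)
  mu <- q_emp[1]
  sigma <- max(stats::sd(x[x <= stats::quantile(x, 0.25)]),
               1e-6 * stats::sd(x))
  alpha <- max(mean_x - mu, 1e-6 * stats::sd(x))
  w <- 1 / (probs * (1 - probs))
  # keep sigma away from the degenerate sigma -> 0 corner the optimizer
  # can fall into when the data deviate from the pure convolution model
  sigma_floor <- 0.01 * stats::sd(x)
  for (iter in seq_len(max_iter)) {
    fit <- stats::optim(c(mu, log(max(sigma - sigma_floor, sigma_floor))),
                        function(par) {
      p <- pnormexp(q_emp, par[1], sigma_floor + exp(par[2]), alpha)
      sum(w * (p - probs)^2)
    }, method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-13))
    mu <- fit$par[1]
    sigma <- sigma_floor + exp(fit$par[2])
    alpha_new <- mean_x - mu
    if (alpha_new <= 0) {
      warning("normexp_fit: estimated signal mean alpha is near zero (background-only input?)")
      alpha_new <- 1e-6 * stats::sd(x)
    }
    done <- abs(alpha_new - alpha) < 1e-8 * abs(alpha)
    alpha <- alpha_new
    if (done) break
  }
  if (alpha < sigma) {
    warning("normexp_fit: estimated signal mean alpha is near zero relative to the background sd (background-only input?)")
  }
  structure(list(alpha = alpha, mu = mu, sigma = sigma),
            class = "NormexpParams")
}

#' @export
print.NormexpParams <- function(x, ...) {
  cat(sprintf("NormexpParams: alpha = %.4g, mu = %.4g, sigma = %.4g\n",
              x$alpha, x$mu, x$sigma))
  invisible(x)
}

## CDF of X = Exponential(mean alpha) + Normal(mu, sigma^2), computed in
## log space to avoid overflow for x << mu.
pnormexp <- function(x, mu, sigma, alpha) {
  v <- (x - mu) / sigma
  log_tail <- (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
    stats::pnorm(v - sigma / alpha, log.p = TRUE)
  p <- stats::pnorm(v) - exp(log_tail)
  pmin(pmax(p, 0), 1)
}

#' Normexp background correction
#'
#' Replaces each observed intensity `x` by the conditional expectation of
#' the true signal given the observation, `E[S | S + B = x]`, under the
#' fitted convolution model.  The result is strictly positive and monotone
#' increasing in `x`.
#'
#' @param x numeric vector of observed intensities (linear scale).
#' @param params a `NormexpParams` from [normexp_fit()], or `NULL` to fit
#'   on `x` first.
#' @return corrected intensity vector.
#' @export
normexp_correct <- function(x, params = NULL) {
  if (is.null(params)) params <- normexp_fit(x)
  if (!all(is.finite(c(params$alpha, params$mu, params$sigma))) ||
      params$alpha <= 0 || params$sigma <= 0) {
    stop("domain error: invalid normexp parameters")
  }
  mu_sf <- x - params$mu - params$sigma^2 / params$alpha
  z <- mu_sf / params$sigma
  # inverse Mills ratio phi(z)/Phi(z); asymptote -z in the far left tail
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  bad <- !is.finite(mills)
  mills[bad] <- pmax(-z[bad], 0)
  out <- mu_sf + params$sigma * mills
  pmax(out, .Machine$double.xmin)
}

#' Quantile normalization
#'
#' Forces identical empirical distributions across experiments: the value
#' at rank `r` in each vector is replaced by the mean across vectors of
#' their rank-`r` values (or by the reference's rank-`r` value when a
#' reference is given).  Ties receive the mean of their spanned rank
#' values.
#'
#' @param x numeric matrix (features x experiments) or list of equally
#'   featured named vectors.
#' @param reference optional reference vector; with a reference a single
#'   input vector is allowed.
#' @return object of the same shape as `x` with normalized values.
#' @examples
#' quantile_normalize(cbind(a = c(2, 6), b = c(4, 8)))  # both become (3, 7)
#' @export
quantile_normalize <- function(x, reference = NULL) {
  was_list <- is.list(x)
  if (was_list) {
    check_same_features(x)
    nm1 <- names(x[[1]])
    mat <- vapply(x, function(v) if (is.null(nm1)) v else v[nm1],
                  numeric(length(x[[1]])))
    mat <- matrix(mat, ncol = length(x),
                  dimnames = list(nm1, names(x)))
  } else {
    mat <- as.matrix(x)
  }
  if (is.null(reference) && ncol(mat) < 2) {
    stop("quantile normalization needs >= 2 vectors, or 1 vector plus a reference")
  }
  n <- nrow(mat)
  ref_sorted <- if (is.null(reference)) {
    rowMeans(apply(mat, 2, sort))
  } else {
    if (length(reference) != n) {
      stop("feature sets differ: reference length ", length(reference),
           " vs ", n)
    }
    sort(reference)
  }
  out <- apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- ref_sorted[floor(r)]
    hi <- ref_sorted[ceiling(r)]
    (lo + hi) / 2
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(mat))
  if (was_list) {
    res <- lapply(seq_len(ncol(out)), function(j) {
      stats::setNames(out[, j], rownames(out))
    })
    names(res) <- names(x)
    # restore each vector's original feature order
    res <- mapply(function(v, orig) {
      if (is.null(names(orig))) v else v[names(orig)]
    }, res, x, SIMPLIFY = FALSE)
    res
  } else out
}

#' Scaling normalization
#'
#' Rescales each experiment multiplicatively so that its mean (`average`
#' mode) or `p`-th percentile (`percentile` mode) equals the across-vector
#' mean of that statistic.
#'
#' @param x numeric matrix (features x experiments) or list of vectors.
#' @param mode `"average"` or `"percentile"`.
#' @param p percentile in (0, 100) for percentile mode (default 75).
#' @return same shape as `x`.
#' @export
scale_normalize <- function(x, mode = c("average", "percentile"), p = 75) {
  mode <- match.arg(mode)
  if (mode == "percentile" && (p <= 0 || p >= 100)) {
    stop("parameter error: p must be in (0, 100)")
  }
  vecs <- if (is.list(x)) x else lapply(seq_len(ncol(as.matrix(x))),
                                        function(j) as.matrix(x)[, j])
  stat <- vapply(vecs, function(v) {
    if (mode == "average") mean(v) else
      stats::quantile(v, p / 100, names = FALSE)
  }, numeric(1))
  if (any(stat == 0)) {
    stop("error: zero ", if (mode == "average") "mean" else "percentile",
         " in at least one vector; cannot rescale")
  }
  target <- mean(stat)
  scaled <- mapply(function(v, s) v * (target / s), vecs, stat,
                   SIMPLIFY = FALSE)
  if (is.list(x)) {
    names(scaled) <- names(x)
    scaled
  } else {
    out <- do.call(cbind, scaled)
    dimnames(out) <- dimnames(as.matrix(x))
    out
  }
}

#' Loess MA normalization for two-channel arrays
#'
#' Computes `M = log2(red/green)` and `A = (log2(red) + log2(green))/2`,
#' fits a loess trend of M on A, and returns the residual M (intensity-
#' dependent dye bias removed).  With printtip block indices an independent
#' trend is fitted per block; blocks with fewer than 10 features fall back
#' to the global fit with a warning.
#'
#' @param red,green positive numeric vectors (linear scale) of one array's
#'   two channels.
#' @param span loess span (default 0.3).
#' @param printtip optional integer block index per feature.
#' @return list with corrected `M` and `A`.
#' @export
loess_ma <- function(red, green, span = 0.3, printtip = NULL) {
  if (any(red <= 0) || any(green <= 0)) {
    stop("domain error: loess MA normalization requires positive intensities")
  }
  check_same_features(list(red, green))
  M <- log2(red / green)
  A <- (log2(red) + log2(green)) / 2
  fit_resid <- function(idx) {
    fit <- stats::loess(M[idx] ~ A[idx], span = span, degree = 1,
                        family = "gaussian")
    M[idx] - stats::fitted(fit)
  }
  out <- M
  if (is.null(printtip)) {
    out <- fit_resid(seq_along(M))
  } else {
    global <- NULL
    for (b in unique(printtip)) {
      idx <- which(printtip == b)
      if (length(idx) < 10) {
        warning(sprintf("printtip block %s has < 10 features; using global fit", b))
        if (is.null(global)) global <- fit_resid(seq_along(M))
        out[idx] <- global[idx]
      } else {
        out[idx] <- fit_resid(idx)
      }
    }
  }
  list(M = out, A = A)
}

#' Median polish
#'
#' Tukey's alternating row/column median sweeping: medians are removed
#' from rows, then columns, until the largest absolute change in a sweep
#' falls below `tol` or `max_iter` iterations are reached.
#'
#' @param mat numeric matrix.
#' @param tol convergence tolerance on the maximal absolute change.
#' @param max_iter maximal number of full (row+column) sweeps.
#' @return list with `overall`, `row` effects, `col` effects, `residuals`.
#' @export
median_polish <- function(mat, tol = 1e-4, max_iter = 10L) {
  mat <- as.matrix(mat)
  overall <- 0
  row_eff <- numeric(nrow(mat))
  col_eff <- numeric(ncol(mat))
  res <- mat
  for (iter in seq_len(max_iter)) {
    delta <- 0
    rm <- apply(res, 1, stats::median)
    res <- res - rm
    row_eff <- row_eff + rm
    cm <- stats::median(col_eff)
    col_eff <- col_eff - cm
    overall <- overall + cm
    delta <- max(delta, max(abs(rm)), abs(cm))
    cm2 <- apply(res, 2, stats::median)
    res <- sweep(res, 2, cm2)
    col_eff <- col_eff + cm2
    rm2 <- stats::median(row_eff)
    row_eff <- row_eff - rm2
    overall <- overall + rm2
    delta <- max(delta, max(abs(cm2)), abs(rm2))
    if (delta < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = res)
}

#' Summarize probes into probesets
#'
#' Collapses the probes of each probeset (feature) into one value per
#' experiment.  `median_polish` follows the RMA convention (apply on
#' log-scale data; summarized value = overall effect + column effect);
#' `mean` and `median` are column-wise per group.
#'
#' @param mat numeric matrix probes x experiments, rownames = probe ids.
#' @param map a `ProbesetMap` (named vector probe -> feature).
#' @param method `"median_polish"`, `"mean"` or `"median"`.
#' @return numeric matrix features x experiments.
#' @export
summarize_probes <- function(mat, map, method = c("median_polish", "mean",
                                                  "median")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  feat <- unclass(map)[rownames(mat)]
  unmapped <- is.na(feat)
  if (all(unmapped)) stop("no probe of the matrix occurs in the probeset map")
  if (any(unmapped)) {
    warning(sprintf("%d unmapped probe(s) dropped during summarization",
                    sum(unmapped)))
    mat <- mat[!unmapped, , drop = FALSE]
    feat <- feat[!unmapped]
  }
  groups <- split(seq_len(nrow(mat)), feat)
  out <- t(vapply(groups, function(idx) {
    sub <- mat[idx, , drop = FALSE]
    if (length(idx) == 1) return(sub[1, ])
    switch(method,
           mean = colMeans(sub),
           median = apply(sub, 2, stats::median),
           median_polish = {
             mp <- median_polish(sub)
             mp$overall + mp$col
           })
  }, numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  out
}

#' Generic value transforms
#'
#' @param x numeric vector (named by feature).
#' @param c pseudo-count added before taking logs (default 1).
#' @return transformed vector.
#' @rdname value_transform
#' @export
log2_transform <- function(x, c = 1) {
  if (any(x < 0)) stop("domain error: log2 transform requires non-negative input")
  log2(x + c)
}

#' @rdname value_transform
#' @param lo,hi target interval bounds (defaults 0 and 16).
#' @param range optional shared `c(min, max)` of `log2(x + 1)` across a
#'   group of experiments, so that several vectors are mapped with one
#'   common scale; default is the per-vector min/max.
#' @details `interval_map_log` maps values logarithmically onto
#'   `[lo, hi]`: `y = lo + (hi - lo) * (log2(x+1) - m) / (M - m)` with
#'   `m`, `M` the (shared or per-vector) extremes of `log2(x + 1)`.
#' @export
interval_map_log <- function(x, lo = 0, hi = 16, range = NULL) {
  if (any(x < 0)) stop("domain error: interval_map_log requires non-negative input")
  lx <- log2(x + 1)
  if (is.null(range)) range <- c(min(lx), max(lx))
  if (diff(range) == 0) {
    warning("constant vector: all values mapped to the lower bound")
    return(stats::setNames(rep(lo, length(x)), names(x)))
  }
  lo + (hi - lo) * (lx - range[1]) / (range[2] - range[1])
}

#' @rdname value_transform
#' @param red,green two-channel intensity vectors.
#' @export
ma_transform <- function(red, green) {
  if (any(red <= 0) || any(green <= 0)) {
    stop("domain error: MA transform requires positive intensities")
  }
  list(M = log2(red / green), A = (log2(red) + log2(green)) / 2)
}

#' @rdname value_transform
#' @param channels a list of two channel vectors (or an `M`/`A` pair).
#' @details `dye_swap` exchanges the two channels; on MA data this negates
#'   M and is an involution.
#' @export
dye_swap <- function(channels) {
  if (length(channels) != 2) stop("dye swap requires exactly two channels")
  channels[c(2, 1)]
}

#' @rdname value_transform
#' @param map named vector old feature id -> new feature id.
#' @details `map_identifiers` renames features; several features mapping to
#'   the same target are aggregated by their mean.
#' @export
map_identifiers <- function(x, map) {
  new <- unclass(map)[names(x)]
  keep <- !is.na(new)
  if (!any(keep)) stop("no feature of the vector occurs in the identifier map")
  v <- tapply(x[keep], new[keep], mean)
  stats::setNames(as.numeric(v), names(v))
}
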