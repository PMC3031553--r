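# Independent brute-force oracles for the locus merge algebra: exhaustive
# pairwise interval arithmetic on plain data.frames, no index structures,
# no vectorized shortcuts.  Deliberately slow and simple.

canon_loci <- function(x) {
  df <- as.data.frame(x)[, c("species", "chrom", "start", "end", "strand")]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

oracle_pool <- function(sets) {
  do.call(rbind, lapply(sets, as.data.frame))
}

oracle_groups <- function(pool) {
  split(pool, paste(pool$species, pool$chrom, pool$strand))
}

oracle_union <- function(sets, min_size) {
  pool <- oracle_pool(sets)
  keep <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pool))) {
      if (j <= i) next
      if (pool$species[i] == pool$species[j] &&
          pool$chrom[i] == pool$chrom[j] &&
          pool$start[i] == pool$start[j] && pool$end[i] == pool$end[j] &&
          pool$strand[i] == pool$strand[j]) {
        keep[j] <- FALSE
      }
    }
  }
  out <- pool[keep & (pool$end - pool$start) >= min_size, , drop = FALSE]
  canon_loci(out)
}

oracle_pairwise <- function(sets, min_size) {
  pool <- oracle_pool(sets)
  res <- NULL
  for (g in oracle_groups(pool)) {
    bounds <- sort(unique(c(g$start, g$end)))
    if (length(bounds) < 2) next
    for (k in seq_len(length(bounds) - 1)) {
      s <- bounds[k]; e <- bounds[k + 1]
      covered <- FALSE
      for (i in seq_len(nrow(g))) {
        if (g$start[i] < e && g$end[i] > s) covered <- TRUE
      }
      if (covered && (e - s) >= min_size) {
        res <- rbind(res, data.frame(species = g$species[1],
                                     chrom = g$chrom[1], start = s, end = e,
                                     strand = g$strand[1]))
      }
    }
  }
  if (is.null(res)) res <- data.frame(species = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), strand = character())
  canon_loci(res)
}

# Greedy: scan in (start, end) order; recompute the cluster span from its
# members at every step (no incremental bookkeeping).
oracle_greedy <- function(sets, min_overlap = NULL, max_distance = NULL) {
  pool <- oracle_pool(sets)
  res <- NULL
  for (g in oracle_groups(pool)) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    members <- list(1L)
    for (i in seq_len(nrow(g))[-1]) {
      cur <- members[[length(members)]]
      span_s <- min(g$start[cur]); span_e <- max(g$end[cur])
      join <- if (!is.null(min_overlap)) {
        min(span_e, g$end[i]) - max(span_s, g$start[i]) >= min_overlap
      } else {
        g$start[i] - span_e <= max_distance
      }
      if (join) members[[length(members)]] <- c(cur, i)
      else members <- c(members, list(i))
    }
    for (cur in members) {
      res <- rbind(res, data.frame(species = g$species[1], chrom = g$chrom[1],
                                   start = min(g$start[cur]),
                                   end = max(g$end[cur]),
                                   strand = g$strand[1]))
    }
  }
  if (is.null(res)) res <- data.frame(species = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), strand = character())
  canon_loci(res)
}

oracle_minmax <- function(sets, min_size, max_size) {
  pool <- oracle_pool(sets)
  res <- NULL
  for (g in oracle_groups(pool)) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    exts <- list(1L)
    for (i in seq_len(nrow(g))[-1]) {
      cur <- exts[[length(exts)]]
      span_s <- min(g$start[cur]); span_e <- max(g$end[cur])
      overlaps <- g$start[i] < span_e
      within_max <- max(span_e, g$end[i]) - span_s <= max_size
      if (overlaps && within_max) exts[[length(exts)]] <- c(cur, i)
      else exts <- c(exts, list(i))
    }
    for (cur in exts) {
      s <- min(g$start[cur]); e <- max(g$end[cur])
      if (e - s >= min_size && e - s <= max_size) {
        res <- rbind(res, data.frame(species = g$species[1],
                                     chrom = g$chrom[1], start = s, end = e,
                                     strand = g$strand[1]))
      }
    }
  }
  if (is.null(res)) res <- data.frame(species = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), strand = character())
  canon_loci(res)
}

# Random merge test instance: 1-3 sets, <= 50 loci total, coords < 1e4.
random_locus_sets <- function(n_total = sample(5:50, 1),
                              n_sets = sample(1:3, 1),
                              n_chrom = sample(1:2, 1), stranded = TRUE) {
  split_sizes <- tabulate(sample.int(n_sets, n_total, replace = TRUE),
                          n_sets)
  lapply(split_sizes, function(k) {
    if (k == 0) return(locus_set(chrom = character(), start = integer(),
                                 end = integer()))
    start <- sample(0:9700, k, replace = TRUE)
    len <- sample(1:300, k, replace = TRUE)
    locus_set(species = "sp", chrom = paste0("c", sample.int(n_chrom, k,
                                                             replace = TRUE)),
              start = start, end = start + len,
              strand = if (stranded) sample(c("+", "-", "*"), k,
                                            replace = TRUE) else "*")
  })
}

# Naive per-position coverage counter.
oracle_coverage <- function(df, length_out) {
  depth <- integer(length_out)
  for (i in seq_len(nrow(df))) {
    idx <- (df$start[i] + 1):df$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}
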