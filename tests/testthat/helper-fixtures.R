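# Shared fixtures and independent oracles, built in code at test time.

# fragment collection from a compact spec: list of c(start, pattern[, count])
fc <- function(..., chrom = "chr1", n_cpgs = NA, provenance = "fixture") {
  rows <- list(...)
  df <- data.frame(
    chrom = chrom,
    start_cpg = vapply(rows, function(r) as.integer(r[[1]]), integer(1)),
    pattern = vapply(rows, function(r) as.character(r[[2]]), character(1)),
    count = vapply(rows, function(r) {
      if (length(r) >= 3) as.integer(r[[3]]) else 1L
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  fragment_collection(df, provenance = provenance, n_cpgs = n_cpgs)
}

# map with uniform spacing, one chromosome, single island
uniform_map <- function(n, spacing = 25, start = 1000) {
  cpg_map(rep("chr1", n), seq(start, by = spacing, length.out = n))
}

# brute-force per-CpG tally oracle: walks every fragment character
brute_tally <- function(x, n) {
  meth <- tot <- integer(n)
  for (i in seq_len(nrow(x))) {
    calls <- strsplit(x$pattern[i], "")[[1]]
    for (j in seq_along(calls)) {
      if (calls[j] == ".") next
      at <- x$start_cpg[i] + j
      tot[at] <- tot[at] + x$count[i]
      if (calls[j] == "C") meth[at] <- meth[at] + x$count[i]
    }
  }
  list(meth = meth, total = tot)
}

# brute-force O(n^3) average-linkage agglomeration on an L1 distance matrix
brute_average_linkage <- function(m) {
  n <- ncol(m)
  d <- as.matrix(dist(t(m), method = "manhattan"))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive 0.01-step grid search oracle for 2-cell-type NNLS
grid_nnls_2 <- function(A, b) {
  g <- seq(0, 1.5, by = 0.01)
  best <- c(NA, NA); bestv <- Inf
  for (x1 in g) {
    r1 <- b - A[, 1] * x1
    for (x2 in g) {
      v <- sum((r1 - A[, 2] * x2)^2)
      if (v < bestv) { bestv <- v; best <- c(x1, x2) }
    }
  }
  best
}

# exact permutation p-value for the Welch t statistic (all label permutations)
perm_welch_p <- function(x, y) {
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  obs <- abs(welch_t(x, y))
  all <- c(x, y)
  idx <- combn(length(all), length(x))
  ts <- apply(idx, 2, function(ii) abs(welch_t(all[ii], all[-ii])))
  mean(ts >= obs - 1e-12)
}

# small reference world used by several marker/deconvolution tests
small_world <- function(seed = 42, n_cell_types = 4, n_cpgs = 1500,
                        blocks_per_cell_type = 8, coverage = 10,
                        n_reps = 3, island_cpgs = c(6, 12)) {
  cfg <- sim_config(n_cell_types = n_cell_types, n_cpgs = n_cpgs,
                    blocks_per_cell_type = blocks_per_cell_type,
                    island_cpgs = island_cpgs, coverage = coverage,
                    seed = seed)
  map <- build_cpg_map(cfg)
  refs <- simulate_reference_methylomes(map, cfg)
  samples <- list()
  for (ct in refs$cell_types) {
    for (r in seq_len(n_reps)) {
      nm <- sprintf("%s_r%d", ct, r)
      samples[[nm]] <- sample_fragments(refs, cell_type = ct,
                                        coverage = coverage,
                                        seed = seed + 100 * match(ct, refs$cell_types) + r)
    }
  }
  groups <- split(names(samples), sub("_r[0-9]+$", "", names(samples)))
  list(cfg = cfg, map = map, refs = refs, samples = samples, groups = groups)
}
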