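#' Segment the CpG universe into co-methylated blocks
#'
#' Greedy left-to-right scan over the CpG map: the running block is extended
#' to the next CpG iff (a) the block's bp span stays within `max_bp`, (b)
#' the CpG is on the same chromosome, and (c) the mean absolute difference
#' across samples between the candidate CpG's methylation vector and the
#' running block-mean vector is at most `homogeneity_tol`. Runs shorter than
#' `min_cpg` are discarded. The output is a sorted, disjoint set of blocks
#' covering a subset of CpGs.
#'
#' This greedy homogeneity rule is a stated substitute for the segmentation
#' used to produce published block counts; see the package vignette for its
#' known limitations (in particular, boundaries at which only a small
#' minority of samples change methylation are invisible to the mean
#' absolute difference, which is why the synthetic genome places marker
#' islands between CpG-poor gaps wider than `max_bp`).
#'
#' @param meth Numeric matrix, n_cpgs x n_samples, of per-CpG methylation
#'   levels in `[0, 1]`; `NA` allowed (pairs with `NA` are ignored in the
#'   homogeneity comparison).
#' @param map A [cpg_map()] aligned with the rows of `meth`.
#' @param min_cpg Minimum CpGs per block (default 4).
#' @param max_bp Maximum block span in bp (default 5000).
#' @param homogeneity_tol Extension threshold on the mean absolute
#'   difference (default 0.25).
#' @return An object of class `block_set`: data.frame with columns `chrom`,
#'   `start_bp`, `end_bp`, `start_cpg`, `end_cpg`, `n_cpgs` (CpG interval
#'   0-based half-open; bp interval covers the CpG dinucleotides).
#' @export
segment_genome <- function(meth, map, min_cpg = 4, max_bp = 5000,
                           homogeneity_tol = 0.25) {
  stopifnot(inherits(map, "cpg_map"))
  if (is.vector(meth)) meth <- matrix(meth, ncol = 1)
  stopifnot(nrow(meth) == nrow(map))
  if (!is_count(min_cpg)) stop("min_cpg must be a positive integer")
  if (!(is.numeric(max_bp) && max_bp >= 1)) stop("max_bp must be >= 1")
  if (is.unsorted(map$index)) stop("unsorted map")

  n <- nrow(map)
  ns <- ncol(meth)
  starts <- integer(0); ends <- integer(0)
  bs <- 1L                       # block start (1-based row)
  sums <- meth[1L, ]; cnt <- as.numeric(!is.na(sums))
  sums[is.na(sums)] <- 0
  close_block <- function(bs, be) {
    if (be - bs + 1L >= min_cpg) {
      starts <<- c(starts, bs); ends <<- c(ends, be)
    }
  }
  if (n > 1) {
    for (i in 2:n) {
      extend <- map$chrom[i] == map$chrom[bs] &&
        (map$pos[i] + 2L - map$pos[bs]) <= max_bp
      if (extend) {
        mu <- ifelse(cnt > 0, sums / cnt, NA_real_)
        d <- abs(meth[i, ] - mu)
        md <- if (all(is.na(d))) 0 else mean(d, na.rm = TRUE)
        extend <- md <= homogeneity_tol
      }
      if (extend) {
        v <- meth[i, ]
        ok <- !is.na(v)
        sums[ok] <- sums[ok] + v[ok]
        cnt <- cnt + ok
      } else {
        close_block(bs, i - 1L)
        bs <- i
        sums <- meth[i, ]; cnt <- as.numeric(!is.na(sums))
        sums[is.na(sums)] <- 0
      }
    }
  }
  close_block(bs, n)
  blocks <- data.frame(
    chrom = map$chrom[starts],
    start_bp = map$pos[starts],
    end_bp = map$pos[ends] + 2L,
    start_cpg = map$index[starts],
    end_cpg = map$index[ends] + 1L,
    n_cpgs = ends - starts + 1L,
    stringsAsFactors = FALSE
  )
  class(blocks) <- c("block_set", "data.frame")
  blocks
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("Block set: %d blocks, %d CpGs covered, median %d CpGs/block\n",
              nrow(x), sum(x$n_cpgs),
              if (nrow(x)) as.integer(stats::median(x$n_cpgs)) else 0L))
  invisible(x)
}

#' Write / read a block set as 5-column BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, start_cpg, end_cpg. CpG indices are
#' 1-based half-open on disk (the only place the shift happens).
#' @param blocks A `block_set`.
#' @param path File path.
#' @return `write_blocks`: `path` invisibly; `read_blocks`: a `block_set`.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(
    data.frame(blocks$chrom, blocks$start_bp, blocks$end_bp,
               blocks$start_cpg + 1L, blocks$end_cpg + 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start_bp", "end_bp",
                                        "start_cpg", "end_cpg"),
                          stringsAsFactors = FALSE)
  df$start_cpg <- df$start_cpg - 1L
  df$end_cpg <- df$end_cpg - 1L
  df$n_cpgs <- df$end_cpg - df$start_cpg
  class(df) <- c("block_set", "data.frame")
  df
}

#' Samples x blocks mean-methylation table
#'
#' For every block and sample, the cell value is (methylated calls) /
#' (total calls) over the block's CpGs, with the parallel coverage matrix
#' recorded; cells with coverage below `min_depth` (including zero) are set
#' to `NA`.
#'
#' @param blocks A `block_set`.
#' @param samples Named list of [fragment_collection()]s, or of per-CpG
#'   tally lists (`list(meth=, total=)` as produced internally) for
#'   streaming use.
#' @param n_cpgs CpG-universe size (required when tallies are passed and no
#'   collection carries it).
#' @param min_depth Minimum calls for a non-missing cell (10 for
#'   clustering, 5 for marker selection, following the read-depth rules).
#' @return An object of class `block_table`: list with `meth` and
#'   `coverage` matrices (blocks x samples), `blocks`, and `min_depth`.
#' @export
block_methylation_table <- function(blocks, samples, n_cpgs = NULL,
                                    min_depth = 10) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- sprintf("s%02d", seq_along(samples))
  }
  if (is.null(n_cpgs)) {
    for (s in samples) {
      if (inherits(s, "fragment_collection") && !is.na(attr(s, "n_cpgs"))) {
        n_cpgs <- attr(s, "n_cpgs"); break
      }
    }
  }
  if (is.null(n_cpgs)) stop("give `n_cpgs` (cannot infer it from the samples)")
  if (nrow(blocks) > 0 && max(blocks$end_cpg) > n_cpgs) {
    stop("blocks extend beyond the CpG universe")
  }
  nb <- nrow(blocks)
  meth <- cov <- matrix(NA_real_, nb, length(samples),
                        dimnames = list(block_ids(blocks), names(samples)))
  for (j in seq_along(samples)) {
    t <- samples[[j]]
    if (inherits(t, "fragment_collection")) t <- per_cpg_tally(t, n_cpgs)
    cm <- cumsum(t$meth); ct <- cumsum(t$total)
    m <- cm[blocks$end_cpg] - c(0, cm)[blocks$start_cpg + 1L]
    tot <- ct[blocks$end_cpg] - c(0, ct)[blocks$start_cpg + 1L]
    cov[, j] <- tot
    meth[, j] <- ifelse(tot > 0, m / tot, NA_real_)
  }
  meth[cov < min_depth] <- NA_real_
  structure(list(meth = meth, coverage = cov, blocks = blocks,
                 min_depth = min_depth),
            class = "block_table")
}

block_ids <- function(blocks) {
  sprintf("%s:%d-%d", blocks$chrom, blocks$start_bp, blocks$end_bp)
}

#' @export
print.block_table <- function(x, ...) {
  cat(sprintf("Block table: %d blocks x %d samples (min depth %g); %.1f%% cells missing\n",
              nrow(x$meth), ncol(x$meth), x$min_depth,
              100 * mean(is.na(x$meth))))
  invisible(x)
}

#' Keep the most variable fully-observed blocks
#'
#' Blocks with any missing cell are removed first; the remainder are ranked
#' by across-sample variance and the top `ceiling(fraction * n)` kept, ties
#' broken by genomic order.
#'
#' @param table A [block_methylation_table()].
#' @param fraction Fraction of complete blocks to keep (default 0.01, the
#'   "top 1% by variance" rule).
#' @return A `block_table` restricted to the selected blocks.
#' @export
top_variance_blocks <- function(table, fraction = 0.01) {
  stopifnot(inherits(table, "block_table"))
  if (!(is.numeric(fraction) && fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]")
  }
  complete <- which(rowSums(is.na(table$meth)) == 0)
  if (length(complete) == 0) stop("no blocks without missing values")
  v <- apply(table$meth[complete, , drop = FALSE], 1, stats::var)
  k <- ceiling(fraction * length(complete))
  ord <- complete[order(-v, complete)]  # variance desc, then genomic order
  keep <- sort(ord[seq_len(k)])
  structure(list(meth = table$meth[keep, , drop = FALSE],
                 coverage = table$coverage[keep, , drop = FALSE],
                 blocks = table$blocks[keep, , drop = FALSE],
                 min_depth = table$min_depth),
            class = "block_table")
}

#' Hierarchically cluster samples on a block table
#'
#' Pairwise city-block (L1 / manhattan) distances between sample columns,
#' agglomerated with average linkage. The table must have no missing cells
#' (filter with [top_variance_blocks()] first).
#'
#' @param table A complete [block_methylation_table()].
#' @return An [stats::hclust] object (merge list plus heights).
#' @export
cluster_samples <- function(table) {
  stopifnot(inherits(table, "block_table"))
  if (ncol(table$meth) < 2) stop("need at least 2 samples to cluster")
  if (anyNA(table$meth)) {
    stop("block table has missing cells; select complete blocks first")
  }
  d <- stats::dist(t(table$meth), method = "manhattan")
  stats::hclust(d, method = "average")
}
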