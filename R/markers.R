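#' Marker selection configuration
#'
#' @param min_diff Minimum methylation difference between background and
#'   target group means (default 0.3).
#' @param alpha Welch t-test p-value threshold (default 0.05; raw p-values,
#'   no multiple-testing correction — kept faithful to the source method
#'   and flagged here).
#' @param max_na_frac Maximum allowed per-group missing fraction for a
#'   block (default 1/3: blocks with more than 1 in 3 NA values in either
#'   group are removed).
#' @param min_depth Read depth below which a block table cell should have
#'   been set to `NA` when the table was built (default 5); recorded here
#'   for provenance.
#' @param direction `"hypomethylated"` (default) or `"hypermethylated"`.
#' @param k Number of markers to keep per cell type (the source method's
#'   menu is 25, 50, 100, 250, 300, 400 or 500; any positive integer is
#'   accepted).
#' @return An object of class `marker_config`.
#' @export
marker_config <- function(min_diff = 0.3, alpha = 0.05, max_na_frac = 1 / 3,
                          min_depth = 5,
                          direction = c("hypomethylated", "hypermethylated"),
                          k = 100) {
  direction <- match.arg(direction)
  if (!(is.numeric(min_diff) && min_diff > 0 && min_diff <= 1)) {
    stop("min_diff must be in (0, 1]")
  }
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is_prob(max_na_frac)) stop("max_na_frac must be in [0, 1]")
  if (!is_count(k)) stop("k must be a positive integer")
  structure(list(min_diff = min_diff, alpha = alpha, max_na_frac = max_na_frac,
                 min_depth = min_depth, direction = direction, k = as.integer(k)),
            class = "marker_config")
}

# Vectorised two-sided Welch t-test over rows of two matrices (NA-aware).
# Identical statistic and Welch-Satterthwaite df to stats::t.test; with
# zero variance in both groups the p-value degenerates to 0 when the means
# differ (stats::t.test errors there instead).
welch_rows <- function(x, y) {
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- ifelse(se2 == 0, ifelse(mx == my, NA_real_, 0),
              2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p, mean_x = mx, mean_y = my, n_x = nx, n_y = ny)
}

#' Find cell-type-specific differentially methylated marker candidates
#'
#' Screens every block of a block table for cell-type-specific
#' hypomethylation (or hypermethylation) of the target group against the
#' background group. Blocks with a missing fraction above `max_na_frac` in
#' either group are removed before testing; blocks where either group has
#' fewer than 2 non-missing values are skipped (the t-test is undefined).
#' A candidate is retained iff the group-mean difference in the requested
#' direction is at least `min_diff` and the two-sided Welch t-test p-value
#' is at most `alpha`. Each candidate's separation margin is computed from
#' order-statistic percentiles (linear interpolation): for hypomethylated
#' markers, background 2.5th percentile minus target 75th percentile.
#'
#' @param table A [block_methylation_table()] (built with the
#'   marker-selection depth rule, `min_depth = 5`).
#' @param target,background Disjoint, non-empty character vectors of sample
#'   (column) names.
#' @param config A [marker_config()].
#' @return data.frame of candidates: block columns plus `target_mean`,
#'   `background_mean`, `diff`, `p_value`, `margin`.
#' @export
find_markers <- function(table, target, background, config = marker_config()) {
  stopifnot(inherits(table, "block_table"), inherits(config, "marker_config"))
  if (length(target) == 0 || length(background) == 0) {
    stop("target and background groups must be non-empty")
  }
  if (length(intersect(target, background)) > 0) {
    stop("target and background groups must be disjoint")
  }
  miss <- setdiff(c(target, background), colnames(table$meth))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))

  mt <- table$meth[, target, drop = FALSE]
  mb <- table$meth[, background, drop = FALSE]
  ok <- rowMeans(is.na(mt)) <= config$max_na_frac &
        rowMeans(is.na(mb)) <= config$max_na_frac
  ok <- ok & rowSums(!is.na(mt)) >= 2 & rowSums(!is.na(mb)) >= 2
  idx <- which(ok)
  if (length(idx) == 0) {
    out <- cbind(table$blocks[0, ],
                 target_mean = numeric(0), background_mean = numeric(0),
                 diff = numeric(0), p_value = numeric(0), margin = numeric(0))
    return(out)
  }
  w <- welch_rows(mt[idx, , drop = FALSE], mb[idx, , drop = FALSE])
  hypo <- config$direction == "hypomethylated"
  diff <- if (hypo) w$mean_y - w$mean_x else w$mean_x - w$mean_y
  keep <- !is.na(diff) & diff >= config$min_diff &
          !is.na(w$p) & w$p <= config$alpha
  idx2 <- idx[keep]
  if (length(idx2) == 0) {
    out <- cbind(table$blocks[0, ],
                 target_mean = numeric(0), background_mean = numeric(0),
                 diff = numeric(0), p_value = numeric(0), margin = numeric(0))
    return(out)
  }
  q <- function(m, p) apply(m, 1, stats::quantile, probs = p, na.rm = TRUE,
                            names = FALSE)
  tg <- mt[idx2, , drop = FALSE]; bg <- mb[idx2, , drop = FALSE]
  margin <- if (hypo) q(bg, 0.025) - q(tg, 0.75) else q(tg, 0.25) - q(bg, 0.975)
  out <- cbind(table$blocks[idx2, ],
               target_mean = w$mean_x[keep], background_mean = w$mean_y[keep],
               diff = diff[keep], p_value = w$p[keep], margin = margin)
  rownames(out) <- NULL
  out
}

#' Rank candidates by separation margin and keep the best k
#'
#' Candidates are ordered by margin (descending), ties broken by p-value
#' (ascending) then genomic order, and the top `k` kept. An empty candidate
#' list yields an empty marker set with a warning.
#'
#' @param candidates Output of [find_markers()].
#' @param k Number of markers to keep.
#' @param cell_type Optional label stored on the result.
#' @return An object of class `marker_set` (data.frame ordered best-first).
#' @export
rank_and_select <- function(candidates, k, cell_type = NULL) {
  if (!is_count(k)) stop("k must be a positive integer")
  if (nrow(candidates) == 0) {
    warning("no marker candidates to rank; returning an empty marker set")
    out <- candidates
  } else {
    ord <- order(-candidates$margin, candidates$p_value,
                 candidates$chrom, candidates$start_cpg, method = "radix")
    out <- candidates[ord[seq_len(min(k, nrow(candidates)))], ]
    rownames(out) <- NULL
  }
  if (!is.null(cell_type)) out$cell_type <- rep(cell_type, nrow(out))
  class(out) <- c("marker_set", class(candidates))
  out
}

#' Select markers for every cell type of a grouped block table
#'
#' Runs [find_markers()] + [rank_and_select()] for each cell type against
#' all remaining samples, and binds the per-type marker sets into the row
#' universe used to build a deconvolution atlas.
#'
#' @param table A [block_methylation_table()].
#' @param groups Named list: cell type -> character vector of its sample
#'   columns.
#' @param config A [marker_config()]; `config$k` markers kept per type.
#' @return A `marker_set` data.frame with a `cell_type` column.
#' @export
select_all_markers <- function(table, groups, config = marker_config()) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  sets <- lapply(names(groups), function(ct) {
    cand <- find_markers(table, groups[[ct]],
                         unlist(groups[names(groups) != ct], use.names = FALSE),
                         config)
    suppressWarnings(rank_and_select(cand, config$k, cell_type = ct))
  })
  out <- do.call(rbind, sets)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Write / read a marker set as BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, start_cpg, end_cpg (1-based on disk),
#' cell_type, diff, p, margin.
#' @param markers A `marker_set`.
#' @param path File path.
#' @export
write_markers <- function(markers, path) {
  ct <- if ("cell_type" %in% names(markers)) markers$cell_type else NA
  utils::write.table(
    data.frame(chrom = markers$chrom, start_bp = markers$start_bp,
               end_bp = markers$end_bp, start_cpg = markers$start_cpg + 1L,
               end_cpg = markers$end_cpg + 1L, cell_type = ct,
               diff = markers$diff, p = markers$p_value,
               margin = markers$margin),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$start_cpg <- df$start_cpg - 1L
  df$end_cpg <- df$end_cpg - 1L
  names(df)[names(df) == "p"] <- "p_value"
  df$n_cpgs <- df$end_cpg - df$start_cpg
  class(df) <- c("marker_set", "data.frame")
  df
}
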