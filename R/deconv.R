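#' Deconvolution configuration
#'
#' Fragment-level classification thresholds. A fragment is classified over
#' a marker using only its non-missing calls at CpGs inside the marker: if
#' fewer than `min_fragment_cpgs` such calls exist the fragment is
#' excluded; otherwise it is `U` when its methylated-call fraction is at
#' most `u_threshold`, `M` when at least `m_threshold`, and `X` otherwise.
#' The 0.25/0.75 thresholds and the minimum of 3 in-marker calls follow
#' the established fragment-level (U/X/M) deconvolution conventions; all
#' are configurable.
#'
#' @param u_threshold Maximum methylated fraction for a `U` call
#'   (default 0.25).
#' @param m_threshold Minimum methylated fraction for an `M` call
#'   (default 0.75).
#' @param min_fragment_cpgs Minimum observed in-marker calls (default 3).
#' @param min_fragments_per_marker Minimum classified fragments an atlas
#'   row needs in every column (default 1).
#' @param detection_epsilon Estimated proportion above which a cell type
#'   counts as detected (default 0: any mass).
#' @return An object of class `deconv_config`.
#' @export
deconv_config <- function(u_threshold = 0.25, m_threshold = 0.75,
                          min_fragment_cpgs = 3, min_fragments_per_marker = 1,
                          detection_epsilon = 0) {
  if (!(is_prob(u_threshold) && is_prob(m_threshold) &&
        u_threshold < m_threshold)) {
    stop("need 0 <= u_threshold < m_threshold <= 1")
  }
  if (!is_count(min_fragment_cpgs)) stop("min_fragment_cpgs must be a positive integer")
  if (!is_count(min_fragments_per_marker)) {
    stop("min_fragments_per_marker must be a positive integer")
  }
  structure(list(u_threshold = u_threshold, m_threshold = m_threshold,
                 min_fragment_cpgs = as.integer(min_fragment_cpgs),
                 min_fragments_per_marker = as.integer(min_fragments_per_marker),
                 detection_epsilon = detection_epsilon),
            class = "deconv_config")
}

# U/X/M/excluded tallies of a collection over each marker (rows of
# `markers`). Returns an n_markers x 4 matrix of fragment counts.
uxm_counts <- function(x, markers, config = deconv_config()) {
  stopifnot(inherits(x, "fragment_collection"))
  nb <- nrow(markers)
  out <- matrix(0L, nb, 4, dimnames = list(NULL, c("U", "X", "M", "excluded")))
  if (nb == 0 || nrow(x) == 0) return(out)
  calls <- expand_calls(x)
  # one vectorised boundary search: findInterval re-checks sortedness and
  # coerces its second argument on every call, so never call it per marker
  los <- findInterval(markers$start_cpg - 0.5, calls$cpg) + 1L
  his <- findInterval(markers$end_cpg - 0.5, calls$cpg)
  for (i in seq_len(nb)) {
    if (his[i] < los[i]) next
    w <- los[i]:his[i]
    f <- calls$frag[w]
    tot <- rowsum(rep(1L, length(w)), f)
    met <- rowsum(as.integer(calls$meth[w]), f)
    enough <- tot[, 1] >= config$min_fragment_cpgs
    frac <- met[enough, 1] / tot[enough, 1]
    out[i, "U"] <- sum(frac <= config$u_threshold)
    out[i, "M"] <- sum(frac >= config$m_threshold)
    out[i, "X"] <- sum(enough) - out[i, "U"] - out[i, "M"]
    out[i, "excluded"] <- sum(!enough)
  }
  out
}

#' Classify one fragment over a marker
#'
#' @param fragment A single-row [fragment_collection()] or a list with
#'   `start_cpg` and `pattern`.
#' @param marker A single block (one row of a `block_set`/`marker_set`, or
#'   a list with `start_cpg` and `end_cpg`).
#' @param config A [deconv_config()].
#' @return One of `"U"`, `"X"`, `"M"`, `"excluded"`.
#' @examples
#' classify_fragment(list(start_cpg = 10, pattern = "TTTT"),
#'                   list(start_cpg = 8, end_cpg = 16))
#' @export
classify_fragment <- function(fragment, marker, config = deconv_config()) {
  calls <- strsplit(fragment$pattern[1], "")[[1]]
  idx <- fragment$start_cpg[1] + seq_along(calls) - 1L
  inm <- idx >= marker$start_cpg[1] & idx < marker$end_cpg[1] & calls != "."
  if (sum(inm) < config$min_fragment_cpgs) return("excluded")
  frac <- mean(calls[inm] == "C")
  if (frac <= config$u_threshold) "U"
  else if (frac >= config$m_threshold) "M"
  else "X"
}

#' Build a U-fraction reference atlas
#'
#' For every marker (rows: the union of all cell types' marker sets) and
#' every reference cell type (columns), the atlas entry is the fraction of
#' that cell type's classified fragments that are `U`:
#' `#U / (#U + #X + #M)`. Rows with an undefined entry (fewer than
#' `min_fragments_per_marker` classified fragments) in any column are
#' dropped with a message. Samples used as spike-in sources must not
#' appear among the references (the caller's responsibility; the spike-in
#' harness uses a sibling replicate as spike source).
#'
#' @param ref_frags Named list: cell type -> [fragment_collection()] of
#'   reference fragments.
#' @param markers A `marker_set` with a `cell_type` column (union over
#'   cell types).
#' @param config A [deconv_config()].
#' @return An object of class `uxm_atlas`: list with matrix `A` (markers x
#'   cell types), the retained `markers`, per-entry fragment `support`
#'   counts, and `config`.
#' @export
build_atlas <- function(ref_frags, markers, config = deconv_config()) {
  stopifnot(is.list(ref_frags), !is.null(names(ref_frags)))
  counts <- lapply(ref_frags, uxm_counts, markers = markers, config = config)
  atlas_from_counts(counts, markers, config)
}

# Assemble an atlas from per-cell-type U/X/M count matrices (streaming
# entry point: the spike-in harness computes counts one cell type at a
# time and discards the fragments).
atlas_from_counts <- function(counts, markers, config = deconv_config()) {
  cts <- names(counts)
  tot <- vapply(counts, function(m) m[, "U"] + m[, "X"] + m[, "M"],
                numeric(nrow(markers)))
  tot <- matrix(tot, nrow = nrow(markers), dimnames = list(NULL, cts))
  dead <- colSums(tot) == 0
  if (any(dead)) {
    stop("cell type(s) with zero classifiable fragments: ",
         paste(cts[dead], collapse = ", "))
  }
  u <- vapply(counts, function(m) m[, "U"], numeric(nrow(markers)))
  u <- matrix(u, nrow = nrow(markers), dimnames = list(NULL, cts))
  keep <- rowSums(tot < config$min_fragments_per_marker) == 0
  if (!any(keep)) stop("no usable markers: every row lacks support in some cell type")
  if (any(!keep)) {
    message(sum(!keep), " marker row(s) dropped for missing fragment support")
  }
  A <- (u / tot)[keep, , drop = FALSE]
  mk <- markers[keep, , drop = FALSE]
  rownames(A) <- block_ids(mk)
  structure(list(A = A, markers = mk, support = tot[keep, , drop = FALSE],
                 config = config),
            class = "uxm_atlas")
}

#' @export
print.uxm_atlas <- function(x, ...) {
  cat(sprintf("U-fraction atlas: %d markers x %d cell types\n",
              nrow(x$A), ncol(x$A)))
  tab <- table(x$markers$cell_type)
  cat("  markers per owning cell type: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an atlas as TSV
#'
#' First column `marker` (`chrom:start-end`), then one U-fraction column
#' per cell type, plus the owning cell type.
#' @param atlas A `uxm_atlas`.
#' @param path File path.
#' @export
write_atlas <- function(atlas, path) {
  df <- data.frame(marker = rownames(atlas$A),
                   cell_type = atlas$markers$cell_type,
                   atlas$A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate cell-type proportions in a cfDNA mixture
#'
#' The mixture's per-marker U-fractions `b` are matched against the atlas
#' columns by non-negative least squares: solve `min || A x - b ||_2`
#' subject to `x >= 0`, then normalise `x` to sum to one. Atlas rows with
#' no classifiable mixture fragments are dropped pairwise from `A` and `b`.
#'
#' @param mixture A [fragment_collection()].
#' @param atlas A [build_atlas()] result.
#' @param config A [deconv_config()]; defaults to the atlas's.
#' @return An object of class `uxm_fit`: estimated `proportions` (named,
#'   non-negative, summing to 1), the raw NNLS solution, the residual norm,
#'   and bookkeeping counts. Supports `print()`, `summary()`, `coef()`,
#'   `fitted()`, `residuals()` and `plot()`.
#' @export
deconvolve <- function(mixture, atlas, config = atlas$config) {
  stopifnot(inherits(atlas, "uxm_atlas"))
  if (nrow(atlas$A) == 0) stop("atlas is empty")
  counts <- uxm_counts(mixture, atlas$markers, config)
  tot <- counts[, "U"] + counts[, "X"] + counts[, "M"]
  keep <- tot >= max(1L, config$min_fragments_per_marker)
  if (!any(keep)) stop("no informative markers covered by the mixture")
  A <- atlas$A[keep, , drop = FALSE]
  b <- (counts[keep, "U"] / tot[keep])
  sol <- pracma::lsqnonneg(A, b)
  x <- sol$x
  names(x) <- colnames(A)
  s <- sum(x)
  props <- if (s > 0) x / s else x
  structure(list(
    proportions = props, raw = x,
    residual = sqrt(sum((A %*% x - b)^2)),
    n_markers_used = sum(keep),
    n_fragments_used = as.integer(sum(tot[keep])),
    b = b, A = A
  ), class = "uxm_fit")
}

#' @export
print.uxm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("U/X/M deconvolution fit: %d markers, %d fragments, residual %.4g\n",
              x$n_markers_used, x$n_fragments_used, x$residual))
  nz <- x$proportions[x$proportions > 0]
  cat("Estimated proportions (non-zero):\n")
  print(round(sort(nz, decreasing = TRUE), digits))
  invisible(x)
}

#' @export
summary.uxm_fit <- function(object, ...) {
  cat(sprintf("Cell types: %d (detected > 0: %d)\n",
              length(object$proportions), sum(object$proportions > 0)))
  print(object)
  invisible(object)
}

#' @export
coef.uxm_fit <- function(object, ...) object$proportions

#' @export
fitted.uxm_fit <- function(object, ...) as.numeric(object$A %*% object$raw)

#' @export
residuals.uxm_fit <- function(object, ...) object$b - fitted(object)

#' @export
plot.uxm_fit <- function(x, ...) {
  graphics::barplot(sort(x$proportions, decreasing = TRUE),
                    las = 2, ylab = "estimated proportion", ...)
  invisible(x)
}

#' Cell types detected in a fit
#' @param fit A [deconvolve()] result.
#' @param epsilon Detection threshold on the estimated proportion
#'   (strictly greater than; default 0, i.e. any mass counts).
#' @return Character vector of detected cell types.
#' @export
detected_cell_types <- function(fit, epsilon = 0) {
  names(fit$proportions)[fit$proportions > epsilon]
}
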