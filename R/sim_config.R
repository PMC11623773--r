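#' Simulation configuration
#'
#' Bundles every knob of the synthetic methylome generator. The synthetic
#' genome is laid out as CpG-dense "islands" separated by CpG-poor gaps:
#' cell-type-specific hypomethylated blocks are planted inside whole islands,
#' emulating the CpG-island-like architecture of real hypomethylated
#' regulatory markers. With the default `gap_bp` larger than the segmentation
#' span cap, island boundaries coincide with forced block boundaries.
#'
#' @param n_cell_types Number of reference cell types.
#' @param n_cpgs Total number of CpG sites in the synthetic map.
#' @param n_chroms Number of chromosomes the map is split across.
#' @param spacing_model `"island"` (default; dense islands, sparse gaps) or
#'   `"fixed"` (constant spacing everywhere, useful for arithmetic checks).
#' @param spacing_bp Mean within-island CpG spacing in bp (exact spacing for
#'   the `"fixed"` model).
#' @param gap_bp Gap in bp between consecutive islands (`"island"` model).
#' @param island_cpgs Length-2 integer vector: min and max CpGs per island.
#' @param blocks_per_cell_type Hypomethylated blocks planted per cell type.
#' @param low_propensity Methylation propensity inside a planted block for
#'   its owning cell type.
#' @param high_propensity Background methylation propensity (everywhere
#'   else, and inside planted blocks for all non-owning cell types).
#' @param frag_len_mean Mean fragment length in CpGs (truncated geometric).
#' @param frag_len_max Maximum fragment length in CpGs. Real cfDNA fragments
#'   cover few CpGs; the cap keeps fragment-level U/X/M calls meaningful.
#' @param miscall_rate Symmetric per-call bisulfite miscall probability.
#' @param coverage Default sequencing coverage (mean CpG calls per site).
#' @param seed Default seed recorded in the config; operations take an
#'   explicit `seed` argument which falls back to this.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cell_types = 2, n_cpgs = 500, blocks_per_cell_type = 5)
#' @export
sim_config <- function(n_cell_types = 10,
                       n_cpgs = 5000,
                       n_chroms = 1,
                       spacing_model = c("island", "fixed"),
                       spacing_bp = 25,
                       gap_bp = 6000,
                       island_cpgs = c(6, 12),
                       blocks_per_cell_type = 20,
                       low_propensity = 0.10,
                       high_propensity = 0.90,
                       frag_len_mean = 5,
                       frag_len_max = 20,
                       miscall_rate = 0.005,
                       coverage = 10,
                       seed = 1L) {
  spacing_model <- match.arg(spacing_model)
  if (!is_count(n_cpgs)) {
    stop("configuration error: `n_cpgs` must be a positive integer")
  }
  if (!is_count(n_cell_types)) {
    stop("configuration error: `n_cell_types` must be a positive integer")
  }
  if (!is_count(n_chroms) || n_chroms > n_cpgs) {
    stop("configuration error: `n_chroms` must be a positive integer <= n_cpgs")
  }
  if (!is_count(blocks_per_cell_type, min = 0)) {
    stop("configuration error: `blocks_per_cell_type` must be a non-negative integer")
  }
  if (!(is.numeric(island_cpgs) && length(island_cpgs) == 2 &&
        all(island_cpgs >= 1) && island_cpgs[1] <= island_cpgs[2])) {
    stop("configuration error: `island_cpgs` must be c(min, max) with 1 <= min <= max")
  }
  for (nm in c("low_propensity", "high_propensity", "miscall_rate")) {
    if (!is_prob(get(nm))) {
      stop("configuration error: `", nm, "` must be a probability in [0, 1]")
    }
  }
  if (!(is.numeric(coverage) && length(coverage) == 1 && coverage > 0)) {
    stop("configuration error: `coverage` must be > 0")
  }
  if (!is_count(frag_len_max) || frag_len_mean < 1 || frag_len_mean > frag_len_max) {
    stop("configuration error: need 1 <= frag_len_mean <= frag_len_max")
  }
  if (spacing_bp < 2) stop("configuration error: `spacing_bp` must be >= 2 (CpG width)")

  structure(
    list(
      n_cell_types = as.integer(n_cell_types),
      n_cpgs = as.integer(n_cpgs),
      n_chroms = as.integer(n_chroms),
      spacing_model = spacing_model,
      spacing_bp = spacing_bp,
      gap_bp = gap_bp,
      island_cpgs = as.integer(island_cpgs),
      blocks_per_cell_type = as.integer(blocks_per_cell_type),
      low_propensity = low_propensity,
      high_propensity = high_propensity,
      frag_len_mean = frag_len_mean,
      frag_len_max = as.integer(frag_len_max),
      miscall_rate = miscall_rate,
      coverage = coverage,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d cell types, %d CpGs on %d chromosome(s) [%s spacing]\n",
              x$n_cell_types, x$n_cpgs, x$n_chroms, x$spacing_model))
  cat(sprintf("  %d planted blocks/cell type, propensities %.2f (planted) vs %.2f (background)\n",
              x$blocks_per_cell_type, x$low_propensity, x$high_propensity))
  cat(sprintf("  fragments: mean %.1f CpGs (max %d), miscall rate %.4f, coverage %gx\n",
              x$frag_len_mean, x$frag_len_max, x$miscall_rate, x$coverage))
  invisible(x)
}
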