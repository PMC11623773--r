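#' CpG map: the ordered universe of CpG sites
#'
#' Maps the consecutive 0-based CpG index space onto genomic coordinates.
#' Positions are strictly increasing within each chromosome and CpG indices
#' run consecutively over the whole map. A map optionally carries an island
#' annotation (`attr(map, "islands")`): contiguous CpG-index intervals that
#' fragments never span (a cfDNA fragment of ~200 bp cannot cover CpGs
#' separated by a multi-kb gap).
#'
#' @param chrom Character vector of chromosome labels (one per CpG, grouped).
#' @param pos Integer vector of base-pair positions.
#' @param islands Optional data.frame with columns `island`, `chrom`,
#'   `start_cpg`, `end_cpg` (0-based half-open CpG-index intervals).
#' @return An object of class `cpg_map`: a data.frame with columns `chrom`,
#'   `pos`, `index`.
#' @export
cpg_map <- function(chrom, pos, islands = NULL) {
  stopifnot(length(chrom) == length(pos), length(pos) >= 1)
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  # chromosomes must be grouped, positions strictly increasing within each
  r <- rle(chrom)
  if (anyDuplicated(r$values)) stop("chromosome labels must be contiguous in the map")
  for (g in split(pos, factor(chrom, levels = r$values))) {
    if (length(g) > 1 && any(diff(g) <= 0)) {
      stop("positions must be strictly increasing within a chromosome")
    }
  }
  map <- data.frame(chrom = chrom, pos = pos, index = seq_along(pos) - 1L,
                    stringsAsFactors = FALSE)
  if (is.null(islands)) {
    starts <- c(0L, cumsum(r$lengths))
    islands <- data.frame(
      island = seq_along(r$values), chrom = r$values,
      start_cpg = starts[-length(starts)], end_cpg = starts[-1]
    )
  }
  attr(map, "islands") <- islands
  class(map) <- c("cpg_map", "data.frame")
  map
}

#' Number of CpGs in a map
#' @param map A [cpg_map()].
#' @export
n_cpgs <- function(map) nrow(map)

#' Build a synthetic CpG map
#'
#' Draws a CpG coordinate layout from the configured spacing model. Under
#' the `"island"` model, islands of `island_cpgs` CpGs (within-island
#' spacing geometric with mean `spacing_bp`, minimum 2 bp) are separated by
#' `gap_bp` gaps; under `"fixed"`, every spacing equals `spacing_bp` so
#' coordinates are an arithmetic sequence (islands are still annotated as
#' consecutive chunks). Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [cpg_map()] with `n_cpgs` sites and an island annotation.
#' @examples
#' map <- build_cpg_map(sim_config(n_cpgs = 100, spacing_model = "fixed",
#'                                 spacing_bp = 50))
#' @export
build_cpg_map <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_cpgs
    # island sizes drawn until the CpG budget is consumed
    lo <- config$island_cpgs[1]; hi <- config$island_cpgs[2]
    sizes <- integer(0)
    remaining <- n
    while (remaining > 0) {
      batch <- pmin(sample(lo:hi, max(16, ceiling(remaining / lo)), replace = TRUE),
                    remaining)
      take <- which(cumsum(batch) >= remaining)[1]
      if (is.na(take)) { sizes <- c(sizes, batch); remaining <- remaining - sum(batch) }
      else {
        batch <- batch[seq_len(take)]
        batch[take] <- remaining - sum(batch[-take])
        sizes <- c(sizes, batch); remaining <- 0
      }
    }
    sizes <- sizes[sizes > 0]
    n_isl <- length(sizes)

    # allocate islands to chromosomes in contiguous runs of ~equal CpG counts
    chrom_of_island <- if (config$n_chroms == 1) rep(1L, n_isl) else {
      mid <- cumsum(sizes) - sizes / 2
      pmin(config$n_chroms, pmax(1L, ceiling(mid / (n / config$n_chroms))))
    }

    spacing <- if (config$spacing_model == "fixed") {
      rep(config$spacing_bp, n)
    } else {
      2L + stats::rgeom(n, prob = 1 / max(config$spacing_bp - 1, 1.0001))
    }
    gap <- if (config$spacing_model == "fixed") config$spacing_bp else config$gap_bp

    pos <- integer(n)
    chrom <- character(n)
    idx <- 1L
    cur_pos <- 1000L
    cur_chrom <- 0L
    for (i in seq_len(n_isl)) {
      if (chrom_of_island[i] != cur_chrom) {
        cur_chrom <- chrom_of_island[i]
        cur_pos <- 1000L
      } else {
        cur_pos <- cur_pos + as.integer(gap)
      }
      k <- sizes[i]
      offs <- cumsum(c(0L, spacing[idx + seq_len(k - 1) - 1L]))[seq_len(k)]
      pos[idx:(idx + k - 1L)] <- cur_pos + offs
      chrom[idx:(idx + k - 1L)] <- paste0("chr", cur_chrom)
      cur_pos <- pos[idx + k - 1L]
      idx <- idx + k
    }
    ends <- cumsum(sizes)
    islands <- data.frame(
      island = seq_len(n_isl),
      chrom = paste0("chr", chrom_of_island),
      start_cpg = c(0L, ends[-n_isl]),
      end_cpg = ends
    )
    cpg_map(chrom, pos, islands)
  })
}

#' @export
print.cpg_map <- function(x, ...) {
  isl <- attr(x, "islands")
  cat(sprintf("CpG map: %d sites on %d chromosome(s), %d island(s)\n",
              nrow(x), length(unique(x$chrom)), nrow(isl)))
  cat(sprintf("  span: %s:%d-%s:%d\n", x$chrom[1], x$pos[1],
              x$chrom[nrow(x)], x$pos[nrow(x)]))
  invisible(x)
}

# island index (row of islands table) covering each 0-based CpG index
island_of <- function(map, idx0) {
  isl <- attr(map, "islands")
  findInterval(idx0, isl$start_cpg)
}
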