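#' Simulate cell-type reference methylomes with planted hypomethylated blocks
#'
#' Each cell type gets a per-CpG methylation propensity vector: the
#' background propensity everywhere, except inside that cell type's planted
#' blocks, where the propensity drops to `low_propensity`. A planted block
#' occupies one whole CpG island (islands with at least 4 CpGs are
#' eligible), so the block is at background propensity in every other cell
#' type and the target-vs-rest propensity gap equals
#' `high_propensity - low_propensity` at every planted CpG.
#'
#' @param map A [build_cpg_map()] result (island-annotated).
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `reference_set`: list with `propensity`
#'   (n_cpgs x n_cell_types matrix), `cell_types`, `ledger` (ground-truth
#'   planted blocks: chrom, start/end bp, start/end CpG index, cell type),
#'   `map`, and `config`.
#' @export
simulate_reference_methylomes <- function(map, config, seed = config$seed) {
  stopifnot(inherits(map, "cpg_map"), inherits(config, "sim_config"))
  isl <- attr(map, "islands")
  eligible <- which(isl$end_cpg - isl$start_cpg >= 4L)
  need <- config$n_cell_types * config$blocks_per_cell_type
  if (length(eligible) < need) {
    stop(sprintf(paste0("placement error: %d planted blocks requested but only %d ",
                        "islands of >= 4 CpGs available; increase n_cpgs"),
                 need, length(eligible)))
  }
  cell_types <- sprintf("ct%02d", seq_len(config$n_cell_types))
  with_seed(seed, {
    chosen <- sample(eligible, need)
    owner <- rep(cell_types, each = config$blocks_per_cell_type)
    propensity <- matrix(config$high_propensity, nrow = nrow(map),
                         ncol = config$n_cell_types,
                         dimnames = list(NULL, cell_types))
    for (j in seq_len(need)) {
      i <- chosen[j]
      idx <- (isl$start_cpg[i] + 1L):isl$end_cpg[i]
      propensity[idx, owner[j]] <- config$low_propensity
    }
    ledger <- data.frame(
      chrom = isl$chrom[chosen],
      start_bp = map$pos[isl$start_cpg[chosen] + 1L],
      end_bp = map$pos[isl$end_cpg[chosen]] + 2L,
      start_cpg = isl$start_cpg[chosen],
      end_cpg = isl$end_cpg[chosen],
      n_cpgs = isl$end_cpg[chosen] - isl$start_cpg[chosen],
      cell_type = owner,
      stringsAsFactors = FALSE
    )
    ledger <- ledger[order(ledger$start_cpg), ]
    rownames(ledger) <- NULL
    structure(list(propensity = propensity, cell_types = cell_types,
                   ledger = ledger, map = map, config = config, seed = seed),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d cell types over %d CpGs; %d planted blocks/type (gap %.2f)\n",
              length(x$cell_types), nrow(x$propensity),
              x$config$blocks_per_cell_type,
              x$config$high_propensity - x$config$low_propensity))
  invisible(x)
}

#' Write the planted-block ground truth as BED
#'
#' Five BED-like columns plus the owning cell type: chrom, start_bp, end_bp,
#' start_cpg, end_cpg (1-based on disk), cell_type.
#' @param refs A `reference_set`.
#' @param path Output path.
#' @export
write_ledger_bed <- function(refs, path) {
  l <- refs$ledger
  utils::write.table(
    data.frame(l$chrom, l$start_bp, l$end_bp, l$start_cpg + 1L, l$end_cpg + 1L,
               l$cell_type),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sample WGBS fragments from a reference methylome
#'
#' Fragment start positions are uniform over CpG indices; lengths (in CpGs)
#' are truncated-geometric with mean `frag_len_mean` capped at
#' `frag_len_max`; fragments are clipped at island (and hence chromosome)
#' boundaries. Each covered CpG call is drawn Bernoulli(propensity) and then
#' flipped with probability `miscall_rate` (symmetric bisulfite error).
#' Fragments are drawn until the total number of calls reaches
#' `coverage * n_cpgs`.
#'
#' @param propensity Per-CpG methylation probability vector, or a
#'   `reference_set` together with `cell_type`.
#' @param map A [cpg_map()] (taken from the reference set if omitted).
#' @param coverage Target mean calls per CpG; defaults to `config$coverage`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param cell_type When `propensity` is a `reference_set`: which column.
#' @param provenance Label recorded on the collection.
#' @return A [fragment_collection()].
#' @export
sample_fragments <- function(propensity, map = NULL, coverage = NULL,
                             config = NULL, seed = NULL, cell_type = NULL,
                             provenance = NULL) {
  if (inherits(propensity, "reference_set")) {
    refs <- propensity
    if (is.null(cell_type)) stop("give `cell_type` when sampling from a reference set")
    map <- map %||% refs$map
    config <- config %||% refs$config
    provenance <- provenance %||% cell_type
    propensity <- refs$propensity[, cell_type]
  }
  stopifnot(inherits(map, "cpg_map"), inherits(config, "sim_config"))
  coverage <- coverage %||% config$coverage
  if (coverage <= 0) stop("configuration error: coverage must be > 0")
  provenance <- provenance %||% "sample"
  n <- nrow(map)
  stopifnot(length(propensity) == n)
  isl <- attr(map, "islands")

  with_seed(seed, {
    target_calls <- coverage * n
    p_geom <- 1 / max(config$frag_len_mean, 1.0001)
    starts <- integer(0); lens <- integer(0)
    got <- 0
    while (got < target_calls) {
      nb <- max(64L, ceiling((target_calls - got) / config$frag_len_mean * 1.25))
      s <- sample.int(n, nb, replace = TRUE) - 1L
      l <- pmin(1L + stats::rgeom(nb, p_geom), config$frag_len_max)
      # clip at the end of the island containing the start CpG
      end_isl <- isl$end_cpg[findInterval(s, isl$start_cpg)]
      l <- pmin(l, end_isl - s)
      cum <- got + cumsum(l)
      m <- which(cum >= target_calls)[1]
      if (!is.na(m)) { s <- s[seq_len(m)]; l <- l[seq_len(m)]; got <- cum[m] }
      else got <- cum[nb]
      starts <- c(starts, s); lens <- c(lens, l)
    }
    total <- sum(lens)
    idx <- rep.int(starts, lens) + (sequence(lens) - 1L)
    meth <- stats::rbinom(total, 1L, propensity[idx + 1L])
    if (config$miscall_rate > 0) {
      flip <- stats::runif(total) < config$miscall_rate
      meth <- (meth + flip) %% 2L
    }
    big <- intToUtf8(84L - 17L * meth)
    ends <- cumsum(lens)
    pattern <- substring(big, ends - lens + 1L, ends)
    fragment_collection(
      data.frame(chrom = map$chrom[starts + 1L], start_cpg = starts,
                 pattern = pattern, count = 1L, stringsAsFactors = FALSE),
      provenance = provenance, seed = seed %||% NA, n_cpgs = n)
  })
}

#' Mix background and spike fragment pools at a known spike fraction
#'
#' Builds a synthetic cfDNA mixture: the expected share of CpG calls
#' originating from the spike pool equals `spike_fraction`, and the expected
#' total coverage equals `target_coverage`. Pools are down-sampled without
#' replacement and up-sampled with replacement when too small. The origin of
#' each fragment is retained in an `origin` column for validation only (it
#' is not written to PAT).
#'
#' @param background,spike [fragment_collection()]s over the same CpG map.
#' @param spike_fraction Fraction of calls drawn from the spike pool, in
#'   `[0, 1]`.
#' @param target_coverage Target mean calls per CpG of the mixture.
#' @param seed Integer seed.
#' @return A [fragment_collection()] with an `origin` column.
#' @export
mix_fragments <- function(background, spike, spike_fraction, target_coverage,
                          seed = NULL) {
  stopifnot(inherits(background, "fragment_collection"),
            inherits(spike, "fragment_collection"))
  if (!is_prob(spike_fraction)) stop("spike_fraction must be in [0, 1]")
  nc <- attr(background, "n_cpgs")
  if (is.na(nc)) nc <- attr(spike, "n_cpgs")
  if (is.na(nc)) stop("cannot determine the CpG universe size of the pools")
  if (nrow(background) == 0 && spike_fraction < 1) {
    stop("empty background pool with spike_fraction < 1")
  }
  if (nrow(spike) == 0 && spike_fraction > 0) {
    stop("empty spike pool with spike_fraction > 0")
  }
  total_target <- round(target_coverage * nc)
  spike_target <- round(spike_fraction * total_target)
  bg_target <- total_target - spike_target

  with_seed(seed, {
    take <- function(pool, call_target) {
      if (call_target <= 0) return(pool[0, , drop = FALSE])
      ids <- rep.int(seq_len(nrow(pool)), pool$count)
      len <- (nchar(pool$pattern) - nchar(gsub("[CT]", "", pool$pattern)))[ids]
      pick <- integer(0); got <- 0
      repeat {
        o <- sample(seq_along(ids))  # without replacement within each pass
        cum <- got + cumsum(len[o])
        m <- which(cum >= call_target)[1]
        if (!is.na(m)) { pick <- c(pick, ids[o[seq_len(m)]]); break }
        pick <- c(pick, ids[o]); got <- cum[length(cum)]  # up-sample: next pass
      }
      out <- pool[pick, , drop = FALSE]
      out$count <- 1L
      out
    }
    bg <- take(background, bg_target)
    sp <- take(spike, spike_target)
    df <- rbind(as.data.frame(bg)[, c("chrom", "start_cpg", "pattern", "count")],
                as.data.frame(sp)[, c("chrom", "start_cpg", "pattern", "count")])
    df$origin <- rep(c("background", "spike"), c(nrow(bg), nrow(sp)))
    rownames(df) <- NULL
    fragment_collection(df,
                        provenance = sprintf("mixture(%s + %g%% %s)",
                                             attr(background, "provenance"),
                                             100 * spike_fraction,
                                             attr(spike, "provenance")),
                        seed = seed %||% NA, n_cpgs = nc)
  })
}
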