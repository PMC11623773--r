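#' Spike-in grid configuration
#'
#' The evaluation grid mirrors the study design: spike fractions between 0
#' and 10%, coverage between 2.5x and 30x, 25-500 markers per cell type,
#' segmentation minimum block size 3 or 4 CpGs, and one replicate per
#' synthetic background "individual" (12 by default, mirroring the twelve
#' healthy plasma samples).
#'
#' @param fractions Spike-in fractions (0 must be included when AUC is
#'   wanted: the unspiked replicates are the negatives).
#' @param coverages Mixture coverages in x.
#' @param k Markers per cell type (menu 25, 50, 100, 250, 300, 400, 500).
#' @param min_cpg Segmentation minimum block sizes to evaluate.
#' @param replicates Background individuals per condition.
#' @param base_seed Seed from which every grid cell's seed is derived.
#' @return An object of class `spike_grid_config`.
#' @export
spike_grid_config <- function(fractions = c(0, 1e-4, 1e-3, 5e-3, 0.01, 0.05, 0.10),
                              coverages = c(2.5, 5, 10, 20, 30),
                              k = 500,
                              min_cpg = 4,
                              replicates = 12,
                              base_seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions <= 1), all(coverages > 0),
            all(k >= 1), all(min_cpg >= 1), is_count(replicates))
  structure(list(fractions = fractions, coverages = coverages,
                 k = as.integer(k), min_cpg = as.integer(min_cpg),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "spike_grid_config")
}

#' Prepare the simulation assets a spike-in grid runs on
#'
#' Builds, for one base seed: the CpG map; reference methylomes with
#' planted cell-type-specific hypomethylated blocks; `n_ref_reps`
#' reference WGBS samples per cell type (streamed to per-CpG tallies for
#' segmentation and marker discovery, regenerated per cell type when the
#' atlas is built); per-`min_cpg` segmentations, marker candidates and
#' full-candidate U/X/M atlas counts; background "individual" fragment
#' pools (mixtures of the non-target cell types with Dirichlet-distributed
#' proportions, emulating healthy plasma cfDNA); and a spike-source pool
#' sampled from the target cell type's methylome as a sibling replicate
#' that never enters the references (the overfitting guard).
#'
#' @param config A [sim_config()].
#' @param target_cell_type Column of the reference set to spike (default
#'   the first, conventionally the motor-neuron stand-in).
#' @param n_ref_reps Reference samples per cell type (default 3).
#' @param ref_coverage Coverage of each reference sample (default 30).
#' @param n_individuals Background pools to generate (default 12).
#' @param background_coverage Coverage of each background pool; keep above
#'   the largest mixture coverage to avoid heavy up-sampling (default 12).
#' @param spike_coverage Coverage of the spike pool (default 30).
#' @param min_cpg_values Segmentation minimum block sizes (default 4).
#' @param max_bp Segmentation span cap (default 5000).
#' @param marker_cfg A [marker_config()] (its `k` is ignored here: the
#'   grid selects k at run time).
#' @param deconv_cfg A [deconv_config()].
#' @param seed Base seed; defaults to `config$seed`.
#' @return An object of class `spikein_assets`.
#' @export
prepare_spikein_assets <- function(config,
                                   target_cell_type = NULL,
                                   n_ref_reps = 3,
                                   ref_coverage = 30,
                                   n_individuals = 12,
                                   background_coverage = 12,
                                   spike_coverage = 30,
                                   min_cpg_values = 4,
                                   max_bp = 5000,
                                   marker_cfg = marker_config(),
                                   deconv_cfg = deconv_config(),
                                   seed = config$seed) {
  map <- build_cpg_map(config, seed = derive_seed(seed, 1))
  refs <- simulate_reference_methylomes(map, config, seed = derive_seed(seed, 2))
  target <- target_cell_type %||% refs$cell_types[1]
  stopifnot(target %in% refs$cell_types)
  n <- nrow(map)
  cts <- refs$cell_types

  ref_seed <- function(ct, rep) derive_seed(seed, 100 + match(ct, cts) * 50 + rep)
  sample_names <- as.vector(outer(cts, seq_len(n_ref_reps),
                                  function(ct, r) sprintf("%s_r%d", ct, r)))
  groups <- lapply(cts, function(ct) sprintf("%s_r%d", ct, seq_len(n_ref_reps)))
  names(groups) <- cts

  # stream reference samples to per-CpG tallies (enough for segmentation
  # and block tables); fragments are regenerated later for the atlas
  tallies <- vector("list", length(sample_names))
  names(tallies) <- sample_names
  beta <- matrix(NA_real_, n, length(sample_names),
                 dimnames = list(NULL, sample_names))
  for (ct in cts) {
    for (r in seq_len(n_ref_reps)) {
      nm <- sprintf("%s_r%d", ct, r)
      fr <- sample_fragments(refs, cell_type = ct, coverage = ref_coverage,
                             seed = ref_seed(ct, r), provenance = nm)
      t <- per_cpg_tally(fr, n)
      tallies[[nm]] <- t
      beta[, nm] <- ifelse(t$total > 0, t$meth / t$total, NA_real_)
      rm(fr)
    }
  }

  per_min_cpg <- lapply(min_cpg_values, function(mc) {
    blocks <- segment_genome(beta, map, min_cpg = mc, max_bp = max_bp)
    table <- block_methylation_table(blocks, tallies, n_cpgs = n,
                                     min_depth = marker_cfg$min_depth)
    candidates <- lapply(cts, function(ct) {
      find_markers(table, groups[[ct]],
                   unlist(groups[cts != ct], use.names = FALSE), marker_cfg)
    })
    names(candidates) <- cts
    union_markers <- do.call(rbind, lapply(cts, function(ct) {
      cand <- candidates[[ct]]
      if (nrow(cand)) cand$cell_type <- ct
      cand
    }))
    # U/X/M counts for every candidate row, one cell type at a time
    counts <- lapply(cts, function(ct) {
      merged <- do.call(rbind, lapply(seq_len(n_ref_reps), function(r) {
        as.data.frame(sample_fragments(refs, cell_type = ct,
                                       coverage = ref_coverage,
                                       seed = ref_seed(ct, r)))
      }))
      fc <- fragment_collection(merged, provenance = ct, n_cpgs = n)
      uxm_counts(fc, union_markers, deconv_cfg)
    })
    names(counts) <- cts
    list(min_cpg = mc, blocks = blocks, candidates = candidates,
         union_markers = union_markers, counts = counts)
  })
  names(per_min_cpg) <- as.character(min_cpg_values)

  bg_cts <- setdiff(cts, target)
  backgrounds <- lapply(seq_len(n_individuals), function(i) {
    with_seed(derive_seed(seed, 5000 + i), {
      w <- stats::rgamma(length(bg_cts), 1)
      w <- w / sum(w)
    })
    parts <- lapply(seq_along(bg_cts), function(j) {
      cov_j <- background_coverage * w[j]
      if (cov_j * n < 1) return(NULL)
      as.data.frame(sample_fragments(refs, cell_type = bg_cts[j],
                                     coverage = cov_j,
                                     seed = derive_seed(seed, 6000 + i * 37 + j)))
    })
    fragment_collection(do.call(rbind, parts),
                        provenance = sprintf("individual%02d", i), n_cpgs = n)
  })

  spike <- sample_fragments(refs, cell_type = target, coverage = spike_coverage,
                            seed = derive_seed(seed, 9001),
                            provenance = paste0(target, "_spike"))

  structure(list(map = map, refs = refs, target = target,
                 per_min_cpg = per_min_cpg, backgrounds = backgrounds,
                 spike = spike, groups = groups,
                 marker_cfg = marker_cfg, deconv_cfg = deconv_cfg,
                 seed = seed),
            class = "spikein_assets")
}

#' @export
print.spikein_assets <- function(x, ...) {
  cat(sprintf("Spike-in assets: target '%s', %d cell types, %d background individuals\n",
              x$target, length(x$refs$cell_types), length(x$backgrounds)))
  for (p in x$per_min_cpg) {
    cat(sprintf("  min_cpg %d: %d blocks, %d candidate markers\n",
                p$min_cpg, nrow(p$blocks), nrow(p$union_markers)))
  }
  invisible(x)
}

#' Run a spike-in evaluation grid
#'
#' For every (spike fraction, coverage, k, min_cpg, replicate) cell of the
#' grid, a mixture is built from the replicate's background pool and the
#' spike pool, deconvolved against the k-marker atlas, and recorded. A
#' failed cell is recorded with `NA` estimates rather than aborting the
#' grid.
#'
#' @param grid A [spike_grid_config()].
#' @param assets A [prepare_spikein_assets()] result; must cover the
#'   grid's `min_cpg` values and `replicates`.
#' @return data.frame of class `spikein_results`: one row per grid cell x
#'   replicate with the condition, the estimated proportion of every cell
#'   type (`prop.<cell_type>` columns), `target_estimate`, `n_detected`
#'   (cell types with estimate > detection epsilon) and bookkeeping.
#' @export
run_spikein_grid <- function(grid, assets) {
  stopifnot(inherits(grid, "spike_grid_config"),
            inherits(assets, "spikein_assets"))
  missing_mc <- setdiff(as.character(grid$min_cpg), names(assets$per_min_cpg))
  if (length(missing_mc)) {
    stop("assets lack segmentation for min_cpg = ", paste(missing_mc, collapse = ", "))
  }
  if (grid$replicates > length(assets$backgrounds)) {
    stop("assets provide fewer background individuals than grid replicates")
  }
  cts <- assets$refs$cell_types
  eps <- assets$deconv_cfg$detection_epsilon
  rows <- list()
  cell_i <- 0L
  for (mc in grid$min_cpg) {
    pm <- assets$per_min_cpg[[as.character(mc)]]
    for (k in grid$k) {
      sel <- do.call(rbind, lapply(cts, function(ct) {
        suppressWarnings(rank_and_select(pm$candidates[[ct]], k, cell_type = ct))
      }))
      ids <- paste(sel$start_cpg, sel$cell_type)
      pos <- match(ids, paste(pm$union_markers$start_cpg, pm$union_markers$cell_type))
      counts_k <- lapply(pm$counts, function(m) m[pos, , drop = FALSE])
      atlas <- atlas_from_counts(counts_k, sel, assets$deconv_cfg)
      for (f in grid$fractions) {
        for (cov in grid$coverages) {
          for (rep_i in seq_len(grid$replicates)) {
            cell_i <- cell_i + 1L
            cell_seed <- derive_seed(grid$base_seed, 20000 + cell_i)
            row <- data.frame(fraction = f, coverage = cov, k = k,
                              min_cpg = mc, replicate = rep_i,
                              seed = cell_seed)
            est <- tryCatch({
              mix <- mix_fragments(assets$backgrounds[[rep_i]], assets$spike,
                                   spike_fraction = f, target_coverage = cov,
                                   seed = cell_seed)
              fit <- deconvolve(mix, atlas)
              fit
            }, error = function(e) NULL)
            if (is.null(est)) {
              props <- rep(NA_real_, length(cts))
              row$target_estimate <- NA_real_
              row$n_detected <- NA_integer_
              row$n_markers_used <- NA_integer_
              row$n_fragments_used <- NA_integer_
            } else {
              props <- est$proportions[cts]
              row$target_estimate <- unname(props[assets$target])
              row$n_detected <- sum(props > eps)
              row$n_markers_used <- est$n_markers_used
              row$n_fragments_used <- est$n_fragments_used
            }
            pm2 <- as.data.frame(as.list(props))
            names(pm2) <- paste0("prop.", cts)
            rows[[cell_i]] <- cbind(row, pm2)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target") <- assets$target
  attr(out, "cell_types") <- cts
  class(out) <- c("spikein_results", "data.frame")
  out
}

#' Detection probability at a spike fraction
#'
#' Fraction of replicates at `fraction` in which `cell_type`'s estimated
#' proportion exceeds `epsilon` (default 0: any mass counts as detection).
#'
#' @param results A [run_spikein_grid()] result (filter it first if you
#'   want a single coverage/k condition).
#' @param cell_type Cell type to score; default the spiked target.
#' @param fraction Spike fraction to score.
#' @param epsilon Detection threshold (strict inequality).
#' @return Detection probability in `[0, 1]`.
#' @export
detection_probability <- function(results, cell_type = attr(results, "target"),
                                  fraction, epsilon = 0) {
  sc <- results[results$fraction == fraction, paste0("prop.", cell_type)]
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) stop("no replicates at fraction ", fraction)
  mean(sc > epsilon)
}

#' Rank-based detection AUC at a spike fraction
#'
#' Mann-Whitney AUC using the estimated proportion of `cell_type` as the
#' score: spiked replicates at `fraction` are the positives, the 0%-spike
#' replicates the negatives; ties contribute 1/2. Filter `results` to one
#' coverage/k condition to score within-condition AUC.
#'
#' @inheritParams detection_probability
#' @return AUC in `[0, 1]`.
#' @export
detection_auc <- function(results, fraction,
                          cell_type = attr(results, "target")) {
  col <- paste0("prop.", cell_type)
  pos <- results[results$fraction == fraction, col]
  neg <- results[results$fraction == 0, col]
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("need both spiked (fraction = ", fraction, ") and unspiked replicates")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Linearity of recovery: OLS of estimated on true spike fraction
#'
#' @param results A [run_spikein_grid()] result.
#' @param fractions Spike fractions to include (default every spiked
#'   fraction in 1-10%, the range over which recovery is linear).
#' @param cell_type Cell type whose estimate is regressed.
#' @return List with `slope`, `intercept`, `adj_r_squared`, `p_value`
#'   (two-sided, slope), `n`, and the `lm` fit.
#' @export
recovery_regression <- function(results, fractions = NULL,
                                cell_type = attr(results, "target")) {
  col <- paste0("prop.", cell_type)
  fr <- unique(results$fraction)
  fractions <- fractions %||% fr[fr >= 0.01 & fr <= 0.10]
  if (length(unique(fractions)) < 3) stop("need at least 3 distinct fractions")
  d <- results[results$fraction %in% fractions & !is.na(results[[col]]), ]
  fit <- stats::lm(d[[col]] ~ d$fraction)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = s$adj.r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = nrow(d), fit = fit)
}

#' False-positive model: detected cell types vs coverage and marker count
#'
#' OLS with intercept of the number of cell types detected on the mixture
#' coverage and the number of markers per cell type, reproducing the
#' direction of the coverage/markers effects on spurious detections.
#'
#' @param results A [run_spikein_grid()] result with variation in both
#'   `coverage` and `k`.
#' @return List with named `coefficients`, `p_values`, and the `lm` fit.
#' @export
false_positive_model <- function(results) {
  d <- results[!is.na(results$n_detected), ]
  fit <- stats::lm(n_detected ~ coverage + k, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("collinear design: coverage and marker count do not both vary")
  s <- summary(fit)
  list(coefficients = cf, p_values = s$coefficients[, 4], fit = fit)
}

#' Per-condition summary of a spike-in grid
#'
#' @param object A `spikein_results` data.frame.
#' @param epsilon Detection threshold.
#' @param ... Unused.
#' @return data.frame: one row per (fraction, coverage, k, min_cpg) with
#'   mean/sd of the target estimate, detection probability, and mean
#'   false-positive count.
#' @export
summary.spikein_results <- function(object, epsilon = 0, ...) {
  key <- interaction(object$fraction, object$coverage, object$k,
                     object$min_cpg, drop = TRUE)
  agg <- function(f) as.numeric(tapply(seq_len(nrow(object)), key, f))
  first <- function(col) as.numeric(tapply(object[[col]], key, function(v) v[1]))
  data.frame(
    fraction = first("fraction"), coverage = first("coverage"),
    k = first("k"), min_cpg = first("min_cpg"),
    n = as.integer(tapply(object$target_estimate, key,
                          function(v) sum(!is.na(v)))),
    mean_estimate = as.numeric(tapply(object$target_estimate, key, mean,
                                      na.rm = TRUE)),
    sd_estimate = as.numeric(tapply(object$target_estimate, key, stats::sd,
                                    na.rm = TRUE)),
    detection_prob = as.numeric(tapply(object$target_estimate, key,
                                       function(v) mean(v > epsilon, na.rm = TRUE))),
    mean_n_detected = as.numeric(tapply(object$n_detected, key, mean,
                                        na.rm = TRUE))
  )
}
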